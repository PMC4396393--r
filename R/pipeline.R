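#' Read a run configuration file
#'
#' The pipeline is driven by a single structured text (YAML) file with one
#' section per stage: `geometry`, `schedule`, `trajectory`, `noise`,
#' `reduction`, `guinier`, `kinetics`, `sphere`, plus top-level `seed` and
#' `outdir`. Missing sections fall back to the package defaults, so an
#' empty file is a valid configuration.
#'
#' @param path YAML file path, or `NULL` for an all-defaults config.
#' @return a named list of class `"run_config"`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else {
    out <- tryCatch(yaml::read_yaml(path), error = function(e) {
      stop("cannot parse config ", path, ": ", conditionMessage(e))
    })
    if (is.null(out)) list() else out
  }
  defaults <- list(seed = 1, outdir = "trxss_run",
                   geometry = list(), schedule = list(), trajectory = list(),
                   noise = list(), reduction = list(), guinier = list(),
                   kinetics = list(), sphere = list())
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  structure(cfg, class = "run_config")
}

# instantiate the stage objects from a config, applying overrides onto the
# package defaults; every constructor revalidates its invariants
.build_stages <- function(config) {
  mk <- function(fun, over, drop = character()) {
    over <- over[setdiff(names(over), drop)]
    do.call(fun, over)
  }
  list(
    geometry = mk(experiment_geometry, config$geometry),
    schedule = mk(delay_schedule, config$schedule),
    trajectory = mk(trajectory_params, config$trajectory),
    noise = mk(noise_model, config$noise),
    window = mk(norm_window, config$reduction,
                drop = c("threshold", "iterate")),
    const = mk(guinier_constants, config$guinier, drop = "q_range")
  )
}

#' Validate a run configuration
#'
#' Checks every sub-configuration against the invariants of its
#' constructor and returns the violations (empty character vector when the
#' configuration is valid). Each violation names the offending section and
#' field.
#'
#' @param config a `"run_config"` from [read_run_config()].
#' @return character vector of violations.
#' @export
validate_config <- function(config) {
  viol <- character()
  try_stage <- function(label, expr) {
    err <- tryCatch({expr; NULL}, error = function(e) conditionMessage(e))
    if (!is.null(err)) viol <<- c(viol, paste0(label, ": ", err))
  }
  try_stage("geometry", do.call(experiment_geometry, config$geometry))
  try_stage("schedule", do.call(delay_schedule, config$schedule))
  try_stage("trajectory", do.call(trajectory_params, config$trajectory))
  try_stage("noise", do.call(noise_model, config$noise))
  red <- config$reduction
  try_stage("reduction",
            do.call(norm_window,
                    red[setdiff(names(red), c("threshold", "iterate"))]))
  if (!is.null(red$threshold) && !(red$threshold > 0)) {
    viol <- c(viol, "reduction: threshold must be > 0")
  }
  gui <- config$guinier
  try_stage("guinier",
            do.call(guinier_constants,
                    gui[setdiff(names(gui), "q_range")]))
  if (!is.null(gui$q_range) &&
      (length(gui$q_range) != 2 || gui$q_range[1] >= gui$q_range[2])) {
    viol <- c(viol, "guinier: q_range must be an increasing pair")
  }
  kin <- config$kinetics
  if (!is.null(kin$irf_fwhm) && kin$irf_fwhm < 0) {
    viol <- c(viol, "kinetics: irf_fwhm must be >= 0")
  }
  sph <- config$sphere
  if (length(sph)) {
    try_stage("sphere", {
      do.call(mb_sphere_material,
              sph[intersect(names(sph), c("v_l", "v_t", "d_P", "R"))])
      do.call(acoustic_medium,
              sph[intersect(names(sph), c("d_m", "v_m"))])
    })
  }
  if (!is.null(config$seed) &&
      (!is.numeric(config$seed) || config$seed != round(config$seed))) {
    viol <- c(viol, "seed: must be an integer")
  }
  viol
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate, reduce, difference-Guinier series fit, kinetic
#' fits of both observables, and the sphere-mode calculation, writing every
#' stage's artifacts under `outdir`: the raw frame directory with its
#' manifest, per-delay reduced difference patterns, the screening summary,
#' the structural-parameter series table, the kinetic fit coefficients,
#' the mode table, a log, and a `checksums.csv` manifest (md5 of every
#' artifact). Deterministic given the seed: rerunning with the same
#' configuration reproduces the checksums.
#'
#' @param config a `"run_config"` (default: all package defaults).
#' @param outdir output directory; overrides `config$outdir`.
#' @param seed integer seed; overrides `config$seed`.
#' @param write_frames also write every raw frame (default `TRUE`; the
#'   frame files dominate the output size).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the run, the reduction, the fitted
#'   series, both kinetic fits, the sphere modes and the artifact table.
#' @export
run_all <- function(config = read_run_config(), outdir = NULL, seed = NULL,
                    write_frames = TRUE, quiet = FALSE) {
  viol <- validate_config(config)
  if (length(viol)) {
    stop("invalid configuration:\n  ", paste(viol, collapse = "\n  "))
  }
  if (is.null(outdir)) outdir <- config$outdir
  if (is.null(seed)) seed <- config$seed
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) {
    msg <- sprintf(...)
    writeLines(msg, log_con)
    if (!quiet) message(msg)
  }
  stage <- function(label, expr) {
    say("[%s] start", label)
    out <- tryCatch(expr, error = function(e) {
      say("[%s] FAILED: %s", label, conditionMessage(e))
      stop("pipeline stage '", label, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    say("[%s] done", label)
    out
  }

  stages <- .build_stages(config)
  q_range <- config$guinier$q_range
  if (is.null(q_range)) q_range <- c(0.02, 0.08)
  threshold <- config$reduction$threshold
  if (is.null(threshold)) threshold <- 2
  irf <- config$kinetics$irf_fwhm
  if (is.null(irf)) irf <- stages$trajectory$irf_fwhm
  say("seed: %d", as.integer(seed))

  run <- stage("simulate", simulate_run(
    schedule = stages$schedule, params = stages$trajectory,
    noise = stages$noise, const = stages$const, seed = seed))
  if (write_frames) {
    stage("write-frames", write_run(run, file.path(outdir, "frames")))
  } else {
    utils::write.csv(run$manifest, file.path(outdir, "manifest.csv"),
                     row.names = FALSE)
  }

  reduced <- stage("reduce", reduce_run(
    run, window = stages$window, threshold = threshold,
    screen = stages$noise$sigma_rel > 0))
  red_dir <- file.path(outdir, "reduced")
  dir.create(red_dir, showWarnings = FALSE)
  for (p in reduced$patterns) {
    write_pattern(p, file.path(red_dir,
                               sprintf("diff_%+08.2fps.dat", p$meta$delay)))
  }
  utils::write.csv(reduced$summary, file.path(outdir, "screening.csv"),
                   row.names = FALSE)
  say("screening: %d/%d differences rejected",
      sum(reduced$summary$n_rejected), sum(reduced$summary$n_total))

  series <- stage("fit-guinier", fit_series(
    reduced$patterns, q_range = q_range, const = stages$const,
    unit_weights = stages$noise$sigma_rel == 0))
  utils::write.csv(as.data.frame(series),
                   file.path(outdir, "guinier_series.csv"),
                   row.names = FALSE)

  kin <- list()
  for (obs in c("dRg", "dVp")) {
    kin[[obs]] <- stage(paste0("fit-kinetics-", obs), fit_kinetics(
      delay_series(series, obs), irf_fwhm = irf))
  }
  kin_tab <- do.call(rbind, lapply(names(kin), function(obs) {
    f <- kin[[obs]]
    data.frame(observable = obs, parameter = names(f$coefficients),
               estimate = unname(f$coefficients),
               se = unname(f$se[names(f$coefficients)]),
               chi2red = f$chi2red)
  }))
  utils::write.csv(kin_tab, file.path(outdir, "kinetics.csv"),
                   row.names = FALSE)

  sph_cfg <- config$sphere
  material <- do.call(mb_sphere_material,
                      sph_cfg[intersect(names(sph_cfg),
                                        c("v_l", "v_t", "d_P", "R"))])
  medium <- do.call(acoustic_medium,
                    sph_cfg[intersect(names(sph_cfg), c("d_m", "v_m"))])
  modes <- stage("sphere-modes", find_modes(material, medium))
  utils::write.csv(as.data.frame(modes), file.path(outdir, "modes.csv"),
                   row.names = FALSE)

  files <- sort(setdiff(list.files(outdir, recursive = TRUE),
                        c("run.log", "checksums.csv")))
  checks <- data.frame(file = files,
                       md5 = unname(tools::md5sum(file.path(outdir, files))))
  utils::write.csv(checks, file.path(outdir, "checksums.csv"),
                   row.names = FALSE)
  say("wrote %d artifacts", nrow(checks))

  invisible(list(run = run, reduced = reduced, series = series,
                 kinetics = kin, modes = modes, checksums = checks))
}
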