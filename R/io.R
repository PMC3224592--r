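#' Load a parameter set from a config file
#'
#' Reads a flat JSON key-value config (keys are the parameter names of
#' [as_params()]), fills every missing key from the named default profile,
#' validates, and returns the resolved parameter set. An empty or absent
#' file returns the profile defaults.
#'
#' @param path path to a JSON config, or `NULL` for profile defaults
#'   only.
#' @param profile default profile: `"table2"`, `"table5"`,
#'   `"bangladesh_pre"` or `"bangladesh_post"`.
#' @param inhibition_convention see [as_params()].
#' @param quiet suppress the resolved-value log.
#' @return an `as_params` object.
#' @export
load_parameters <- function(path = NULL, profile = "table2",
                            inhibition_convention = "table", quiet = TRUE) {
  p <- as_params(profile, inhibition_convention = inhibition_convention)
  overrides <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("parameter file not found: ", path)
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (nzchar(trimws(txt))) {
      overrides <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
      if (!is.list(overrides)) stop("parameter file must be a JSON object")
    }
    p <- set_params(p, overrides)
  }
  if (!quiet) {
    for (k in PARAM_KEYS) {
      message(sprintf("  %-12s = %-10g %s", k, p[[k]],
                      if (k %in% names(overrides)) "(file)" else "(profile)"))
    }
  }
  p
}

#' Write / read a trajectory as CSV
#'
#' Column 1 is time (hr); one column per state field follows, in
#' canonical order (concentrations in uM, urine in umol; the in-vitro
#' variant uses phase-qualified names with totals in nmol).
#'
#' @param traj an `as_trajectory` or `invitro_trajectory` data frame.
#' @param path file path.
#' @return `write_trajectory_csv` returns `path` invisibly;
#'   `read_trajectory_csv` returns a data frame.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  utils::read.csv(path)
}

write_manifest <- function(outdir, command, seed, p, inputs = character(0),
                           extra = list()) {
  manifest <- c(list(
    command = command,
    seed = seed,
    package = "asmethyl",
    version = as.character(utils::packageVersion("asmethyl")),
    r_version = R.version.string,
    parameters = stats::setNames(
      lapply(PARAM_KEYS, function(k) p[[k]]), PARAM_KEYS),
    input_hashes = as.list(tools::md5sum(inputs))
  ), extra)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Execute a named pipeline command
#'
#' Programmatic equivalent of the command-line front end
#' (`inst/cli/asmethyl.R`). Runs one of the pipeline commands and writes
#' its artifacts plus a machine-readable `manifest.json` (resolved
#' parameters, seed, version, input file hashes) into `outdir`.
#'
#' Commands: `"simulate"` (dose schedule -> trajectory + excretion CSV),
#' `"invitro"` (hepatocyte time course), `"steady"` (chronic steady-state
#' profile), `"folate-compare"` (pre/post SAM scenario comparison),
#' `"generate"` (synthetic triple-arm datasets), `"fit"` (staged
#' calibration on generated or supplied datasets).
#'
#' @param command one of the commands above.
#' @param outdir output directory (created if needed).
#' @param params_file optional JSON parameter config.
#' @param profile default parameter profile.
#' @param dose,species,days single/repeated dose settings (ug, arsenical,
#'   number of daily doses).
#' @param chronic_daily chronic intake (ug/day) for `steady` and
#'   `folate-compare`.
#' @param background dietary background intake (ug/day).
#' @param sam,sam_post SAM levels (uM) for scenario commands.
#' @param upregulation AS3MT expression multiplier.
#' @param initial_um initial medium concentration (uM) for `invitro`.
#' @param horizon simulation horizon (hr).
#' @param cv noise coefficient of variation for `generate`.
#' @param seed integer seed recorded in the manifest and used for any
#'   randomness.
#' @return invisibly, a list of the artifacts written (paths and main
#'   results).
#' @export
run_command <- function(command = c("simulate", "invitro", "steady",
                                    "folate-compare", "generate", "fit"),
                        outdir = ".", params_file = NULL, profile = "table2",
                        dose = 500, species = "iAs", days = 1,
                        chronic_daily = 300, background = 7,
                        sam = 15, sam_post = 60, upregulation = 2,
                        initial_um = 0.1, horizon = 100, cv = 0.05,
                        seed = 1L) {
  command <- match.arg(command)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- load_parameters(params_file, profile = profile)
  inputs <- if (is.null(params_file)) character(0) else params_file
  art <- list()
  if (command == "simulate") {
    sched <- if (days > 1) {
      repeated_dose_schedule(dose, days, species, background_rate = background)
    } else {
      dose_schedule(dose_event(0, dose, species), background_rate = background)
    }
    times <- seq(0, horizon, by = min(1, horizon / 100))
    traj <- simulate_arsenic(p, sched, times)
    art$trajectory <- write_trajectory_csv(
      traj, file.path(outdir, "trajectory.csv"))
    st <- seq(0, horizon, length.out = 21)
    art$excretion <- write_excretion_csv(
      interval_excretion_rates(traj, st),
      file.path(outdir, "excretion.csv"))
  } else if (command == "invitro") {
    traj <- simulate_invitro(initial_um, times = seq(0, horizon, by = 0.5))
    art$trajectory <- write_trajectory_csv(
      traj, file.path(outdir, "invitro_trajectory.csv"))
  } else if (command == "steady") {
    prof <- run_chronic_profile(chronic_daily, sam, upregulation, p)
    df <- data.frame(
      row = c("blood_percent", "urine_percent"),
      iAs = round_half_up(c(prof$blood_percent[1], prof$urine_percent[1])),
      MMA = round_half_up(c(prof$blood_percent[2], prof$urine_percent[2])),
      DMA = round_half_up(c(prof$blood_percent[3], prof$urine_percent[3])))
    art$profile_csv <- file.path(outdir, "profile.csv")
    utils::write.csv(df, art$profile_csv, row.names = FALSE)
    art$profile <- prof
  } else if (command == "folate-compare") {
    pre <- run_chronic_profile(chronic_daily, sam, upregulation, p)
    post <- run_chronic_profile(chronic_daily, sam_post, upregulation, p)
    cmp <- folate_comparison(pre, post)
    out <- list(
      pre = list(blood_percent = pre$blood_percent,
                 urine_percent = pre$urine_percent),
      post = list(blood_percent = post$blood_percent,
                  urine_percent = post$urine_percent),
      percent_change = as.list(cmp))
    art$comparison <- file.path(outdir, "folate_comparison.json")
    jsonlite::write_json(out, art$comparison, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    art$changes <- cmp
  } else if (command == "generate") {
    arms <- synthetic_triple_arm(p, noise_model(cv = cv, seed = seed))
    for (nm in names(arms)) {
      art[[nm]] <- write_excretion_csv(
        arms[[nm]]$series, file.path(outdir, paste0("arm_", nm, ".csv")))
      truth <- stats::setNames(lapply(PARAM_KEYS, function(k) p[[k]]),
                               PARAM_KEYS)
      jsonlite::write_json(
        list(truth = truth, cv = cv, seed = seed),
        file.path(outdir, paste0("arm_", nm, "_truth.json")),
        auto_unbox = TRUE, digits = NA)
    }
  } else if (command == "fit") {
    arms <- synthetic_triple_arm(p, noise_model(cv = cv, seed = seed))
    hashes <- list()
    for (nm in names(arms)) {
      f <- write_excretion_csv(arms[[nm]]$series,
                               file.path(outdir, paste0("arm_", nm, ".csv")))
      hashes[[nm]] <- unname(tools::md5sum(f))
    }
    fit <- staged_calibration(arms, base_params = p, seed = seed,
                              n_starts = 3, n_hops = 40, patience = 20)
    art$fit <- file.path(outdir, "fit_result.json")
    jsonlite::write_json(
      list(estimates = as.list(fit$estimates), loss = fit$loss,
           converged = vapply(fit$stages, `[[`, logical(1), "converged"),
           seed = seed, stage_order = names(fit$stages),
           dataset_md5 = hashes),
      art$fit, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    art$estimates <- fit$estimates
  }
  write_manifest(outdir, command, seed, p, inputs)
  invisible(art)
}
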