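# Configuration validation and batch orchestration.

config_defaults <- function() {
  list(
    baseline_n = 5L,
    k_sd = 2,
    consecutive = 2L,
    band_hz = c(0.16, 2.5),
    threshold_um = 0.5,
    depth_of_field_um = 0.7,
    pixel_size_um = 0.1,
    z_step_um = 0.75,
    bandpass = TRUE,
    bandpass_low_px = 3,
    bandpass_high_px = 40,
    threshold_method = "otsu",
    min_area_px = 2L,
    min_component_px = 5L,
    min_branch_px = 5L,
    seed = 1L,
    inputs = list()
  )
}

#' Validate a run configuration
#'
#' Accepts a list or a YAML file path. Unknown keys are rejected; defaults
#' are injected for absent keys (baseline_n = 5, k_sd = 2, consecutive = 2,
#' band 0.16-2.5 Hz, association threshold 0.5 um, depth of field 0.7 um,
#' pixel size 0.1 um, z-step 0.75 um). Keys carry explicit units in their
#' names; `threshold_nm` is accepted and normalised to `threshold_um`.
#' Every referenced input file must exist. All problems are reported
#' together in one structured error.
#'
#' @param cfg A named list or path to a YAML mapping. Inputs are entries of
#'   `inputs`, each a list with `path` and `role` (one of `timesweep`,
#'   `freqsweep`, `network_stack`, `coloc_stack`; stack paths are sidecar
#'   prefixes).
#' @return A validated `run_config` list.
#' @export
validate_config <- function(cfg = list()) {
  if (is.character(cfg)) {
    check_that(file.exists(cfg), "config", "config file not found: ", cfg)
    cfg <- yaml::read_yaml(cfg) %||% list()
  }
  check_that(is.list(cfg), "config", "config must be a named list")
  problems <- character(0)
  if ("threshold_nm" %in% names(cfg)) {
    cfg$threshold_um <- cfg$threshold_nm / 1000
    cfg$threshold_nm <- NULL
  }
  defaults <- config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    problems <- c(problems, paste0("unknown key(s): ",
                                   paste(unknown, collapse = ", ")))
  }
  known <- cfg[setdiff(names(cfg), unknown)]
  # inputs is a positional list: merge it whole (modifyList drops unnamed
  # elements)
  out <- utils::modifyList(defaults,
                           known[setdiff(names(known), "inputs")])
  if (!is.null(known$inputs)) out$inputs <- known$inputs
  num_pos <- c("k_sd", "threshold_um", "depth_of_field_um", "pixel_size_um",
               "z_step_um")
  for (k in num_pos) {
    if (!is.numeric(out[[k]]) || length(out[[k]]) != 1 || out[[k]] <= 0) {
      problems <- c(problems, paste0(k, " must be a positive scalar"))
    }
  }
  for (k in c("baseline_n", "consecutive", "min_area_px", "min_component_px",
              "min_branch_px")) {
    if (!is.numeric(out[[k]]) || out[[k]] < 1) {
      problems <- c(problems, paste0(k, " must be >= 1"))
    }
  }
  if (!is.numeric(out$band_hz) || length(out$band_hz) != 2 ||
      out$band_hz[1] >= out$band_hz[2]) {
    problems <- c(problems, "band_hz must be (lower, upper), lower < upper")
  }
  if (out$bandpass_low_px >= out$bandpass_high_px) {
    problems <- c(problems, "bandpass_low_px must be < bandpass_high_px")
  }
  roles <- c("timesweep", "freqsweep", "network_stack", "coloc_stack")
  for (i in seq_along(out$inputs)) {
    inp <- out$inputs[[i]]
    if (is.null(inp$path) || is.null(inp$role)) {
      problems <- c(problems, paste0("input ", i, ": needs path and role"))
      next
    }
    if (!inp$role %in% roles) {
      problems <- c(problems, paste0("input ", i, ": unknown role '",
                                     inp$role, "'"))
    }
    probe <- if (grepl("stack$", inp$role %||% "")) paste0(inp$path, ".yaml")
      else inp$path
    if (!file.exists(probe)) {
      problems <- c(problems, paste0("input ", i, ": file not found: ", probe))
    }
  }
  if (length(problems)) {
    stop_fk("config", "invalid configuration:\n  - ",
            paste(problems, collapse = "\n  - "))
  }
  structure(out, class = "run_config")
}

#' Write a run configuration to YAML
#'
#' @param cfg A `run_config` (or plain list).
#' @param path Output path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

run_one_input <- function(inp, cfg) {
  switch(inp$role,
    timesweep = {
      sw <- read_time_sweep(inp$path)
      kin <- analyze_gelation(sw, baseline_n = cfg$baseline_n, k_sd = cfg$k_sd,
                              consecutive = cfg$consecutive)
      data.frame(metric = c("nucleation_end_t_s", "peak_rate_pa_s",
                            "peak_t_s", "plateau_start_t_s"),
                 value = c(kin$nucleation_end_t, kin$peak_rate, kin$peak_t,
                           kin$plateau_start_t))
    },
    freqsweep = {
      fs <- read_frequency_sweep(inp$path)
      em <- endpoint_moduli(fs, band = cfg$band_hz)
      data.frame(metric = c("gprime_end_pa", "gdoubleprime_end_pa"),
                 value = c(em$gprime_end, em$gdoubleprime_end))
    },
    network_stack = {
      st <- read_stack(inp$path)
      nm <- analyze_network(st, low_px = cfg$bandpass_low_px,
                            high_px = cfg$bandpass_high_px,
                            bandpass = cfg$bandpass,
                            method = cfg$threshold_method,
                            min_component_px = cfg$min_component_px,
                            min_branch_px = cfg$min_branch_px)
      data.frame(metric = c("fibril_content", "mesh_size_um",
                            "junctions_per_fibril", "mean_branch_length_um"),
                 value = c(nm$fibril_content, nm$mesh_size_um,
                           nm$junctions_per_fibril,
                           nm$mean_branch_length_um))
    },
    coloc_stack = {
      st <- read_stack(inp$path)
      cr <- coloc_report(st, threshold_um = cfg$threshold_um,
                         bandpass = cfg$bandpass,
                         low_px = cfg$bandpass_low_px,
                         high_px = cfg$bandpass_high_px,
                         method = cfg$threshold_method,
                         min_area_px = cfg$min_area_px)
      fin <- is.finite(cr$distances_um)
      data.frame(metric = c("n_particles", "mean_fibril_distance_um",
                            "frac_fibril_associated",
                            "frac_junction_associated", "n_unreachable"),
                 value = c(cr$n_particles, mean(cr$distances_um[fin]),
                           cr$frac_fibril_associated,
                           cr$frac_junction_associated, cr$n_unreachable))
    },
    stop_fk("pipeline", "unknown role: ", inp$role)
  )
}

#' Run a validated configuration over its input manifest
#'
#' Executes the stage matching each input's role, collecting one tidy row
#' per (input, metric). Failures are isolated per input and reported in
#' `failures`; the run aborts only when every input fails.
#'
#' @param cfg A `run_config` from [validate_config()].
#' @return List with `results` (data frame: `input`, `role`, `metric`,
#'   `value`), `failures` (named character), and `provenance` (config and
#'   input hashes, seed, package version).
#' @export
run_batch <- function(cfg) {
  check_that(inherits(cfg, "run_config"), "pipeline",
             "cfg must come from validate_config()")
  check_that(length(cfg$inputs) > 0, "pipeline", "no inputs in config")
  rows <- list()
  failures <- character(0)
  for (i in seq_along(cfg$inputs)) {
    inp <- cfg$inputs[[i]]
    res <- tryCatch(run_one_input(inp, cfg), error = function(e) e)
    if (inherits(res, "error")) {
      failures[inp$path] <- conditionMessage(res)
    } else {
      rows[[length(rows) + 1]] <-
        cbind(data.frame(input = inp$path, role = inp$role), res)
    }
  }
  if (length(rows) == 0) {
    stop_fk("pipeline", "all inputs failed:\n  ",
            paste(names(failures), failures, sep = ": ", collapse = "\n  "))
  }
  input_files <- vapply(cfg$inputs, function(inp) {
    if (grepl("stack$", inp$role)) paste0(inp$path, ".yaml") else inp$path
  }, "")
  list(
    results = do.call(rbind, rows),
    failures = failures,
    provenance = list(
      config_hash = hash_object(unclass(cfg)),
      input_hashes = stats::setNames(unname(tools::md5sum(input_files)),
                                     input_files),
      seed = cfg$seed,
      package_version = as.character(utils::packageVersion("fibrilkit")),
      timestamp = format(Sys.time(), tz = "UTC")
    )
  )
}
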