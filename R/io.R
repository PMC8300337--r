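# Dataset I/O (NONMEM-style CSV dialect), pipeline configuration, and the
# end-to-end pipeline.
#
# Dataset dialect: CSV with header ID,TIME,EVID,AMT,DV,MATRIX,VALID.
# EVID 1 = dose (AMT set, DV empty); EVID 0 = observation (DV set, AMT
# empty). TIME in decimal hours from the first dose; MATRIX in
# {serum, urine, synovial, endometrium}; VALID in {0, 1}. Unknown extra
# columns are ignored with a warning.

.DIALECT_COLS <- c("ID", "TIME", "EVID", "AMT", "DV", "MATRIX", "VALID")

#' Read a dataset
#'
#' Parses the package's NONMEM-style CSV dialect and validates it, reporting
#' the offending row numbers (of the data portion of the file) on failure.
#'
#' @param path Path to a CSV file.
#' @return A validated `pk_dataset`.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("read_dataset: no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.DIALECT_COLS, names(raw))
  if (length(missing_cols)) {
    stop("read_dataset: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(raw), .DIALECT_COLS)
  if (length(extra)) {
    warning("read_dataset: ignoring unknown column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  d <- .new_dataset(ID = raw$ID, TIME = as.numeric(raw$TIME),
                    EVID = as.integer(raw$EVID), AMT = as.numeric(raw$AMT),
                    DV = as.numeric(raw$DV), MATRIX = as.character(raw$MATRIX),
                    VALID = as.integer(raw$VALID))
  validate_dataset(d)
}

#' Validate a dataset
#'
#' Checks the dataset invariants: known matrix labels, EVID in {0, 1}, VALID
#' in {0, 1}, non-negative times and concentrations, and mutually exclusive
#' AMT/DV fields. Violations are reported with their row numbers.
#'
#' @param dataset A data frame in the dataset dialect.
#' @return The dataset, invisibly classed as `pk_dataset`.
#' @export
validate_dataset <- function(dataset) {
  .fail <- function(rows, what) {
    stop(sprintf("dataset validation: %s (row%s %s)", what,
                 if (length(rows) > 1L) "s" else "",
                 paste(rows, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!dataset$MATRIX %in% .MATRICES)
  if (length(bad)) .fail(bad, "unknown matrix label")
  bad <- which(!dataset$EVID %in% c(0L, 1L))
  if (length(bad)) .fail(bad, "EVID must be 0 or 1")
  bad <- which(!dataset$VALID %in% c(0L, 1L))
  if (length(bad)) .fail(bad, "VALID must be 0 or 1")
  bad <- which(!is.finite(dataset$TIME) | dataset$TIME < 0)
  if (length(bad)) .fail(bad, "TIME must be finite and >= 0")
  obs <- dataset$EVID == 0L
  bad <- which(obs & (is.na(dataset$DV) | dataset$DV < 0))
  if (length(bad)) .fail(bad, "observation rows must have DV >= 0")
  bad <- which(obs & !is.na(dataset$AMT))
  if (length(bad)) .fail(bad, "observation rows must have empty AMT")
  dose <- dataset$EVID == 1L
  bad <- which(dose & !is.na(dataset$DV))
  if (length(bad)) .fail(bad, "dose rows must have empty DV (AMT and DV are mutually exclusive)")
  bad <- which(dose & (is.na(dataset$AMT) | dataset$AMT <= 0))
  if (length(bad)) .fail(bad, "dose rows must have AMT > 0")
  class(dataset) <- c("pk_dataset", "data.frame")
  invisible(dataset)
}

#' Write a dataset
#'
#' Writes the dataset in the package dialect with deterministic column and
#' row order (subject, time, record kind); invalid rows are retained with
#' their flag. Two writes of the same dataset are byte-identical.
#'
#' @param dataset A `pk_dataset`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  validate_dataset(dataset)
  out <- .order_dataset(as.data.frame(dataset)[, .DIALECT_COLS, drop = FALSE])
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("write_dataset: cannot write to ", path, call. = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' The full default configuration of [run_pipeline()], as a nested list with
#' blocks `design`, `model`, `saem`, `diagnostics` and `output`. Every seed
#' is an explicit integer.
#'
#' @return A nested list.
#' @export
default_config <- function() {
  list(
    design = list(n_subjects = 8L, dose_amount = 10, dose_times = c(0, 12, 24, 36, 48),
                  serum_times = c(0, 0.25, 0.5, 1, 2, 6, 12, 18, 24, 24.5, 28, 30,
                                  36, 36.5, 42, 48, 48.5, 54, 60, 72),
                  urine_times = c(0, 24, 36, 48, 60),
                  synovial_times = c(0, 24, 36, 48, 60),
                  endometrium_times = c(51, 60, 72),
                  dropout = list(serum = 11L, urine = 2L, synovial = 1L, endometrium = 0L)),
    simulate = list(enabled = TRUE, seed = 20211L,
                    truth = list(theta = list(ka = 10.3, v = 108, kel = 0.0253),
                                 omega = list(ka = 2.56, v = 0.877, kel = 0),
                                 error = list(kind = "combined", a = 0.01, b = 0.18)),
                    tissue = list(urine = 0.6, synovial = 0.3, endometrium = 0.65)),
    data = NULL,  # path to an existing dataset when simulate$enabled is FALSE
    model = list(error = list(kind = "combined", a = 0.01, b = 0.2),
                 iiv = list(ka = TRUE, v = TRUE, kel = FALSE),
                 init = NULL),  # NULL = data-derived initial values
    saem = list(n_exploratory = 1000L, n_smoothing = 200L, n_chains = 1L,
                mh_steps_per_iteration = 5L, seed = 42L),
    diagnostics = list(n_sim = 500L, percentiles = c(5, 50, 95), seed = 43L),
    posthoc = list(n = 500L, seed = 44L),
    output = list(dir = "doxypk-output")
  )
}

.read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON file path", call. = FALSE)
  utils::modifyList(default_config(), config)
}

.design_from_config <- function(cfg) {
  d <- cfg$design
  study_design(n_subjects = d$n_subjects, dose_amount = d$dose_amount,
               dose_times = unlist(d$dose_times), serum_times = unlist(d$serum_times),
               urine_times = unlist(d$urine_times), synovial_times = unlist(d$synovial_times),
               endometrium_times = unlist(d$endometrium_times),
               dropout = unlist(d$dropout))
}

.pop_from_config <- function(block) {
  err <- error_model(block$error$kind, a = block$error$a, b = block$error$b)
  population_model(theta = unlist(block$theta), omega = unlist(block$omega),
                   error = err)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> fit -> diagnostics -> post-hoc ->
#' summaries and writes all result tables to the output directory:
#' the dataset, the population estimates with RSEs, iteration traces, the
#' goodness-of-fit table (observed/predicted/IWRES/NPDE), prediction bands,
#' individual estimates with their five-number summary, per-matrix
#' concentration summaries, and a run log recording seeds, versions and
#' stage timings. A failing stage aborts with the stage name; outputs of
#' completed stages persist.
#'
#' @param config A nested configuration list (see [default_config()]) or the
#'   path to a YAML/JSON file with the same structure.
#' @param out_dir Output directory override (defaults to
#'   `config$output$dir`).
#' @return Invisibly, a list with the fit, the dataset, the diagnostics
#'   tables and the output paths.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  cfg <- .read_config(config)
  dir_out <- if (!is.null(out_dir)) out_dir else cfg$output$dir
  dir.create(dir_out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(dir_out, "run_log.txt")
  cat(sprintf("doxypk %s | R %s | started %s\n",
              as.character(utils::packageVersion("doxypk")),
              paste(R.version$major, R.version$minor, sep = "."),
              format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      file = log_path)
  .log <- function(...) cat(sprintf(...), "\n", file = log_path, append = TRUE, sep = "")
  .stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      .log("stage %s FAILED: %s", name, conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    .log("stage %s done in %.1f s", name, proc.time()[["elapsed"]] - t0)
    res
  }

  design <- .design_from_config(cfg)
  dataset <- .stage("simulate", {
    if (isTRUE(cfg$simulate$enabled)) {
      .log("simulate seed = %d", as.integer(cfg$simulate$seed))
      truth <- .pop_from_config(cfg$simulate$truth)
      d <- generate_study(design, truth, seed = cfg$simulate$seed)
      d <- generate_tissue_records(d, partition = unlist(cfg$simulate$tissue),
                                   design = design, seed = cfg$simulate$seed + 1L)
      d <- apply_missingness(d, design, seed = cfg$simulate$seed + 2L)
      write_dataset(d, file.path(dir_out, "dataset.csv"))
      truth_tab <- data.frame(parameter = names(truth$theta),
                              theta = as.numeric(truth$theta),
                              omega = as.numeric(truth$omega))
      utils::write.csv(truth_tab, file.path(dir_out, "truth_parameters.csv"),
                       row.names = FALSE)
      d
    } else {
      if (is.null(cfg$data)) stop("no data path configured and simulation disabled")
      read_dataset(cfg$data)
    }
  })

  fit <- .stage("fit", {
    .log("saem seed = %d", as.integer(cfg$saem$seed))
    settings <- saem_settings(n_exploratory = cfg$saem$n_exploratory,
                              n_smoothing = cfg$saem$n_smoothing,
                              n_chains = cfg$saem$n_chains,
                              mh_steps_per_iteration = cfg$saem$mh_steps_per_iteration,
                              seed = cfg$saem$seed)
    pop0 <- if (!is.null(cfg$model$init)) .pop_from_config(cfg$model$init) else NULL
    f <- fit_saem(dataset, pop0 = pop0, settings = settings)
    est <- data.frame(parameter = names(f$pop_hat$theta),
                      estimate = as.numeric(f$pop_hat$theta),
                      rse_percent = if (!is.null(f$rse)) as.numeric(f$rse) else NA_real_,
                      omega = as.numeric(f$pop_hat$omega))
    utils::write.csv(est, file.path(dir_out, "estimates.csv"), row.names = FALSE)
    utils::write.csv(f$traces, file.path(dir_out, "traces.csv"), row.names = FALSE)
    .log("loglik = %.3f, BIC = %.3f, converged = %s", f$loglik, f$bic, f$converged)
    f
  })

  gof <- .stage("diagnostics", {
    .log("diagnostics seed = %d, n_sim = %d", as.integer(cfg$diagnostics$seed),
         as.integer(cfg$diagnostics$n_sim))
    ovp <- observed_vs_predicted(fit, dataset, seed = cfg$diagnostics$seed)
    iw <- iwres(fit, dataset, seed = cfg$diagnostics$seed)
    np <- npde(fit, dataset, n_sim = cfg$diagnostics$n_sim,
               seed = cfg$diagnostics$seed)
    gof <- data.frame(ovp, iwres = iw$iwres, npde = np$npde)
    utils::write.csv(gof, file.path(dir_out, "gof.csv"), row.names = FALSE)
    regimen <- dosing_regimen(design$dose_times, design$dose_amount)
    bands <- prediction_bands(fit, regimen, grid = design$times$serum,
                              n_sim = cfg$diagnostics$n_sim,
                              percentiles = cfg$diagnostics$percentiles,
                              seed = cfg$diagnostics$seed + 1L)
    utils::write.csv(bands, file.path(dir_out, "prediction_bands.csv"),
                     row.names = FALSE)
    list(gof = gof, bands = bands)
  })

  indiv <- .stage("posthoc", {
    .log("posthoc seed = %d", as.integer(cfg$posthoc$seed))
    est <- individual_estimates(fit, dataset, n = cfg$posthoc$n,
                                seed = cfg$posthoc$seed)
    utils::write.csv(est, file.path(dir_out, "individual_estimates.csv"),
                     row.names = FALSE)
    fns <- five_number_summary(est)
    utils::write.csv(fns, file.path(dir_out, "individual_summary.csv"),
                     row.names = FALSE)
    list(estimates = est, summary = fns)
  })

  .stage("summaries", {
    for (m in .MATRICES) {
      if (!any(dataset$MATRIX == m & dataset$EVID == 0L)) next
      utils::write.csv(mean_profile(dataset, m),
                       file.path(dir_out, paste0("summary_", m, ".csv")),
                       row.names = FALSE)
    }
    invisible(NULL)
  })
  .log("pipeline complete")

  invisible(list(fit = fit, dataset = dataset, diagnostics = gof,
                 posthoc = indiv, out_dir = dir_out))
}
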