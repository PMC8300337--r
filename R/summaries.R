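# Descriptive, non-compartmental-style summaries: per-interval Cmax and
# per-matrix concentration profiles by nominal time. These summarize the
# observed records (protocol times), not model predictions. Endometrium
# values are ug of drug per biopsy, not concentrations (biopsies were not
# weighed).

#' Per-subject Cmax within a dosing interval
#'
#' Maximum observed serum concentration per subject at nominal times within
#' `[dose_i, dose_(i+1))`; the last interval extends to the last sample.
#' Subjects with no valid samples in the interval are excluded and counted.
#'
#' @param dataset A `pk_dataset`.
#' @param regimen A [dosing_regimen()] defining the intervals.
#' @param interval_index Which dosing interval (1 = after the first dose).
#' @return A list with `per_subject` (data frame `ID, cmax, tmax_obs`),
#'   pooled `mean`, `sd`, `median`, `range`, and `n_excluded`.
#' @examples
#' d <- generate_study(seed = 1)
#' cmax_by_interval(d, dosing_regimen(c(0, 12, 24, 36, 48), 10), 1)$mean
#' @export
cmax_by_interval <- function(dataset, regimen, interval_index) {
  stopifnot(inherits(regimen, "dosing_regimen"))
  nd <- nrow(regimen)
  if (interval_index < 1L || interval_index > nd) {
    stop(sprintf("cmax_by_interval: interval_index must be in 1..%d", nd), call. = FALSE)
  }
  obs <- dataset[dataset$EVID == 0L & dataset$MATRIX == "serum" &
                   dataset$VALID == 1L, , drop = FALSE]
  lo <- regimen$time[interval_index]
  hi <- if (interval_index < nd) regimen$time[interval_index + 1L] else Inf
  inside <- if (is.finite(hi)) obs$TIME >= lo & obs$TIME < hi else obs$TIME >= lo
  obs <- obs[inside, , drop = FALSE]
  ids <- unique(dataset$ID)
  with_data <- intersect(ids, unique(obs$ID))
  per_subject <- do.call(rbind, lapply(with_data, function(id) {
    oi <- obs[obs$ID == id, , drop = FALSE]
    top <- which.max(oi$DV)
    data.frame(ID = id, cmax = oi$DV[top], tmax_obs = oi$TIME[top])
  }))
  cm <- per_subject$cmax
  list(per_subject = per_subject,
       mean = mean(cm),
       sd = if (length(cm) > 1L) stats::sd(cm) else 0,
       median = stats::median(cm),
       range = range(cm),
       n_excluded = length(ids) - length(with_data))
}

#' Concentration summary by nominal time for one matrix
#'
#' Groups the valid observation records of one sample matrix by nominal time
#' and reports n, mean, SD, median, min and max. Records flagged invalid
#' never contribute; cells with a single record report SD 0 with n = 1.
#' Missing (all-invalid) cells are reported with n = 0, never imputed.
#'
#' @param dataset A `pk_dataset`.
#' @param matrix One of `"serum"`, `"urine"`, `"synovial"`, `"endometrium"`.
#' @return A data frame of class `profile_summary` with columns
#'   `matrix, time, n, mean, sd, median, min, max` (ug/mL; endometrium in ug
#'   per biopsy).
#' @export
mean_profile <- function(dataset, matrix = "serum") {
  if (!matrix %in% .MATRICES) {
    stop("mean_profile: unknown matrix '", matrix, "'; expected one of ",
         paste(.MATRICES, collapse = ", "), call. = FALSE)
  }
  all_obs <- dataset[dataset$EVID == 0L & dataset$MATRIX == matrix, , drop = FALSE]
  obs <- all_obs[all_obs$VALID == 1L, , drop = FALSE]
  times <- sort(unique(all_obs$TIME))
  rows <- lapply(times, function(tm) {
    v <- obs$DV[obs$TIME == tm]
    if (length(v) == 0L) {
      data.frame(matrix = matrix, time = tm, n = 0L, mean = NA_real_,
                 sd = NA_real_, median = NA_real_, min = NA_real_, max = NA_real_)
    } else {
      data.frame(matrix = matrix, time = tm, n = length(v), mean = mean(v),
                 sd = if (length(v) > 1L) stats::sd(v) else 0,
                 median = stats::median(v), min = min(v), max = max(v))
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("profile_summary", "data.frame")
  out
}

#' Time of the maximum mean concentration
#'
#' The nominal time with the largest mean in a [mean_profile()] summary,
#' with ties broken toward the earliest time.
#'
#' @param summary A `profile_summary`.
#' @return A list with `time`, `mean` and `sd` at that time.
#' @export
max_mean_time <- function(summary) {
  if (NROW(summary) == 0L) stop("max_mean_time: empty summary", call. = FALSE)
  ok <- summary[!is.na(summary$mean), , drop = FALSE]
  if (NROW(ok) == 0L) stop("max_mean_time: no summarized cells", call. = FALSE)
  ok <- ok[order(ok$time), , drop = FALSE]
  top <- which.max(ok$mean)  # first maximum = earliest time on ties
  list(time = ok$time[top], mean = ok$mean[top], sd = ok$sd[top])
}
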