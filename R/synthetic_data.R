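#' Assay time-course dataset
#'
#' Summary-form container for an LDH/ALP time course: per measurement day
#' the mean and SD of the total cell count and of the total ALP activity
#' over replicate samples, for one experimental condition.
#'
#' @param condition Condition label, e.g. `"control"`, `"stimulated"`, or
#'   `"synthetic:<label>"`.
#' @param days Strictly increasing measurement days.
#' @param cell_count_mean,cell_count_sd Per-day cell-count summaries
#'   (cells); SDs may be `NA` when unknown (weighted fits then refuse).
#' @param alp_mean,alp_sd Per-day total-ALP summaries (activity units).
#' @param n_replicates Replicate samples per time point.
#' @return A data frame of class `assay_dataset` with columns `condition`,
#'   `day`, `cell_count_mean`, `cell_count_sd`, `alp_mean`, `alp_sd`, `n`.
#' @export
assay_dataset <- function(condition, days, cell_count_mean, cell_count_sd,
                          alp_mean, alp_sd, n_replicates) {
  days <- as.numeric(days)
  if (length(days) == 0L) stop("`days` must be non-empty", call. = FALSE)
  if (any(diff(days) <= 0)) {
    stop("`days` must be strictly increasing (offending rows: ",
         paste(which(diff(days) <= 0) + 1L, collapse = ", "), ")", call. = FALSE)
  }
  len <- length(days)
  for (nm in c("cell_count_mean", "cell_count_sd", "alp_mean", "alp_sd")) {
    v <- get(nm)
    if (length(v) == 1L) assign(nm, rep(v, len))
    else if (length(v) != len) {
      stop("`", nm, "` must match `days` in length", call. = FALSE)
    }
  }
  if (any(cell_count_mean < 0, na.rm = TRUE) || any(alp_mean < 0, na.rm = TRUE)) {
    stop("means must be non-negative", call. = FALSE)
  }
  for (nm in c("cell_count_sd", "alp_sd")) {
    v <- get(nm)
    if (any(v < 0, na.rm = TRUE)) {
      stop("negative SD in `", nm, "` (offending rows: ",
           paste(which(v < 0), collapse = ", "), ")", call. = FALSE)
    }
  }
  structure(data.frame(
    condition = as.character(condition),
    day = days,
    cell_count_mean = as.numeric(cell_count_mean),
    cell_count_sd = as.numeric(cell_count_sd),
    alp_mean = as.numeric(alp_mean),
    alp_sd = as.numeric(alp_sd),
    n = as.integer(n_replicates)
  ), class = c("assay_dataset", "data.frame"))
}

# closed-form mean curves of a truth model at the given days
truth_moments <- function(truth, days) {
  if (inherits(truth, "pscd_params")) {
    list(N = pscd_total_cells(days, truth), Phi = pscd_total_alp(days, truth))
  } else if (inherits(truth, "iscd_params")) {
    m <- iscd_moments(days, truth)
    list(N = m$N, Phi = m$Phi)
  } else {
    stop("`truth` must be pscd_params or iscd_params", call. = FALSE)
  }
}

# Normal(mean, sd) truncated at zero, by rejection; exact for sd = 0.
rnorm_trunc0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic assay time course
#'
#' Draws replicate observations around the truth model's closed-form mean
#' curves: per day `d`, `n_samples` cell counts from
#' `Normal(N(d), cv_count * N(d))` and ALP activities from
#' `Normal(Phi(d), cv_alp * Phi(d))`, both truncated at zero, then stores
#' the per-day mean and SD.  This emulates the study design of 4 scaffold
#' samples per condition measured on days 7, 14, 21 and 28 (each sample
#' value itself a collapsed triplicate measurement).  Deterministic given
#' `seed`.
#'
#' @param truth A [pscd_params()] or [iscd_params()] with the amplitude
#'   fields set.
#' @param days Measurement days, all `> 0`; default `c(7, 14, 21, 28)`.
#' @param n_samples Replicates per day (default 4).
#' @param cv_count,cv_alp Coefficients of variation of the measurement
#'   noise (defaults 0.10 and 0.05).
#' @param seed Integer RNG seed.
#' @param condition Condition label; default `"synthetic:pscd"` /
#'   `"synthetic:iscd"` by truth class.
#' @return An [assay_dataset()]; the replicate-level draws are attached as
#'   attribute `"replicates"` (long-form data frame).
#' @export
generate_assay_dataset <- function(truth, days = c(7, 14, 21, 28),
                                   n_samples = 4, cv_count = 0.10,
                                   cv_alp = 0.05, seed = 1,
                                   condition = NULL) {
  if (length(days) == 0L) stop("`days` must be non-empty", call. = FALSE)
  if (any(days <= 0)) stop("`days` must be positive", call. = FALSE)
  if (cv_count < 0 || cv_alp < 0) stop("CVs must be >= 0", call. = FALSE)
  if (n_samples < 1) stop("`n_samples` must be >= 1", call. = FALSE)
  condition <- condition %||%
    paste0("synthetic:", if (inherits(truth, "pscd_params")) "pscd" else "iscd")
  mu <- truth_moments(truth, days)
  set.seed(as.integer(seed))
  long <- do.call(rbind, lapply(seq_along(days), function(i) {
    counts <- rnorm_trunc0(n_samples, mu$N[i], cv_count * mu$N[i])
    alps <- rnorm_trunc0(n_samples, mu$Phi[i], cv_alp * mu$Phi[i])
    data.frame(condition = condition, day = days[i],
               replicate = seq_len(n_samples),
               cell_count = counts, alp_activity = alps)
  }))
  agg <- function(v) {
    m <- tapply(v, long$day, mean)
    s <- tapply(v, long$day, stats::sd)
    if (n_samples == 1L) s[] <- 0
    list(mean = as.numeric(m), sd = as.numeric(s))
  }
  cc <- agg(long$cell_count); al <- agg(long$alp_activity)
  out <- assay_dataset(condition, days, cc$mean, cc$sd, al$mean, al$sd, n_samples)
  attr(out, "replicates") <- long
  out
}

#' Generate a matched control / stimulated dataset pair
#'
#' Convenience generator reproducing the qualitative picture of the
#' electrical-stimulation assay: both conditions share the cell-count
#' amplitude `N_bar0 = 535` cells/day^2 (counts indistinguishable between
#' conditions), while the ALP curves differ — control
#' `Phi0 = 0.8007`, `1/d0 = 5.84` days versus stimulated `Phi0 = 0.84`,
#' `1/d0 = 6.2` days (initial-time values at the reference day `t0`),
#' giving the stimulated culture a slightly higher ALP curve with a later
#' peak (12.4 vs 11.68 days).
#'
#' @param seed Integer seed (`seed` and `seed + 1` drive the two
#'   conditions).
#' @param t0 Reference day for the initial-time parameterization
#'   (default 7).
#' @param days,n_samples,cv_count,cv_alp Passed to
#'   [generate_assay_dataset()].
#' @return A list with elements `control` and `stimulated`
#'   ([assay_dataset()]s) and `truth` (the two [pscd_params()]).
#' @export
generate_paperlike_pair <- function(seed = 1, t0 = 7, days = c(7, 14, 21, 28),
                                    n_samples = 4, cv_count = 0.10,
                                    cv_alp = 0.05) {
  p_control <- convert_params(
    pscd_params(d0 = 1 / 5.84, N0 = 535 * t0^2, Phi0 = 0.8007, t0 = t0),
    "to_amplitude")
  p_stim <- convert_params(
    pscd_params(d0 = 1 / 6.2, N0 = 535 * t0^2, Phi0 = 0.84, t0 = t0),
    "to_amplitude")
  control <- generate_assay_dataset(p_control, days, n_samples, cv_count,
                                    cv_alp, seed = seed, condition = "control")
  stimulated <- generate_assay_dataset(p_stim, days, n_samples, cv_count,
                                       cv_alp, seed = as.integer(seed) + 1L,
                                       condition = "stimulated")
  list(control = control, stimulated = stimulated,
       truth = list(control = p_control, stimulated = p_stim))
}

assay_cols_summary <- c("condition", "day", "cell_count_mean", "cell_count_sd",
                        "alp_mean", "alp_sd", "n")
assay_cols_long <- c("condition", "day", "replicate", "cell_count", "alp_activity")

#' Read / write assay datasets as CSV
#'
#' `write_assay_csv()` writes the summary form (columns `condition`,
#' `day`, `cell_count_mean`, `cell_count_sd`, `alp_mean`, `alp_sd`, `n`).
#' `read_assay_csv()` accepts the summary form or the long form
#' (`condition`, `day`, `replicate`, `cell_count`, `alp_activity`), which
#' is summarized on read.  A summary file without SD columns is accepted
#' with `NA` SDs (weighted fits will then refuse with a clear error).
#' The round trip `read(write(x))` is lossless for all summary fields.
#'
#' @param data An [assay_dataset()] or a list of them (multi-condition
#'   file).
#' @param path File path.
#' @return `write_assay_csv()`: the path, invisibly.  `read_assay_csv()`:
#'   an [assay_dataset()], or a named list of them if the file holds
#'   several conditions.
#' @export
write_assay_csv <- function(data, path) {
  if (inherits(data, "assay_dataset")) data <- list(data)
  df <- do.call(rbind, lapply(data, as.data.frame))
  utils::write.csv(df[, assay_cols_summary], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assay_csv
#' @export
read_assay_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(assay_cols_long %in% names(df))) {
    df <- summarize_long_assay(df)
  } else {
    need <- c("condition", "day", "cell_count_mean", "alp_mean")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop("missing required columns: ", paste(miss, collapse = ", "), call. = FALSE)
    }
    if (!"cell_count_sd" %in% names(df)) df$cell_count_sd <- NA_real_
    if (!"alp_sd" %in% names(df)) df$alp_sd <- NA_real_
    if (!"n" %in% names(df)) df$n <- NA_integer_
  }
  for (nm in c("cell_count_sd", "alp_sd")) {
    bad <- which(!is.na(df[[nm]]) & df[[nm]] < 0)
    if (length(bad)) {
      stop("negative SD in `", nm, "` at rows ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  split_df <- split(df, df$condition)
  out <- lapply(split_df, function(d) {
    ord <- order(d$day)
    if (any(diff(d$day[ord]) <= 0)) {
      dup <- which(diff(d$day[ord]) <= 0)
      stop("non-increasing / duplicated days for condition '", d$condition[1],
           "' at rows ", paste(rownames(d)[ord][dup + 1L], collapse = ", "),
           call. = FALSE)
    }
    d <- d[ord, ]
    assay_dataset(d$condition[1], d$day, d$cell_count_mean, d$cell_count_sd,
                  d$alp_mean, d$alp_sd, d$n)
  })
  if (length(out) == 1L) out[[1]] else out
}

summarize_long_assay <- function(long) {
  key <- interaction(long$condition, long$day, drop = TRUE)
  agg <- function(v, f) as.numeric(tapply(v, key, f))
  first <- function(x) x[1]
  cond <- as.character(tapply(long$condition, key, first))
  data.frame(
    condition = cond,
    day = agg(long$day, first),
    cell_count_mean = agg(long$cell_count, mean),
    cell_count_sd = agg(long$cell_count, stats::sd),
    alp_mean = agg(long$alp_activity, mean),
    alp_sd = agg(long$alp_activity, stats::sd),
    n = agg(long$replicate, length)
  )
}
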