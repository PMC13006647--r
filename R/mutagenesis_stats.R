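# Mutation statistics: stationary-phase mutagenesis (SPM) cumulative
# revertant-frequency curves and fold changes, and Luria-Delbruck
# fluctuation-test mutation-rate estimation by the Lea-Coulson method of
# the median (r/m - ln m = 1.24).

#' Stationary-phase mutagenesis time series
#'
#' @param strain_id Strain label.
#' @param day Integer days (>= 1, strictly increasing).
#' @param new_revertants New revertant colonies scored on each day
#'   (non-negative).
#' @param cfu_plated Initial CFU plated (> 0, scalar).
#' @param viability Optional per-day background CFU (reported alongside;
#'   never used to rescale the frequency curve, which is normalized to
#'   initial CFU plated only).
#' @return Object of class `spm_series`.
#' @export
spm_series <- function(strain_id, day, new_revertants, cfu_plated,
                       viability = NULL) {
  day <- as.integer(day)
  stopifnot(length(day) == length(new_revertants), length(day) >= 1L)
  if (any(diff(day) <= 0L)) stop("days must be strictly increasing")
  if (any(new_revertants < 0)) stop("revertant counts must be non-negative")
  if (length(cfu_plated) != 1L || cfu_plated <= 0) {
    stop("cfu_plated must be a single positive count")
  }
  if (!is.null(viability)) stopifnot(length(viability) == length(day))
  structure(list(strain_id = strain_id, day = day,
                 new_revertants = as.numeric(new_revertants),
                 cfu_plated = as.numeric(cfu_plated), viability = viability),
            class = "spm_series")
}

#' Cumulative revertant frequency per day
#'
#' Day-d value: (sum of new revertants through day d) / CFU plated.
#' Monotone non-decreasing by construction.
#'
#' @param series `spm_series`.
#' @return data.frame `day`, `cumulative_revertants`, `frequency`.
#' @export
cumulative_frequency <- function(series) {
  stopifnot(inherits(series, "spm_series"))
  cum <- cumsum(series$new_revertants)
  data.frame(day = series$day, cumulative_revertants = cum,
             frequency = cum / series$cfu_plated)
}

#' Fold change in cumulative revertant frequency between two strains
#'
#' @param a,b `spm_series` (numerator / denominator).
#' @param day Day at which to compare; default, the last day covered by
#'   both series.
#' @return Ratio of cumulative frequencies at that day. A zero
#'   denominator returns `NA_real_` with a warning (undefined, not
#'   infinite).
#' @export
fold_change <- function(a, b, day = NULL) {
  fa <- cumulative_frequency(a)
  fb <- cumulative_frequency(b)
  if (is.null(day)) {
    common <- intersect(fa$day, fb$day)
    if (length(common) == 0L) stop("series share no day")
    day <- max(common)
  }
  if (!day %in% fa$day || !day %in% fb$day) {
    stop("day ", day, " not covered by both series")
  }
  num <- fa$frequency[fa$day == day]
  den <- fb$frequency[fb$day == day]
  if (den == 0) {
    warning("fold_change undefined: zero denominator frequency at day ", day)
    return(NA_real_)
  }
  num / den
}

#' Interpolated (order-statistic) median
#'
#' Standard median; for even n the mean of the two central order
#' statistics (half-integers permitted).
#'
#' @param counts Nonempty numeric vector.
#' @return The median.
#' @export
median_interpolated <- function(counts) {
  if (length(counts) == 0L) stop("median of an empty vector")
  s <- sort(counts)
  n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) %/% 2L] else (s[n %/% 2L] + s[n %/% 2L + 1L]) / 2
}

#' Fluctuation-test dataset
#'
#' @param mutant_counts Per-culture mutant counts (one per culture).
#' @param n_final Cells per culture at plating (N_t > 0).
#' @return Object of class `fluctuation_dataset` with `mutant_counts`,
#'   `n_final`, `n_cultures`.
#' @export
fluctuation_dataset <- function(mutant_counts, n_final) {
  stopifnot(length(mutant_counts) >= 1L, all(mutant_counts >= 0),
            length(n_final) == 1L, n_final > 0)
  structure(list(mutant_counts = as.numeric(mutant_counts),
                 n_final = as.numeric(n_final),
                 n_cultures = length(mutant_counts)),
            class = "fluctuation_dataset")
}

#' Lea-Coulson method-of-the-median mutation-rate estimate
#'
#' Solves `r/m - ln(m) = 1.24` for m (expected mutations per culture),
#' where r is the interpolated median of the per-culture mutant counts,
#' by bracketed root finding on `[1e-6, 1e6]` to `|f| < 1e-9`. The rate is
#' `mu = m / N_t`, per cell per culture growth (no ln-2 per-generation
#' refinement; the simplest classical form).
#'
#' An optional leave-one-culture-out jackknife over cultures gives a
#' labeled extra confidence interval (not part of the classical method).
#'
#' @param data `fluctuation_dataset`, or a bare numeric vector of counts
#'   (then `n_final` must be given).
#' @param n_final Cells per culture at plating, if `data` is a vector.
#' @param jackknife Also compute a jackknife SE/CI over cultures?
#' @return List (class `rate_estimate`): `m`, `mu`, `r_median`,
#'   `n_cultures`, `n_final`, and (if requested) `jackknife` with `se_m`
#'   and `ci95_m`.
#' @examples
#' lea_coulson_median(fluctuation_dataset(c(0, 1, 2, 5, 30), 1e8))
#' @export
lea_coulson_median <- function(data, n_final = NULL, jackknife = FALSE) {
  if (!inherits(data, "fluctuation_dataset")) {
    if (is.null(n_final)) stop("n_final required with a bare count vector")
    data <- fluctuation_dataset(data, n_final)
  }
  r <- median_interpolated(data$mutant_counts)
  if (r <= 0) {
    stop("rate below detection for this design: median mutant count is 0")
  }
  m <- solve_lea_coulson(r)
  out <- list(m = m, mu = m / data$n_final, r_median = r,
              n_cultures = data$n_cultures, n_final = data$n_final)
  if (jackknife && data$n_cultures >= 3L) {
    mj <- vapply(seq_len(data$n_cultures), function(i) {
      ri <- median_interpolated(data$mutant_counts[-i])
      if (ri <= 0) NA_real_ else solve_lea_coulson(ri)
    }, 0)
    mj <- mj[!is.na(mj)]
    n <- length(mj)
    se <- sqrt((n - 1) / n * sum((mj - mean(mj))^2))
    out$jackknife <- list(se_m = se,
                          ci95_m = c(m - 1.96 * se, m + 1.96 * se))
  }
  structure(out, class = "rate_estimate")
}

# Root of f(m) = r/m - ln(m) - 1.24, strictly decreasing in m, on a
# bracket widened from [1e-6, 1e6] if ever needed.
solve_lea_coulson <- function(r) {
  f <- function(m) r / m - log(m) - 1.24
  lo <- 1e-6; hi <- 1e6
  while (f(lo) < 0) lo <- lo / 10
  while (f(hi) > 0) hi <- hi * 10
  root <- stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.75)$root
  # polish by bisection until |f| < 1e-9 (uniroot tol is on m, not f)
  a <- lo; b <- hi
  m <- root
  while (abs(f(m)) >= 1e-9) {
    if (f(m) > 0) a <- m else b <- m
    m <- (a + b) / 2
  }
  m
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("<rate_estimate> m = ", format(x$m, digits = 6),
      " mutations/culture (median r = ", x$r_median, ", ", x$n_cultures,
      " cultures); mu = ", format(x$mu, digits = 6),
      " per cell per culture growth\n", sep = "")
  invisible(x)
}

#' Read an SPM time-series TSV
#'
#' Columns: `strain_id`, `day`, `new_revertants`, `cfu_plated`, optional
#' `viability`. One `spm_series` per strain.
#' @param path TSV path.
#' @return Named list of `spm_series`.
#' @export
read_spm_tsv <- function(path) {
  df <- read_table_tsv(path)
  need <- c("strain_id", "day", "new_revertants", "cfu_plated")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("SPM table '", path, "' missing column(s): ",
                         paste(miss, collapse = ", "))
  out <- list()
  for (sid in unique(df$strain_id)) {
    d <- df[df$strain_id == sid, , drop = FALSE]
    d <- d[order(d$day), , drop = FALSE]
    out[[sid]] <- spm_series(sid, d$day, d$new_revertants, d$cfu_plated[1L],
                             viability = if ("viability" %in% names(d))
                               d$viability else NULL)
  }
  out
}
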