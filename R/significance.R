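#' Histogram of expression ratios
#'
#' Bins a vector of dimensionless expression ratios into fixed-width bins
#' covering the data range. Bins are left-closed, right-open intervals
#' `[lo, lo + w)`, except that the maximum value is assigned to the last
#' bin so that counts are conserved.
#'
#' @param ratios numeric vector of positive ratios.
#' @param bin_width bin width on the ratio scale (default 0.05).
#' @return An object of class `"ratio_histogram"`: a list with `breaks`,
#'   `centers`, `counts`, `bin_width` and `n`.
#' @examples
#' h <- build_ratio_histogram(c(1.0, 1.0, 1.1), bin_width = 0.1)
#' h$counts
#' @export
build_ratio_histogram <- function(ratios, bin_width = 0.05) {
  stopifnot(is.numeric(ratios), length(ratios) > 0L, bin_width > 0)
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) == 0L) stop("no finite ratios to bin")
  lo <- floor(min(ratios) / bin_width) * bin_width
  n_bins <- max(1L, ceiling((max(ratios) - lo) / bin_width))
  # a value exactly on the top break falls in the last bin
  idx <- pmin(floor((ratios - lo) / bin_width) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(
    breaks    = lo + bin_width * (0:n_bins),
    centers   = lo + bin_width * (seq_len(n_bins) - 0.5),
    counts    = counts,
    bin_width = bin_width,
    n         = length(ratios)
  ), class = "ratio_histogram")
}

#' @export
print.ratio_histogram <- function(x, ...) {
  cat("Ratio histogram:", x$n, "ratios in", length(x$counts),
      "bins of width", format(x$bin_width), "\n")
  cat("  range [", format(min(x$breaks)), ",", format(max(x$breaks)), ")\n")
  invisible(x)
}

#' Fit a Gaussian null model to a ratio distribution
#'
#' Fits `amplitude * exp(-(x - mean)^2 / (2 * sd^2))` to the binned
#' frequency distribution of expression ratios by nonlinear least squares.
#' The fitted mean and SD define the null (unregulated) ratio population
#' from which sigma-tier significance thresholds are derived: most proteins
#' in a relative quantitation experiment are unaffected by treatment, so
#' the central mode of the ratio distribution estimates the technical +
#' biological null.
#'
#' @param ratios numeric vector of positive ratios, or a `ratio_histogram`.
#' @param bin_width bin width used when `ratios` is numeric (default 0.05).
#' @return An object of class `"ratio_null"` with components
#'   `coefficients` (amplitude, mean, sd), `r.squared`, `n` (number of
#'   ratios), `n_bins` (bins with nonzero count), `bin_width`, `histogram`,
#'   `fitted.values` and `data`.
#' @seealso [tier_thresholds()], [classify_tiers()], and the
#'   [predict.ratio_null()] method which classifies new ratios.
#' @examples
#' set.seed(1)
#' fit <- fit_ratio_null(rnorm(370, 1.02, 0.10))
#' coef(fit)
#' @export
fit_ratio_null <- function(ratios, bin_width = 0.05) {
  if (inherits(ratios, "ratio_histogram")) {
    h <- ratios
    x <- NULL
  } else {
    stopifnot(is.numeric(ratios))
    x <- ratios[is.finite(ratios)]
    h <- build_ratio_histogram(x, bin_width)
  }
  nonzero <- sum(h$counts > 0)
  if (nonzero < 3L)
    stop("Gaussian fit refused: fewer than 3 nonzero bins (", nonzero, ")")
  # moment-based starting values from the histogram itself
  w  <- h$counts / sum(h$counts)
  m0 <- sum(w * h$centers)
  s0 <- sqrt(max(sum(w * (h$centers - m0)^2), (h$bin_width / 4)^2))
  a0 <- max(h$counts)
  df <- data.frame(xc = h$centers, ct = h$counts)
  fit <- minpack.lm::nlsLM(
    ct ~ a * exp(-(xc - m)^2 / (2 * s^2)),
    data = df,
    start = list(a = a0, m = m0, s = s0),
    lower = c(a = 0, m = -Inf, s = 1e-8),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  fitted_counts <- stats::fitted(fit)
  ss_res <- sum((df$ct - fitted_counts)^2)
  ss_tot <- sum((df$ct - mean(df$ct))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(
    coefficients  = c(amplitude = unname(cf["a"]), mean = unname(cf["m"]),
                      sd = abs(unname(cf["s"]))),
    r.squared     = r2,
    n             = if (is.null(x)) h$n else length(x),
    n_bins        = nonzero,
    bin_width     = h$bin_width,
    histogram     = h,
    fitted.values = as.numeric(fitted_counts),
    data          = x,
    call          = match.call()
  ), class = "ratio_null")
}

#' @export
coef.ratio_null <- function(object, ...) object$coefficients

#' @export
residuals.ratio_null <- function(object, ...) {
  object$histogram$counts - object$fitted.values
}

#' @export
print.ratio_null <- function(x, digits = 4, ...) {
  cf <- x$coefficients
  cat("Gaussian null model of the ratio frequency distribution\n")
  cat(sprintf("  mean = %.*g, sd = %.*g, amplitude = %.*g\n",
              digits, cf["mean"], digits, cf["sd"], digits, cf["amplitude"]))
  cat(sprintf("  n = %d ratios, %d nonzero bins of width %g, R-squared = %.4f\n",
              x$n, x$n_bins, x$bin_width, x$r.squared))
  invisible(x)
}

#' Summarize a fitted Gaussian ratio null
#'
#' @param object a `ratio_null` fit.
#' @param ... unused.
#' @return An object of class `"summary.ratio_null"` carrying the fit
#'   coefficients and the six sigma-tier thresholds.
#' @export
summary.ratio_null <- function(object, ...) {
  structure(list(
    coefficients = object$coefficients,
    r.squared    = object$r.squared,
    n            = object$n,
    n_bins       = object$n_bins,
    bin_width    = object$bin_width,
    thresholds   = tier_thresholds(object)
  ), class = "summary.ratio_null")
}

#' @export
print.summary.ratio_null <- function(x, ...) {
  cat("Gaussian null model of the ratio frequency distribution\n\n")
  cat("Coefficients:\n")
  print(round(x$coefficients, 4))
  cat(sprintf("\nn = %d ratios, %d nonzero bins (width %g), R-squared = %.4f\n",
              x$n, x$n_bins, x$bin_width, x$r.squared))
  cat("\nSigma-tier thresholds (mean +/- k sd):\n")
  print(round(unclass(x$thresholds), 4))
  invisible(x)
}

#' @export
plot.ratio_null <- function(x, main = "Ratio frequency distribution",
                            xlab = "ratio", ylab = "frequency", ...) {
  h <- x$histogram
  graphics::plot(h$centers, h$counts, type = "h", lwd = 3, col = "grey60",
                 main = main, xlab = xlab, ylab = ylab, ...)
  cf <- x$coefficients
  xs <- seq(min(h$breaks), max(h$breaks), length.out = 300)
  graphics::lines(xs, cf["amplitude"] * exp(-(xs - cf["mean"])^2 /
                                              (2 * cf["sd"]^2)), col = "red3")
  graphics::abline(v = tier_thresholds(x), lty = 3, col = "steelblue")
  invisible(x)
}

#' @export
simulate.ratio_null <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  cf <- object$coefficients
  out <- as.data.frame(replicate(nsim, stats::rnorm(object$n, cf["mean"],
                                                    cf["sd"])))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Classify new ratios or evaluate the fitted curve
#'
#' @param object a `ratio_null` fit.
#' @param newdata numeric vector of ratios; defaults to the fitted data.
#' @param type `"tier"` returns the sigma-tier classification of each
#'   ratio under the fitted thresholds; `"response"` evaluates the fitted
#'   Gaussian curve (expected bin count) at `newdata`.
#' @param ... unused.
#' @return An ordered factor of tiers, or a numeric vector of curve values.
#' @export
predict.ratio_null <- function(object, newdata = NULL,
                               type = c("tier", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    newdata <- if (!is.null(object$data)) object$data else object$histogram$centers
  }
  cf <- object$coefficients
  if (type == "response")
    return(cf["amplitude"] * exp(-(newdata - cf["mean"])^2 / (2 * cf["sd"]^2)))
  classify_tiers(newdata, tier_thresholds(object))
}

#' Sigma-tier thresholds from a fitted (or given) Gaussian null
#'
#' The six classification boundaries `mean +/- k * sd`, k in 1..3, used to
#' rank protein expression ratios into significance tiers. With the
#' canonical calibration mean 1.02 and SD 0.10 the boundaries are
#' 0.72, 0.82, 0.92, 1.12, 1.22, 1.32.
#'
#' @param object a `ratio_null` fit, or the null mean as a number.
#' @param ... further arguments; for the numeric method, `sd`.
#' @return A named numeric vector of class `"tier_thresholds"`, increasing,
#'   with names `lo3, lo2, lo1, hi1, hi2, hi3` and attributes `mean`, `sd`.
#' @examples
#' tier_thresholds(1.02, sd = 0.10)
#' @export
tier_thresholds <- function(object, ...) UseMethod("tier_thresholds")

#' @rdname tier_thresholds
#' @export
tier_thresholds.ratio_null <- function(object, ...) {
  cf <- object$coefficients
  tier_thresholds(unname(cf["mean"]), sd = unname(cf["sd"]))
}

#' @rdname tier_thresholds
#' @param sd the null standard deviation (numeric method).
#' @export
tier_thresholds.numeric <- function(object, sd, ...) {
  mean <- object
  stopifnot(length(mean) == 1L, length(sd) == 1L, sd > 0)
  th <- c(lo3 = mean - 3 * sd, lo2 = mean - 2 * sd, lo1 = mean - sd,
          hi1 = mean + sd, hi2 = mean + 2 * sd, hi3 = mean + 3 * sd)
  structure(th, mean = mean, sd = sd, class = "tier_thresholds")
}

#' @export
print.tier_thresholds <- function(x, ...) {
  cat("Sigma-tier thresholds (mean", format(attr(x, "mean")),
      "sd", format(attr(x, "sd")), "):\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' The seven sigma-tier labels, in increasing order
#'
#' @return character vector of the ordered tier labels.
#' @export
tier_levels <- function() {
  c("-3sigma", "-2sigma", "-sigma", "none", "+sigma", "+2sigma", "+3sigma")
}

#' Classify expression ratios into sigma tiers
#'
#' Assigns each positive ratio `r` to one of seven tiers by its distance
#' from the null mean in units of the null SD. With boundaries
#' `m - 3s < m - 2s < m - s < m + s < m + 2s < m + 3s` the intervals are:
#' `+sigma` for `m+s <= r < m+2s`, `+2sigma` for `m+2s <= r < m+3s`,
#' `+3sigma` for `r >= m+3s`; and on the down side `-sigma` for
#' `m-2s < r < m-s`, `-2sigma` for `m-3s < r <= m-2s`, `-3sigma` for
#' `r <= m-3s`; everything between `m-s` (inclusive) and `m+s`
#' (exclusive) is `none`. The intervals are disjoint and cover all
#' positive reals.
#'
#' @param ratios numeric vector of positive ratios.
#' @param thresholds a `tier_thresholds` object (or numeric vector of the
#'   six boundaries in increasing order).
#' @return An ordered factor with levels [tier_levels()].
#' @examples
#' th <- tier_thresholds(1.02, sd = 0.10)
#' classify_tiers(c(1.00, 1.25, 0.75, 1.40), th)
#' @export
classify_tiers <- function(ratios, thresholds) {
  stopifnot(is.numeric(ratios), length(thresholds) == 6L)
  if (any(!is.finite(ratios)) || any(ratios <= 0))
    stop("ratios must be finite and > 0")
  th <- as.numeric(thresholds)
  stopifnot(!is.unsorted(th))
  tier <- rep("none", length(ratios))
  tier[ratios >= th[4]] <- "+sigma"
  tier[ratios >= th[5]] <- "+2sigma"
  tier[ratios >= th[6]] <- "+3sigma"
  tier[ratios < th[3]]  <- "-sigma"
  tier[ratios <= th[2]] <- "-2sigma"
  tier[ratios <= th[1]] <- "-3sigma"
  factor(tier, levels = tier_levels(), ordered = TRUE)
}

#' Classify a protein quantitation table into sigma tiers
#'
#' Applies [classify_tiers()] to the overall median ratios of a
#' [aggregate_protein_ratios()] result, one row per protein x condition.
#'
#' @param quant a `protein_quant` object.
#' @param thresholds a `tier_thresholds` object.
#' @return A data frame with columns `accession`, `condition`, `ratio`,
#'   `tier`.
#' @export
classify_protein_quant <- function(quant, thresholds) {
  stopifnot(inherits(quant, "protein_quant"))
  ov <- quant$overall
  data.frame(accession = ov$accession,
             condition = ov$condition,
             ratio     = ov$ratio,
             tier      = classify_tiers(ov$ratio, thresholds),
             stringsAsFactors = FALSE)
}

#' Write the fit diagnostics report
#'
#' @param fit a `ratio_null` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  cf <- fit$coefficients
  df <- data.frame(statistic = c("mean", "sd", "amplitude", "r_squared",
                                 "n", "n_bins", "bin_width"),
                   value = c(cf["mean"], cf["sd"], cf["amplitude"],
                             fit$r.squared, fit$n, fit$n_bins, fit$bin_width))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
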