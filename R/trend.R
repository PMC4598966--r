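# polynomial helpers; coefficients stored in ascending order c0 + c1 x + ...

poly_eval <- function(coef, x) {
  s <- rep(0, length(x))
  for (i in rev(seq_along(coef))) s <- s * x + coef[i]
  s
}

poly_deriv <- function(coef) {
  n <- length(coef)
  if (n < 2) return(0)
  coef[-1] * seq_len(n - 1)
}

# real roots of a polynomial inside the open interval (lo, hi);
# companion-matrix roots (polyroot), imaginary parts below tol discarded
poly_real_roots <- function(coef, lo, hi, imag_tol) {
  coef <- coef[seq_len(max(which(abs(coef) > 0), 1))]  # strip leading zeros
  if (length(coef) < 2) return(numeric(0))
  r <- polyroot(coef)
  r <- Re(r[abs(Im(r)) < imag_tol])
  sort(r[r > lo & r < hi])
}

#' Fit a polynomial trend curve to binned distance counts
#'
#' Ordinary least squares of bin count on bin midpoint over the fit domain
#' `[0, hi]`, where `hi` is the upper edge of the last retained nonzero bin.
#' Trailing empty bins are always excluded. `tail_quantile < 1` additionally
#' trims the sparse upper tail: the domain ends at the first bin whose
#' cumulative count share reaches the quantile, which stabilizes the fit when
#' a handful of extreme distances would otherwise stretch the domain. Interior
#' zero-count bins are kept (`drop_zero_bins = TRUE` removes them).
#'
#' The fit is computed on scaled abscissae (x/hi) via a QR decomposition for
#' numerical conditioning, and coefficients are returned on the original
#' meter scale. When the counts are exactly polynomial of degree <= `degree`
#' at the midpoints, the fit interpolates them.
#'
#' @param binned a [bin_distances()] result.
#' @param degree polynomial degree (>= 2; 2..10 supported). Default 4, the
#'   minimum structure able to express rise, peak, decline and flattening.
#' @param tail_quantile cumulative-count share at which the fit domain is
#'   truncated; 1 (default) keeps every nonzero bin.
#' @param select `"none"` (use `degree`) or `"aic"` (choose the degree in
#'   `degree_range` minimizing AIC under a Gaussian residual model).
#' @param degree_range candidate degrees for `select = "aic"`.
#' @param drop_zero_bins drop interior zero-count bins from the fit data.
#' @return a `trend_curve` object: list with `degree`, `coefficients`
#'   (ascending powers), `domain` (meters), `rss`, `bin_width`, `data` (the
#'   fitted midpoint/count pairs), `n`.
#' @export
fit_trend_curve <- function(binned, degree = 4, tail_quantile = 1,
                            select = c("none", "aic"), degree_range = 2:10,
                            drop_zero_bins = FALSE) {
  select <- match.arg(select)
  if (!inherits(binned, "binned_distances"))
    stop_spaccess("fit_trend_curve expects a binned_distances object",
                  class = "spaccess_validation_error")
  if (tail_quantile <= 0 || tail_quantile > 1)
    stop_spaccess("tail_quantile must be in (0, 1]",
                  class = "spaccess_validation_error")
  counts <- binned$count
  if (sum(counts) == 0)
    stop_spaccess("all bin counts are zero; nothing to fit",
                  class = "spaccess_underdetermined_error")
  last <- if (tail_quantile < 1) {
    min(which(cumsum(counts) / sum(counts) >= tail_quantile))
  } else max(which(counts > 0))
  dat <- data.frame(midpoint = binned$midpoint[seq_len(last)],
                    count = counts[seq_len(last)])
  if (drop_zero_bins) dat <- dat[dat$count > 0, ]
  hi <- binned$bin_hi[last]
  w <- attr(binned, "bin_width")

  fit_one <- function(d) {
    if (!(d >= 2)) stop_spaccess("degree must be >= 2",
                                 class = "spaccess_validation_error")
    if (nrow(dat) <= d)
      stop_spaccess("underdetermined fit: %d data bins for degree %d",
                    nrow(dat), d, class = "spaccess_underdetermined_error")
    X <- outer(dat$midpoint / hi, 0:d, "^")
    co_s <- qr.solve(qr(X), dat$count)
    co <- co_s / hi^(0:d)
    rss <- sum((dat$count - X %*% co_s)^2)
    list(degree = d, coefficients = unname(co), rss = rss)
  }

  fit <- if (select == "aic") {
    cands <- Filter(function(d) nrow(dat) > d, as.list(degree_range))
    if (!length(cands))
      stop_spaccess("no candidate degree is identifiable with %d bins",
                    nrow(dat), class = "spaccess_underdetermined_error")
    fits <- lapply(cands, fit_one)
    aic <- vapply(fits, function(f)
      nrow(dat) * log(max(f$rss, 1e-12) / nrow(dat)) + 2 * (f$degree + 2),
      numeric(1))
    fits[[which.min(aic)]]
  } else fit_one(degree)

  structure(c(fit, list(domain = c(0, hi), bin_width = w, data = dat,
                        n = attr(binned, "n"))),
            class = "trend_curve")
}

#' Evaluate a fitted trend curve
#'
#' @param curve a `trend_curve`.
#' @param x distances (meters) to evaluate at.
#' @param deriv 0 for f, 1 for f', 2 for f''.
#' @return numeric vector of curve values.
#' @export
curve_eval <- function(curve, x, deriv = 0) {
  co <- curve$coefficients
  if (deriv >= 1) co <- poly_deriv(co)
  if (deriv >= 2) co <- poly_deriv(co)
  poly_eval(co, x)
}

#' @export
print.trend_curve <- function(x, ...) {
  cat(sprintf("<trend_curve> degree %d on [0, %g] m, %d bins, RSS %.4g\n",
              x$degree, x$domain[2], nrow(x$data), x$rss))
  cat("coefficients (ascending):", signif(x$coefficients, 6), "\n")
  invisible(x)
}

#' Diagnostic plot of binned counts, fitted curve and detected indices
#'
#' @param x a `trend_curve`.
#' @param indices optional [find_access_indices()] result; detected PWD/TLD
#'   roots are drawn as vertical lines.
#' @param ... passed to [plot()].
#' @export
plot.trend_curve <- function(x, indices = NULL, ...) {
  graphics::plot(x$data$midpoint, x$data$count, pch = 16, cex = 0.6,
                 xlab = "distance to nearest provider (m)",
                 ylab = "participants per bin", ...)
  xs <- seq(x$domain[1], x$domain[2], length.out = 400)
  graphics::lines(xs, curve_eval(x, xs), col = "firebrick", lwd = 2)
  if (!is.null(indices)) {
    if (isTRUE(indices$pwd$detected))
      graphics::abline(v = indices$pwd$root, col = "steelblue", lty = 2)
    if (isTRUE(indices$tld$detected))
      graphics::abline(v = indices$tld$root, col = "darkgreen", lty = 2)
  }
  invisible(x)
}
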