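#' Containing bin and buffer radius of an index root
#'
#' Maps a root distance to its half-open 50-m-style group `[k*w, (k+1)*w)`
#' and to the buffer radius used for ring analysis, which is the upper edge of
#' the containing bin (a root in 1600--1650 m is used as a 1650 m buffer).
#'
#' @param root nonnegative distance in meters.
#' @param bin_width bin width in meters.
#' @return list with `bin_lo`, `bin_hi`, `buffer_radius`.
#' @examples
#' report_index_bin(1612, 50)  # 1600-1650, radius 1650
#' @export
report_index_bin <- function(root, bin_width) {
  if (!is.finite(root) || root < 0)
    stop_spaccess("index root must be a nonnegative number",
                  class = "spaccess_validation_error")
  k <- floor(root / bin_width)
  list(bin_lo = k * bin_width, bin_hi = (k + 1) * bin_width,
       buffer_radius = (k + 1) * bin_width)
}

undetected_index <- function(which) {
  structure(list(index = which, detected = FALSE, root = NA_real_,
                 bin_lo = NA_real_, bin_hi = NA_real_,
                 buffer_radius = NA_real_),
            class = "access_index")
}

detected_index <- function(which, root, bin_width) {
  b <- report_index_bin(root, bin_width)
  structure(list(index = which, detected = TRUE, root = root,
                 bin_lo = b$bin_lo, bin_hi = b$bin_hi,
                 buffer_radius = b$buffer_radius),
            class = "access_index")
}

#' @export
print.access_index <- function(x, ...) {
  if (x$detected)
    cat(sprintf("%s: root %.1f m, bin %g-%g m, buffer radius %g m\n",
                toupper(x$index), x$root, x$bin_lo, x$bin_hi, x$buffer_radius))
  else cat(sprintf("%s: undetected\n", toupper(x$index)))
  invisible(x)
}

# candidate roots of the deriv-th derivative with the requested sign change
# at root +/- delta, strictly inside the open fit domain and at least delta
# from either end (boundary roots are fit artifacts)
sign_change_roots <- function(curve, deriv, before, after, delta) {
  co <- curve$coefficients
  for (i in seq_len(deriv)) co <- poly_deriv(co)
  lo <- curve$domain[1]; hi <- curve$domain[2]
  imag_tol <- 1e-8 * (hi - lo)
  r <- poly_real_roots(co, lo + delta, hi - delta, imag_tol)
  keep <- sign(poly_eval(co, r - delta)) == before &
          sign(poly_eval(co, r + delta)) == after
  r[keep]
}

#' Profit-willing distance (PWD): first interior peak of the trend curve
#'
#' The PWD is the distance `D1` of the first inflection point of the fitted
#' curve: the smallest strictly interior root of `f'` at which the slope
#' changes from positive to negative (a local maximum), assessed at
#' `D1 +/- delta`. It marks the distance band holding the maximum number of
#' participants -- the range providers can serve at a profit.
#'
#' Two artifact guards apply (see the methods vignette). First, a detected
#' peak must not be dominated by the curve's boundary values
#' (`f(D1) >= f(0)` and `f(D1) >= f(hi)`): a "peak" below the curve's value
#' at the origin is an oscillation of the polynomial fit to a decaying
#' distribution, not a mode. Second, when the binned counts themselves are
#' monotone nonincreasing over the fit domain there is no interior empirical
#' mode and the index is undetected by definition -- the typical sparse-supply
#' (rural) regime. Absence is a value, not an error.
#'
#' @param curve a [fit_trend_curve()] result.
#' @param delta slope-assessment offset in meters; default `bin_width/100`.
#' @param check_dominance disable the boundary-dominance guard (for analytic
#'   studies of the raw root definition).
#' @return an `access_index` with fields `detected`, `root`, `bin_lo`,
#'   `bin_hi`, `buffer_radius`.
#' @export
find_pwd <- function(curve, delta = curve$bin_width / 100,
                     check_dominance = TRUE) {
  if (check_dominance) {
    cnt <- curve$data$count
    if (!is.unsorted(rev(cnt)))  # counts nonincreasing: no interior mode
      return(undetected_index("pwd"))
  }
  r <- sign_change_roots(curve, 1, before = 1, after = -1, delta = delta)
  if (check_dominance && length(r)) {
    fr <- curve_eval(curve, r)
    ends <- curve_eval(curve, curve$domain)
    r <- r[fr >= max(ends)]
  }
  if (!length(r)) return(undetected_index("pwd"))
  detected_index("pwd", r[1], curve$bin_width)
}

#' Tolerance-limited distance (TLD): first post-peak concavity change
#'
#' The TLD is the distance `D2` of the second inflection point: the smallest
#' strictly interior root of `f''` beyond the PWD (beyond 0 when the PWD is
#' undetected) at which the curve turns from concave-down to concave-up --
#' the flattening of the decline past the peak. Beyond it, supplying service
#' is taken to exceed the provider's tolerable burden.
#'
#' The default sign convention is the concave-down-to-concave-up geometry
#' (`f''` changes from negative to positive). The opposite convention is
#' available via `convention = "concave-down"`.
#'
#' @param curve a [fit_trend_curve()] result.
#' @param pwd the [find_pwd()] result for the same curve, or `NULL`.
#' @param convention direction of the concavity change at `D2`.
#' @param delta curvature-assessment offset in meters.
#' @return an `access_index`; undetected when no qualifying root exists.
#' @export
find_tld <- function(curve, pwd = NULL,
                     convention = c("concave-up", "concave-down"),
                     delta = curve$bin_width / 100) {
  convention <- match.arg(convention)
  lower <- if (!is.null(pwd) && isTRUE(pwd$detected)) pwd$root else 0
  sgn <- if (convention == "concave-up") c(-1, 1) else c(1, -1)
  r <- sign_change_roots(curve, 2, before = sgn[1], after = sgn[2],
                         delta = delta)
  r <- r[r > lower]
  if (!length(r)) return(undetected_index("tld"))
  detected_index("tld", r[1], curve$bin_width)
}

#' End-to-end accessibility indices from point data
#'
#' Pipeline: nearest-provider distances -> fixed-width binning -> polynomial
#' trend curve -> PWD and TLD by derivative sign-change analysis. Also
#' reports the raw argmax bin (the bin with the maximum observed count) for
#' comparison with the curve-based index.
#'
#' @param participants,providers [located_points] collections, or pass a
#'   precomputed `distances` vector/data frame instead.
#' @param distances optional precomputed nearest distances (meters).
#' @param bin_width bin width in meters (default 50).
#' @param degree,tail_quantile,select passed to [fit_trend_curve()].
#' @param convention TLD concavity convention, see [find_tld()].
#' @return an `access_indices` list: `binned`, `curve`, `pwd`, `tld`,
#'   `argmax_bin`.
#' @export
find_access_indices <- function(participants = NULL, providers = NULL,
                                distances = NULL, bin_width = 50,
                                degree = 4, tail_quantile = 1,
                                select = "none",
                                convention = "concave-up") {
  if (is.null(distances)) {
    if (is.null(participants) || is.null(providers))
      stop_spaccess("supply either distances or participants + providers",
                    class = "spaccess_validation_error")
    distances <- nearest_provider_distance(participants, providers)
  }
  binned <- bin_distances(distances, bin_width)
  curve <- fit_trend_curve(binned, degree = degree,
                           tail_quantile = tail_quantile, select = select)
  pwd <- find_pwd(curve)
  tld <- find_tld(curve, pwd, convention = convention)
  k <- which.max(binned$count)
  structure(list(binned = binned, curve = curve, pwd = pwd, tld = tld,
                 argmax_bin = c(bin_lo = binned$bin_lo[k],
                                bin_hi = binned$bin_hi[k])),
            class = "access_indices")
}

#' @export
print.access_indices <- function(x, ...) {
  cat(sprintf("<access_indices> n = %d, %d bins of %g m, curve degree %d\n",
              attr(x$binned, "n"), nrow(x$binned),
              x$curve$bin_width, x$curve$degree))
  print(x$pwd); print(x$tld)
  cat(sprintf("raw argmax bin: %g-%g m\n",
              x$argmax_bin[["bin_lo"]], x$argmax_bin[["bin_hi"]]))
  invisible(x)
}

index_to_list <- function(ix) {
  if (!isTRUE(ix$detected)) return(NULL)
  list(root = ix$root, bin_lo = ix$bin_lo, bin_hi = ix$bin_hi,
       buffer_radius = ix$buffer_radius)
}

#' JSON-ready index report
#'
#' Stable, versioned report structure; undetected indices are encoded as
#' `null`.
#'
#' @param indices a [find_access_indices()] result.
#' @param path optional path; when given the report is written as JSON.
#' @return the report list, invisibly when written.
#' @export
index_report <- function(indices, path = NULL) {
  rep <- list(
    schema_version = "1.0",
    n = attr(indices$binned, "n"),
    bin_width = indices$curve$bin_width,
    degree = indices$curve$degree,
    coefficients = indices$curve$coefficients,
    domain = indices$curve$domain,
    rss = indices$curve$rss,
    pwd = index_to_list(indices$pwd),
    tld = index_to_list(indices$tld),
    argmax_bin = list(bin_lo = unname(indices$argmax_bin[["bin_lo"]]),
                      bin_hi = unname(indices$argmax_bin[["bin_hi"]])))
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(rep))
  }
  rep
}
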