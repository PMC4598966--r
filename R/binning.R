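#' Bin nearest-provider distances into fixed-width groups
#'
#' Distances are grouped into half-open bins `[k*w, (k+1)*w)` from zero to
#' just beyond the maximum observed distance. The bin counts against bin
#' midpoints are the `(x, y)` data the trend curve is fitted to. The default
#' width is 50 m, the grouping resolution at which the accessibility indices
#' are reported.
#'
#' @param distances numeric vector of nonnegative distances (meters), or the
#'   data frame returned by [nearest_provider_distance()].
#' @param bin_width bin width `w` in meters, `> 0`.
#' @return a `binned_distances` data frame with columns `bin_lo`, `bin_hi`,
#'   `midpoint`, `count` and attributes `bin_width`, `n`.
#' @examples
#' bin_distances(c(0, 49.99, 50), bin_width = 50)
#' @export
bin_distances <- function(distances, bin_width = 50) {
  if (is.data.frame(distances)) distances <- distances$distance
  if (!is.numeric(bin_width) || length(bin_width) != 1 || !is.finite(bin_width) ||
      bin_width <= 0)
    stop_spaccess("bin_width must be a positive number",
                  class = "spaccess_validation_error")
  assert_finite_num(distances %||% numeric(0), "distances")
  if (any(distances < 0))
    stop_spaccess("negative distance(s) supplied to bin_distances",
                  class = "spaccess_validation_error")
  n_bins <- if (length(distances)) floor(max(distances) / bin_width) + 1L else 1L
  counts <- tabulate(floor(distances / bin_width) + 1L, nbins = n_bins)
  lo <- (seq_len(n_bins) - 1L) * bin_width
  out <- data.frame(bin_lo = lo, bin_hi = lo + bin_width,
                    midpoint = lo + bin_width / 2, count = counts)
  structure(out, bin_width = bin_width, n = length(distances),
            class = c("binned_distances", "data.frame"))
}

#' @export
print.binned_distances <- function(x, ...) {
  cat(sprintf("<binned_distances> %d bins of width %g m, n = %d\n",
              nrow(x), attr(x, "bin_width"), attr(x, "n")))
  print.data.frame(utils::head(as.data.frame(x), 8), row.names = FALSE)
  if (nrow(x) > 8) cat(sprintf("... %d more bins\n", nrow(x) - 8L))
  invisible(x)
}

#' @rdname bin_distances
#' @param binned a `binned_distances` object.
#' @param path CSV path; columns `bin_lo,bin_hi,count`.
#' @export
write_binned_csv <- function(binned, path) {
  utils::write.csv(as.data.frame(binned)[c("bin_lo", "bin_hi", "count")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname bin_distances
#' @export
read_binned_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("bin_lo", "bin_hi", "count") %in% names(df)))
    stop_spaccess("%s: header must contain bin_lo,bin_hi,count", path,
                  class = "spaccess_io_error")
  w <- df$bin_hi[1] - df$bin_lo[1]
  out <- data.frame(bin_lo = df$bin_lo, bin_hi = df$bin_hi,
                    midpoint = df$bin_lo + w / 2, count = df$count)
  structure(out, bin_width = w, n = sum(df$count),
            class = c("binned_distances", "data.frame"))
}
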