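#' Provider multiplicity within a buffer radius
#'
#' For each participant, the number of providers within distance `<= R` (a
#' closed ball). Equivalently, the number of provider buffer disks of radius
#' `R` that cover the participant; overlapping buffer rings are what give
#' participants a choice of provider.
#'
#' @param participants,providers [located_points] collections in the same
#'   frame.
#' @param radius buffer radius `R` in meters, `> 0`.
#' @return data frame with columns `id`, `multiplicity`.
#' @export
provider_multiplicity <- function(participants, providers, radius) {
  if (!is.numeric(radius) || length(radius) != 1 || !is.finite(radius) ||
      radius <= 0)
    stop_spaccess("radius must be a positive number",
                  class = "spaccess_validation_error")
  m <- distance_matrix(participants, providers)
  data.frame(id = participants$id,
             multiplicity = as.integer(rowSums(m <= radius)),
             stringsAsFactors = FALSE)
}

#' Provider-choice table with two-level percentage convention
#'
#' Tallies participants by provider multiplicity within a buffer radius, with
#' multiplicities `>= cap` pooled into a top bucket. Percentages follow the
#' two-level convention of buffer-ring reporting: the "without any provider"
#' (m = 0) and "at least one" (m >= 1) rows are shares of all participants,
#' while the individual m >= 1 rows are shares of the m >= 1 subgroup.
#' Percentages are rounded half-away-from-zero to two decimals.
#'
#' @param multiplicities integer vector, or a [provider_multiplicity()]
#'   result.
#' @param cap pooling threshold for the top bucket (default 7, i.e. ">=7").
#' @param radius optional radius label (meters) carried into the table.
#' @return a `choice_table`: list with `radius`, `n_total`, `pct_without`,
#'   `pct_with_any`, and `table` (columns `multiplicity`, `count`,
#'   `pct_total`, `pct_within_any`).
#' @examples
#' build_choice_table(rep(c(0, 1, 2, 3), c(3791, 1501, 270, 65)), cap = 7)
#' @export
build_choice_table <- function(multiplicities, cap = 7, radius = NA_real_) {
  if (is.data.frame(multiplicities)) {
    radius <- attr(multiplicities, "radius") %||% radius
    multiplicities <- multiplicities$multiplicity
  }
  if (!(is.numeric(cap) && length(cap) == 1 && cap >= 1))
    stop_spaccess("cap must be >= 1", class = "spaccess_validation_error")
  cap <- as.integer(cap)
  n_total <- length(multiplicities)
  pooled <- pmin(as.integer(multiplicities), cap)
  counts <- tabulate(pooled + 1L, nbins = cap + 1L)  # m = 0..cap
  labels <- c(as.character(0:(cap - 1L)), paste0(">=", cap))
  n_any <- n_total - counts[1]
  if (n_total > 0) {
    pct_total <- round_half_away(100 * counts / n_total, 2)
    pct_within <- c(NA, if (n_any > 0)
      round_half_away(100 * counts[-1] / n_any, 2) else rep(NA, cap))
    pct_without <- round_half_away(100 * counts[1] / n_total, 2)
    pct_any <- round_half_away(100 * n_any / n_total, 2)
  } else {
    pct_total <- pct_within <- rep(NA_real_, cap + 1L)
    pct_without <- pct_any <- NA_real_
  }
  structure(list(
    radius = radius, n_total = n_total, cap = cap,
    pct_without = pct_without, pct_with_any = pct_any,
    table = data.frame(multiplicity = labels, count = counts,
                       pct_total = pct_total, pct_within_any = pct_within,
                       stringsAsFactors = FALSE)),
    class = "choice_table")
}

#' @export
print.choice_table <- function(x, ...) {
  lab <- if (is.finite(x$radius)) sprintf(" within %g m", x$radius) else ""
  cat(sprintf("<choice_table>%s, n = %d\n", lab, x$n_total))
  if (x$n_total == 0) {
    cat("empty table: percentages undefined\n")
  } else {
    cat(sprintf("without any provider: %.2f%%; with >=1: %.2f%%\n",
                x$pct_without, x$pct_with_any))
  }
  print.data.frame(x$table, row.names = FALSE)
  invisible(x)
}

#' @rdname build_choice_table
#' @param choice a `choice_table`.
#' @param path CSV path (`multiplicity,count,pct_total,pct_within_any`).
#' @export
write_choice_csv <- function(choice, path) {
  utils::write.csv(choice$table, path, row.names = FALSE)
  invisible(path)
}

#' Service-density ratios
#'
#' People-per-provider (reported to one decimal) and, when population and
#' area are supplied, population density in people per square kilometer
#' (two decimals): the conventional disparity measures the distance indices
#' are designed to improve upon.
#'
#' @param n_people number of people in need.
#' @param n_providers number of providers (> 0).
#' @param population,area_km2 optional regional totals for density.
#' @return list `n_people`, `n_providers`, `people_per_provider`, and
#'   optionally `population`, `area_km2`, `people_per_km2`.
#' @examples
#' density_ratios(956, 19)  # 50.3 people per provider
#' @export
density_ratios <- function(n_people, n_providers, population = NULL,
                           area_km2 = NULL) {
  if (!is.numeric(n_providers) || n_providers <= 0)
    stop_spaccess("n_providers must be > 0 to form a ratio",
                  class = "spaccess_validation_error")
  out <- list(n_people = n_people, n_providers = n_providers,
              people_per_provider = round_half_away(n_people / n_providers, 1))
  if (!is.null(population) && !is.null(area_km2)) {
    if (area_km2 <= 0)
      stop_spaccess("area_km2 must be > 0", class = "spaccess_validation_error")
    out$population <- population
    out$area_km2 <- area_km2
    out$people_per_km2 <- round_half_away(population / area_km2, 2)
  }
  out
}

region_summary <- function(label, indices, tables) {
  idx_field <- function(ix) {
    if (is.null(ix) || !isTRUE(ix$detected)) "undetected"
    else sprintf("%g-%g", ix$bin_lo, ix$bin_hi)
  }
  tab_fields <- function(tb, prefix) {
    if (is.null(tb))
      return(stats::setNames(list(NA_real_, NA_real_, FALSE),
                             paste0(prefix, c("_pct_without", "_pct_with_any",
                                              "_computed"))))
    stats::setNames(list(tb$pct_without, tb$pct_with_any, TRUE),
                    paste0(prefix, c("_pct_without", "_pct_with_any",
                                     "_computed")))
  }
  c(list(region = label,
         pwd_detected = isTRUE(indices$pwd$detected),
         tld_detected = isTRUE(indices$tld$detected),
         pwd_bin = idx_field(indices$pwd),
         tld_bin = idx_field(indices$tld)),
    tab_fields(tables$pwd, "pwd"), tab_fields(tables$tld, "tld"))
}

#' Side-by-side regional disparity report
#'
#' Emits, per region, the detected index bins and the with/without-provider
#' percentage summaries of the region's choice tables, each computed at that
#' region's own radii. When an index is undetected for a region the
#' corresponding table slot is absent and flagged rather than borrowed from
#' the other region. Purely descriptive: no inferential claims.
#'
#' @param regions named list; each element is
#'   `list(indices = <access_indices>, tables = list(pwd = <choice_table> or
#'   NULL, tld = ...))`.
#' @return a `disparity_report`: data frame with one row per region.
#' @export
disparity_report <- function(regions) {
  rows <- lapply(names(regions), function(nm)
    as.data.frame(region_summary(nm, regions[[nm]]$indices,
                                 regions[[nm]]$tables),
                  stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  class(out) <- c("disparity_report", "data.frame")
  out
}

#' @export
print.disparity_report <- function(x, ...) {
  cat("<disparity_report>\n")
  print.data.frame(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
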