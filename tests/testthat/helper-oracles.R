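# independent brute-force / closed-form oracles used across tests

oracle_euclid <- function(a, b) sqrt((a[1] - b[1])^2 + (a[2] - b[2])^2)

# exhaustive all-pairs nearest scan, ids ordered for ties
oracle_nearest <- function(participants, providers) {
  t(vapply(seq_len(nrow(participants)), function(i) {
    d <- vapply(seq_len(nrow(providers)), function(j)
      oracle_euclid(c(participants$x[i], participants$y[i]),
                    c(providers$x[j], providers$y[j])), numeric(1))
    best <- min(d)
    ids <- sort(providers$id[d == best])
    c(distance = best, provider = ids[1])
  }, c(distance = "", provider = "")))
}

# independent histogram with left-closed bins
oracle_hist_counts <- function(d, w) {
  breaks <- seq(0, (floor(max(d) / w) + 1) * w, by = w)
  graphics::hist(d, breaks = breaks, right = FALSE, plot = FALSE)$counts
}

# exhaustive multiplicity scan (closed ball)
oracle_multiplicity <- function(participants, providers, R) {
  vapply(seq_len(nrow(participants)), function(i)
    sum(vapply(seq_len(nrow(providers)), function(j)
      oracle_euclid(c(participants$x[i], participants$y[i]),
                    c(providers$x[j], providers$y[j])) <= R,
      logical(1))), integer(1))
}

# direct-formula Pearson statistic
oracle_chi2 <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - E)^2 / E)
}

# full-enumeration two-sided Fisher p (probability-ordering rule)
oracle_fisher_p <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  pr <- stats::dhyper(ks, r1, n - r1, c1)
  p_obs <- stats::dhyper(m[1, 1], r1, n - r1, c1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# direct-formula two-sample t (both variants), independent of the package
oracle_t <- function(ma, sa, na, mb, sb, nb, variant) {
  if (variant == "pooled") {
    sp2 <- ((na - 1) * sa^2 + (nb - 1) * sb^2) / (na + nb - 2)
    (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    (ma - mb) / sqrt(sa^2 / na + sb^2 / nb)
  }
}

# build a binned_distances object directly from counts (unit-agnostic),
# for analytic curve studies where counts are specified, not sampled
binned_from_counts <- function(counts, w) {
  lo <- (seq_along(counts) - 1) * w
  structure(data.frame(bin_lo = lo, bin_hi = lo + w, midpoint = lo + w / 2,
                       count = counts),
            bin_width = w, n = sum(counts),
            class = c("binned_distances", "data.frame"))
}

random_points <- function(n, extent = 10000, prefix = "P", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  located_points(data.frame(id = sprintf("%s%04d", prefix, seq_len(n)),
                            x = runif(n, 0, extent),
                            y = runif(n, 0, extent)), "planar-meters")
}
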