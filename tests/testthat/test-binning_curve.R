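test_that("distances fall into half-open bins and counts conserve n", {
  b <- bin_distances(c(0, 49.99, 50), bin_width = 50)
  expect_equal(b$count[1:2], c(2, 1))
  expect_equal(sum(b$count), 3)
  empty <- bin_distances(numeric(0))
  expect_true(all(empty$count == 0))
  expect_error(bin_distances(c(-1, 5)), class = "spaccess_validation_error")
  expect_error(bin_distances(1:3, bin_width = 0),
               class = "spaccess_validation_error")
})

test_that("binned counts match an independent histogram oracle bin-for-bin", {
  set.seed(41)
  d <- runif(1000, 0, 2000)
  b <- bin_distances(d, 50)
  expect_equal(b$count, oracle_hist_counts(d, 50))
  # other widths too
  for (w in c(10, 123.5)) {
    b <- bin_distances(d, w)
    expect_equal(b$count, oracle_hist_counts(d, w))
    expect_equal(sum(b$count), 1000)
  }
})

test_that("a cubic count pattern is interpolated exactly", {
  # counts y = x (x - 4)^2 at 50-m midpoints with x in km
  w <- 0.05
  mids <- seq(w / 2, 5, by = w)
  counts <- mids * (mids - 4)^2
  b <- binned_from_counts(round(counts * 1e6) / 1e6, w)
  b$count <- counts  # exact values, not integers: analytic study
  fit <- fit_trend_curve(b, degree = 3)
  expect_equal(fit$coefficients, c(0, 16, -8, 1), tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
})

test_that("constant counts give a flat quadratic fit", {
  b <- binned_from_counts(rep(7, 30), 50)
  fit <- fit_trend_curve(b, degree = 2)
  expect_equal(fit$coefficients[1], 7, tolerance = 1e-8)
  expect_lt(max(abs(fit$coefficients[2:3])) * 1500, 1e-6)
})

test_that("higher-degree fits never raise the residual sum of squares", {
  set.seed(42)
  b <- bin_distances(rgamma(2000, 3, scale = 200), 50)
  rss <- vapply(2:8, function(d) fit_trend_curve(b, degree = d)$rss,
                numeric(1))
  expect_true(all(diff(rss) <= 1e-6 * rss[-length(rss)]))
})

test_that("underdetermined fits are refused explicitly", {
  b <- binned_from_counts(c(3, 1, 2), 50)
  expect_error(fit_trend_curve(b, degree = 3),
               class = "spaccess_underdetermined_error")
  expect_error(fit_trend_curve(binned_from_counts(rep(0, 5), 50)),
               class = "spaccess_underdetermined_error")
})

test_that("PWD and TLD of an exact cubic match the symbolic derivative roots", {
  # f(x) = x (x - 4)^2 = 16x - 8x^2 + x^3 on [0, 5]
  # f' = 16 - 16x + 3x^2, roots 4/3 (+ to -) and 4 (- to +)
  # f'' = -16 + 6x, root 8/3 (- to +), and 8/3 > 4/3
  w <- 0.05
  mids <- seq(w / 2, 5, by = w)
  b <- binned_from_counts(rep(1, length(mids)), w)
  b$count <- mids * (mids - 4)^2
  fit <- fit_trend_curve(b, degree = 3)
  pwd <- find_pwd(fit)
  tld <- find_tld(fit, pwd)
  expect_true(pwd$detected)
  expect_true(tld$detected)
  span <- diff(fit$domain)
  expect_lt(abs(pwd$root - 4 / 3), 1e-6 * span)
  expect_lt(abs(tld$root - 8 / 3), 1e-6 * span)
  expect_lt(pwd$root, tld$root)
  # containing bins and buffer radii
  expect_equal(c(pwd$bin_lo, pwd$bin_hi), c(1.30, 1.35))
  expect_equal(tld$buffer_radius, 2.70)
})

test_that("a parabola's vertex is its PWD and it has no TLD", {
  # f(x) = -(x - 2)^2 + 10 on [0, 5]: vertex 2; f'' constant, no root
  w <- 0.05
  mids <- seq(w / 2, 5, by = w)
  b <- binned_from_counts(rep(1, length(mids)), w)
  b$count <- -(mids - 2)^2 + 10
  fit <- fit_trend_curve(b, degree = 2)
  pwd <- find_pwd(fit)
  expect_true(pwd$detected)
  expect_equal(pwd$root, 2, tolerance = 1e-9)
  expect_false(find_tld(fit, pwd)$detected)
})

test_that("monotone decreasing curves yield no PWD", {
  w <- 0.05
  mids <- seq(w / 2, 5, by = w)
  b <- binned_from_counts(rep(1, length(mids)), w)
  b$count <- 100 * exp(-mids)  # monotone decreasing
  expect_false(find_pwd(fit_trend_curve(b, degree = 4))$detected)
})

test_that("a concavity change below the PWD does not qualify as TLD", {
  # f(x) = 20 - x (x - 4)^2: f' changes + to - at x = 4 (local max); the
  # only f'' root is 8/3 with sign + to -, i.e. a concave-down change
  # sitting BELOW the peak
  w <- 0.05
  mids <- seq(w / 2, 5, by = w)
  b <- binned_from_counts(rep(1, length(mids)), w)
  b$count <- -(mids * (mids - 4)^2) + 20
  fit <- fit_trend_curve(b, degree = 3)
  pwd <- find_pwd(fit, check_dominance = FALSE)
  expect_true(pwd$detected)
  expect_equal(pwd$root, 4, tolerance = 1e-6)
  # default convention: no - to + root exists at all
  expect_false(find_tld(fit, pwd)$detected)
  # opposite convention: the root at 8/3 has the right signs but lies below
  # D1 = 4, so it is filtered out ...
  expect_false(find_tld(fit, pwd, convention = "concave-down")$detected)
  # ... and is found only when no PWD constrains the search
  tld0 <- find_tld(fit, NULL, convention = "concave-down")
  expect_true(tld0$detected)
  expect_equal(tld0$root, 8 / 3, tolerance = 1e-6)
})

test_that("index roots scale with distances and bin width (equivariance)", {
  set.seed(43)
  d <- rgamma(4000, shape = 4, scale = 150)
  base <- find_access_indices(distances = d, bin_width = 50, degree = 6,
                              tail_quantile = 0.99)
  for (c_ in c(0.1, 3)) {
    scaled <- find_access_indices(distances = d * c_, bin_width = 50 * c_,
                                  degree = 6, tail_quantile = 0.99)
    expect_equal(scaled$pwd$root, base$pwd$root * c_, tolerance = 1e-6)
    expect_equal(scaled$tld$root, base$tld$root * c_, tolerance = 1e-6)
  }
})

test_that("index bins are reported with upper-edge buffer radii", {
  r <- report_index_bin(1612, 50)
  expect_equal(c(r$bin_lo, r$bin_hi, r$buffer_radius), c(1600, 1650, 1650))
  r <- report_index_bin(600, 50)
  expect_equal(c(r$bin_lo, r$bin_hi, r$buffer_radius), c(600, 650, 650))
  r <- report_index_bin(4 / 3 * 1000, 50)
  expect_equal(c(r$bin_lo, r$bin_hi, r$buffer_radius), c(1300, 1350, 1350))
  expect_error(report_index_bin(-5, 50), class = "spaccess_validation_error")
})

test_that("AIC degree selection returns a valid fit with sane degree", {
  set.seed(44)
  b <- bin_distances(rgamma(3000, 4, scale = 150), 50)
  fit <- fit_trend_curve(b, select = "aic", tail_quantile = 0.99)
  expect_true(fit$degree >= 2 && fit$degree <= 10)
  expect_true(is.finite(fit$rss))
})

test_that("binned CSV round-trips preserve the distribution", {
  set.seed(45)
  b <- bin_distances(runif(500, 0, 3000), 50)
  f <- tempfile(fileext = ".csv")
  write_binned_csv(b, f)
  back <- read_binned_csv(f)
  expect_equal(back$count, b$count)
  expect_equal(attr(back, "bin_width"), 50)
})
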