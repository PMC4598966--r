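test_that("pairwise distance matches Euclidean geometry and the norm oracle", {
  expect_equal(pairwise_distance(c(0, 0), c(3, 4), "planar-meters"), 5)
  expect_equal(pairwise_distance(c(17.2, -3), c(17.2, -3), "planar-meters"), 0)
  expect_equal(pairwise_distance(c(121.5, 25.0), c(121.5, 25.0),
                                 "geographic-wgs84"), 0)
  set.seed(11)
  for (i in 1:10) {
    a <- runif(2, -1000, 1000); b <- runif(2, -1000, 1000)
    expect_equal(pairwise_distance(a, b, "planar-meters"), oracle_euclid(a, b))
  }
})

test_that("geographic distances use the haversine great circle", {
  # one degree of latitude on the mean-radius sphere
  d <- pairwise_distance(c(0, 0), c(0, 1), "geographic-wgs84")
  expect_equal(d, pi / 180 * 6371008.8, tolerance = 1e-9)
  # symmetry and triangle inequality on random lon/lat triples
  set.seed(12)
  for (i in 1:20) {
    p <- matrix(c(runif(3, -180, 180), runif(3, -80, 80)), ncol = 2)
    dab <- pairwise_distance(p[1, ], p[2, ], "geographic-wgs84")
    dba <- pairwise_distance(p[2, ], p[1, ], "geographic-wgs84")
    dbc <- pairwise_distance(p[2, ], p[3, ], "geographic-wgs84")
    dac <- pairwise_distance(p[1, ], p[3, ], "geographic-wgs84")
    expect_equal(dab, dba)
    expect_lte(dac, dab + dbc + 1e-6)
  }
})

test_that("triangle inequality holds for planar distances on random triples", {
  set.seed(13)
  for (i in 1:50) {
    p <- matrix(runif(6, 0, 500), ncol = 2)
    expect_lte(oracle_euclid(p[1, ], p[3, ]),
               pairwise_distance(p[1, ], p[2, ], "planar-meters") +
               pairwise_distance(p[2, ], p[3, ], "planar-meters") + 1e-9)
  }
})

test_that("point validation rejects bad coordinates and duplicate ids", {
  expect_error(located_points(data.frame(id = "a", x = NA, y = 1)),
               class = "spaccess_validation_error")
  expect_error(located_points(data.frame(id = "a", x = Inf, y = 1)),
               class = "spaccess_validation_error")
  expect_error(located_points(data.frame(id = c("a", "a"), x = 1:2, y = 1:2)),
               class = "spaccess_validation_error")
  expect_error(pairwise_distance(c(NA, 0), c(0, 0), "planar-meters"),
               class = "spaccess_validation_error")
})

test_that("mixed coordinate frames are refused", {
  a <- located_points(data.frame(id = "a", x = 1, y = 2), "planar-meters")
  b <- located_points(data.frame(id = "b", x = 1, y = 2), "geographic-wgs84")
  expect_error(nearest_provider_distance(a, b), class = "spaccess_frame_error")
  expect_error(pairwise_distance(a, c(0, 0), "geographic-wgs84"),
               class = "spaccess_frame_error")
})

test_that("nearest-provider distance equals the exhaustive double-loop scan", {
  parts <- random_points(200, prefix = "P", seed = 21)
  provs <- random_points(15, prefix = "S", seed = 22)
  got <- nearest_provider_distance(parts, provs)
  want <- oracle_nearest(parts, provs)
  expect_equal(got$distance, as.numeric(want[, "distance"]))
  expect_equal(got$provider_id, unname(want[, "provider"]))
})

test_that("nearest-provider handles coincidence, minima and empty supply", {
  parts <- located_points(data.frame(id = "p1", x = 0, y = 0))
  provs <- located_points(data.frame(id = c("s1", "s2", "s3"),
                                     x = c(100, 70, 350), y = 0))
  got <- nearest_provider_distance(parts, provs)
  expect_equal(got$distance, 70)
  expect_equal(got$provider_id, "s2")
  coincident <- located_points(data.frame(id = "s9", x = 0, y = 0))
  expect_equal(nearest_provider_distance(parts, coincident)$distance, 0)
  empty <- located_points(data.frame(id = character(), x = numeric(),
                                     y = numeric()))
  expect_error(nearest_provider_distance(parts, empty),
               class = "spaccess_empty_supply_error")
})

test_that("exact distance ties go to the lexicographically smallest id", {
  parts <- located_points(data.frame(id = "p1", x = 0, y = 0))
  provs <- located_points(data.frame(id = c("s2", "s1"), x = c(100, -100),
                                     y = 0))
  expect_equal(nearest_provider_distance(parts, provs)$provider_id, "s1")
})

test_that("nearest over a provider union is the elementwise min of the parts", {
  parts <- random_points(60, prefix = "P", seed = 31)
  s1 <- random_points(5, prefix = "A", seed = 32)
  s2 <- random_points(7, prefix = "B", seed = 33)
  both <- located_points(rbind(as.data.frame(s1), as.data.frame(s2)))
  expect_equal(nearest_provider_distance(parts, both)$distance,
               pmin(nearest_provider_distance(parts, s1)$distance,
                    nearest_provider_distance(parts, s2)$distance))
})

test_that("zone snapping replaces coordinates, is idempotent, never adds sites", {
  zones <- data.frame(zone_id = c("Z1", "Z2"), x = c(500, 900), y = c(500, 0))
  pts <- located_points(data.frame(id = c("a", "b", "c"),
                                   x = c(1, 2, 880), y = c(1, 9, 10),
                                   zone_id = c("Z1", "Z1", "Z2")))
  snapped <- snap_to_zone_centroid(pts, zones)
  expect_equal(nrow(snapped), 3)
  expect_equal(snapped$id, pts$id)
  expect_equal(snapped$x, c(500, 500, 900))
  expect_equal(snapped$y, c(500, 500, 0))
  expect_identical(snap_to_zone_centroid(snapped, zones), snapped)
  expect_lte(nrow(unique(as.data.frame(snapped)[c("x", "y")])),
             nrow(unique(as.data.frame(pts)[c("x", "y")])))
  bad <- located_points(data.frame(id = "d", x = 0, y = 0, zone_id = "Z9"))
  expect_error(snap_to_zone_centroid(bad, zones),
               class = "spaccess_validation_error")
  expect_error(snap_to_zone_centroid(located_points(
    data.frame(id = "e", x = 0, y = 0)), zones),
    class = "spaccess_validation_error")
})

test_that("CSV and GeoJSON point round-trips preserve data and frame", {
  pts <- located_points(data.frame(id = c("a", "b"), x = c(0.5, 3.25),
                                   y = c(-1, 4), zone_id = c("Z1", "Z2")))
  csv <- tempfile(fileext = ".csv")
  write_points_csv(pts, csv)
  back <- read_points_csv(csv, "planar-meters")
  expect_equal(as.data.frame(back), as.data.frame(pts))
  expect_equal(point_frame(back), "planar-meters")
  gj <- tempfile(fileext = ".geojson")
  write_points_geojson(pts, gj)
  back2 <- read_points_geojson(gj, "planar-meters")
  expect_equal(as.data.frame(back2)[c("id", "x", "y", "zone_id")],
               as.data.frame(pts)[c("id", "x", "y", "zone_id")])
})

test_that("malformed CSV input fails with a located diagnostic", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("id,x,y", "a,1,2", "b,not-a-number,3"), f)
  expect_error(read_points_csv(f), "line", class = "spaccess_io_error")
  writeLines(c("id,lon", "a,1"), f)
  expect_error(read_points_csv(f), class = "spaccess_io_error")
})
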