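pts <- function(...) {
  xy <- rbind(...)
  data.frame(x_um = xy[, 1], y_um = xy[, 2])
}

test_that("group_articulations implements strict single linkage at 20 um", {
  expect_length(group_articulations(pts(c(0, 0), c(10, 0))), 1)
  expect_equal(group_articulations(pts(c(0, 0), c(10, 0)))[[1]]$site_type,
               "S2")
  two <- group_articulations(pts(c(0, 0), c(25, 0)))
  expect_length(two, 2)
  expect_true(all(vapply(two, `[[`, character(1), "site_type") == "S1"))
  ## chain 0-15-30: ends are 30 apart but chained through the middle
  chain <- group_articulations(pts(c(0, 0), c(15, 0), c(30, 0)))
  expect_length(chain, 1)
  expect_equal(chain[[1]]$site_type, "S3")
  ## strict inequality: exactly 20 um does not link
  expect_length(group_articulations(pts(c(0, 0), c(20, 0))), 2)
  ## duplicates group together
  expect_length(group_articulations(pts(c(5, 5), c(5, 5))), 1)
  expect_length(group_articulations(pts()[0, ]), 0)
})

test_that("grouping matches exhaustive component search on random sets", {
  set.seed(14)
  for (rep in 1:25) {
    n <- sample(2:40, 1)
    xy <- matrix(runif(2 * n, 0, 150), ncol = 2)
    got <- group_articulations(data.frame(x_um = xy[, 1], y_um = xy[, 2]))
    want <- oracle_components(xy, 20)
    expect_equal(length(got), length(unique(want)))
    ## identical partition, compared as sorted member sets
    got_sets <- sort(vapply(got, function(s)
      paste(sort(s$members), collapse = ","), character(1)))
    want_sets <- sort(vapply(split(seq_len(n), want), function(ix)
      paste(sort(ix), collapse = ","), character(1)))
    expect_equal(got_sets, unname(want_sets))
  }
})

test_that("grouping partitions the input and is order-independent", {
  set.seed(8)
  xy <- matrix(runif(60, 0, 100), ncol = 2)
  d <- data.frame(x_um = xy[, 1], y_um = xy[, 2])
  g1 <- group_articulations(d)
  expect_equal(sum(vapply(g1, `[[`, integer(1), "n")), nrow(d))
  perm <- sample(nrow(d))
  g2 <- group_articulations(d[perm, ])
  c1 <- t(vapply(g1, `[[`, numeric(2), "centroid_um"))
  c2 <- t(vapply(g2, `[[`, numeric(2), "centroid_um"))
  expect_equal(c1, c2, tolerance = 1e-12)
})

test_that("site count is non-increasing in the linkage threshold", {
  set.seed(31)
  for (rep in 1:20) {
    xy <- matrix(runif(2 * sample(5:60, 1), 0, 200), ncol = 2)
    d <- data.frame(x_um = xy[, 1], y_um = xy[, 2])
    counts <- vapply(c(5, 10, 20, 40, 80), function(th)
      length(group_articulations(d, threshold_um = th)), integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("absolute density is count over area", {
  sites <- replicate(47, list(n = 1), simplify = FALSE)
  expect_equal(compute_absolute_density(sites, 3.2), 14.6875)
  expect_equal(compute_absolute_density(list(), 5), 0)
  expect_equal(compute_absolute_density(sites, 6.4), 14.6875 / 2)
  expect_error(compute_absolute_density(sites, 0), "positive")
})

test_that("weighted density follows the S1-normalised area weighting", {
  expect_equal(
    compute_weighted_density(c(10, 5, 2, 1), c(100, 180, 260, 400), 2),
    14.1)
  ## all-S1: weighted equals absolute
  expect_equal(compute_weighted_density(c(7, 0, 0, 0),
                                        c(120, NA, NA, NA), 3.5),
               compute_absolute_density(rep(list(1), 7), 3.5))
  expect_equal(compute_weighted_density(c(0, 0, 0, 0), rep(NA, 4), 2), 0)
  expect_error(compute_weighted_density(c(1, 1, 0, 0), c(0, 100, NA, NA), 2),
               "S1 area")
  expect_error(compute_weighted_density(c(1, 1, 0, 0), c(100, NA, NA, NA), 2),
               "S2")
})

test_that("proportions divide by the total and flag zero counts", {
  expect_equal(compute_proportions(c(10, 5, 2, 1)),
               c(10, 5, 2, 1) / 18)
  expect_equal(round(compute_proportions(c(10, 5, 2, 1)), 4),
               c(0.5556, 0.2778, 0.1111, 0.0556))
  expect_equal(compute_proportions(c(7, 0, 0, 0)), c(1, 0, 0, 0))
  expect_equal(compute_proportions(c(2, 1, 0, 3))[c(2, 1, 4, 3)],
               compute_proportions(c(1, 2, 3, 0)))
  expect_warning(p <- compute_proportions(c(0, 0, 0, 0)), "undefined")
  expect_true(all(is.na(p)))
})

test_that("build_profiles combines counts, areas and densities per scan", {
  pop <- generate_population(tiny_params(seed = 4))
  spec <- pop$specimens[pop$specimens$has_scan, ]
  prof <- build_profiles(pop$points, spec)
  expect_equal(nrow(prof), length(unique(pop$points$scan_id)))
  expect_equal(prof$absolute_density,
               (prof$c1 + prof$c2 + prof$c3 + prof$c4) /
                 prof$chelar_area_mm2)
  ## weights >= 1 (areas increase with type) => weighted >= absolute
  expect_true(all(prof$weighted_density >= prof$absolute_density - 1e-9))
  expect_true(all(abs(prof$p1 + prof$p2 + prof$p3 + prof$p4 - 1) < 1e-9))
  ## grouping at 20 um recovers the generator's site structure almost
  ## always: counts match the annotated types closely
  ann <- table(pop$points$annotated_type[!duplicated(
    paste(pop$points$scan_id, pop$points$x_um))])
  expect_gt(sum(prof$c1), 0)
  expect_gt(sum(prof$c4), 0)
  expect_error(build_profiles(pop$points, spec[-1, ]), "no specimen area")
})

test_that("propodus-only denominator increases densities", {
  pop <- generate_population(tiny_params(seed = 4))
  spec <- pop$specimens[pop$specimens$has_scan, ]
  ptot <- build_profiles(pop$points, spec, area_choice = "total")
  pprop <- build_profiles(pop$points, spec, area_choice = "propodus")
  expect_true(all(pprop$absolute_density > ptot$absolute_density))
})
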