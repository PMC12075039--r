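test_that("compute_osm evaluates the shell-preference line", {
  expect_equal(compute_osm(0), 0.502)
  expect_equal(compute_osm(1.0), 4.103)
  expect_equal(round(compute_osm(0.508), 3), 2.331)
  expect_error(compute_osm(-0.1), "non-negative")
})

test_that("generation is deterministic given the seed", {
  p1 <- generate_population(tiny_params(seed = 99))
  p2 <- generate_population(tiny_params(seed = 99))
  expect_identical(p1$specimens, p2$specimens)
  expect_identical(p1$points, p2$points)
  expect_identical(lapply(p1$configurations, `[[`, "landmarks"),
                   lapply(p2$configurations, `[[`, "landmarks"))
  p3 <- generate_population(tiny_params(seed = 100))
  expect_false(identical(p1$specimens$mass_g, p3$specimens$mass_g))
  ## and the caller's RNG state is untouched
  set.seed(5); before <- .Random.seed
  generate_population(tiny_params(seed = 1))
  expect_identical(before, .Random.seed)
})

test_that("population bookkeeping: two claws per crab, masses in range", {
  pop <- generate_population(sim_params(n_female = 5L, n_male = 5L,
                                        seed = 2))
  expect_equal(length(unique(pop$specimens$crab_id)), 10)
  expect_equal(nrow(pop$specimens), 20)
  expect_true(all(table(pop$specimens$crab_id) == 2))
  expect_true(all(pop$specimens$mass_g >= 0.015 &
                    pop$specimens$mass_g <= 1.088))
  ## each point references an existing scan
  expect_true(all(pop$points$scan_id %in% pop$specimens$scan_id))
  ## MJC scans have 16 landmarks, MNC 15
  for (cf in pop$configurations)
    expect_equal(nrow(cf$landmarks), if (cf$claw_type == "MJC") 16 else 15)
})

test_that("empirical mass moments approach the stated parameters", {
  pop <- generate_population(sim_params(n_female = 400L, n_male = 400L,
                                        seed = 3),
                             landmarks = FALSE, points = FALSE)
  m <- pop$specimens$mass_g[pop$specimens$claw_type == "MJC"]
  ## truncation pulls the realised moments slightly inward
  expect_lt(abs(mean(m) - 0.508), 0.03)
  expect_lt(abs(sd(m) - 0.257), 0.05)
})

test_that("heterochely and allometry are built into the population", {
  pop <- generate_population(sim_params(seed = 5), landmarks = FALSE,
                             points = FALSE)
  sp <- pop$specimens
  wide <- merge(sp[sp$claw_type == "MJC", c("crab_id", "chelar_area_total_mm2")],
                sp[sp$claw_type == "MNC", c("crab_id", "chelar_area_total_mm2")],
                by = "crab_id", suffixes = c("_mjc", "_mnc"))
  expect_gt(mean(wide$chelar_area_total_mm2_mjc >
                   wide$chelar_area_total_mm2_mnc), 0.95)
  ## log-log area-mass slope near the allometry parameter
  fit <- lm(log(chelar_area_total_mm2) ~ log(mass_g),
            sp[sp$claw_type == "MJC", ])
  expect_lt(abs(coef(fit)[2] - 0.67), 0.15)
})

test_that("sim_params validates its invariants", {
  expect_error(sim_params(mass_min = 2, mass_max = 1), "mass_min")
  expect_error(sim_params(area_means_um2 = c(S1 = 100, S2 = 90, S3 = 200,
                                             S4 = 300)), "increasing")
  expect_error(sim_params(type_mix = list(MJC = c(0.5, 0.2, 0.2, 0.2),
                                          MNC = c(0.25, 0.25, 0.25, 0.25))),
               "sum to 1")
  expect_error(sim_params(nonsense = 1), "unknown")
  degen <- cbind(1:16, 2 * (1:16))
  rownames(degen) <- paste0("LM", 1:16)
  expect_error(sim_params(mean_shapes = list(MJC = degen,
                                             MNC = claw_template("MNC"))),
               "degenerate")
})

test_that("spatial fields put S1 proximal and S4 distal on the claw", {
  pop <- generate_population(tiny_params(seed = 8))
  ## work in the template frame: S4 sites should sit near the distal
  ## tip (landmark LM1), S1 nearer the proximal body of the claw.
  ## Compare mean distance to the MJC tip across types via annotations.
  pts <- pop$points
  mjc_ids <- pop$specimens$scan_id[pop$specimens$claw_type == "MJC"]
  pts <- pts[pts$scan_id %in% mjc_ids, ]
  tipdist <- function(tp) {
    out <- numeric(0)
    for (sid in unique(pts$scan_id)) {
      cf <- pop$configurations[[sid]]
      if (is.null(cf)) next
      tip <- scaled_coords(cf)["LM1", ]
      sel <- pts$scan_id == sid & pts$annotated_type == tp
      if (!any(sel)) next
      out <- c(out, sqrt((pts$x_um[sel] - tip[1])^2 +
                           (pts$y_um[sel] - tip[2])^2))
    }
    mean(out)
  }
  expect_lt(tipdist("S4"), tipdist("S1"))
})

test_that("write_population emits readable artifacts plus truth.json", {
  pop <- generate_population(tiny_params(seed = 13))
  dir <- withr::local_tempdir()
  write_population(pop, dir)
  expect_true(file.exists(file.path(dir, "mjc.tps")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  spec <- read_specimen_table(file.path(dir, "specimens.csv"))
  pts <- read_site_table(file.path(dir, "points.csv"))
  expect_equal(nrow(spec), sum(pop$specimens$has_scan))
  expect_equal(nrow(pts), nrow(pop$points))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$seed, 13)
  expect_equal(truth$density_base, pop$truth$density_base)
})
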