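## small balanced repeated-measures dataset generator
make_lmm_data <- function(n_crab = 24, sd_crab = 0.3, sd_res = 0.2,
                          beta_mass = 1.0, claw_eff = 0.5,
                          inter = 0, seed = 1) {
  set.seed(seed)
  crab <- sprintf("c%02d", 1:n_crab)
  sex <- rep(c("F", "M"), length.out = n_crab)
  mass <- runif(n_crab, 0.1, 1)
  u <- rnorm(n_crab, 0, sd_crab)
  d <- expand.grid(crab_id = crab, claw_type = c("MJC", "MNC"),
                   stringsAsFactors = FALSE)
  i <- match(d$crab_id, crab)
  d$sex <- sex[i]; d$mass_g <- mass[i]
  d$y <- 2 + beta_mass * log(d$mass_g) + claw_eff * (d$claw_type == "MNC") +
    inter * (d$sex == "F" & d$claw_type == "MJC") +
    u[i] + rnorm(nrow(d), 0, sd_res)
  d$log_mass <- log(d$mass_g)
  d
}

test_that("fit_lmm recovers variance components and a boundary fit", {
  d <- make_lmm_data(n_crab = 40, sd_crab = 0.5, sd_res = 0.2, seed = 2)
  f <- fit_lmm(model_spec("y", c("log_mass", "sex", "claw_type")), d)
  expect_true(f$converged)
  expect_lt(abs(sqrt(f$varcomp["sigma2_group"]) - 0.5), 0.2)
  expect_lt(abs(sqrt(f$varcomp["sigma2_resid"]) - 0.2), 0.1)
  ## no crab-level variance: estimate pinned at the boundary
  d0 <- make_lmm_data(n_crab = 40, sd_crab = 0, sd_res = 0.3, seed = 3)
  f0 <- suppressMessages(fit_lmm(model_spec("y", "log_mass"), d0))
  expect_lt(f0$varcomp["sigma2_group"], 0.01)
})

test_that("Satterthwaite df matches closed-form ANOVA df on balanced designs", {
  ## between-crab factor, balanced, 3 replicates per crab:
  ## classical denominator df for sex = n_crab - 2
  set.seed(4)
  n_crab <- 10
  crab <- sprintf("c%02d", 1:n_crab)
  sex <- rep(c("F", "M"), each = n_crab / 2)
  u <- rnorm(n_crab, 0, 1)
  d <- data.frame(crab_id = rep(crab, each = 3),
                  sex = rep(sex, each = 3))
  d$y <- 1 + 0.5 * (d$sex == "M") + u[match(d$crab_id, crab)] +
    rnorm(nrow(d), 0, 0.5)
  f <- fit_lmm(model_spec("y", "sex"), d)
  expect_equal(f$anova$df2[f$anova$term == "sex"], n_crab - 2,
               tolerance = 0.05)
  ## within-crab factor: df = n_obs - n_crab - 1
  d$claw_type <- rep(c("MJC", "MNC", "MJC"), n_crab)
  d2 <- d[rep(seq_len(nrow(d))[seq(1, nrow(d), 3)], each = 2), ]
  d2$claw_type <- rep(c("MJC", "MNC"), n_crab)
  d2$y <- d2$y + 0.3 * (d2$claw_type == "MNC") + rnorm(nrow(d2), 0, 0.4)
  f2 <- fit_lmm(model_spec("y", c("sex", "claw_type")), d2)
  expect_equal(f2$anova$df2[f2$anova$term == "claw_type"],
               nrow(d2) - n_crab - 1, tolerance = 0.1)
})

test_that("estimates are invariant to relabelling grouping levels", {
  d <- make_lmm_data(seed = 6)
  f1 <- fit_lmm(model_spec("y", c("log_mass", "claw_type")), d)
  d2 <- d
  d2$crab_id <- paste0("zz_", rev(as.integer(factor(d$crab_id))))
  f2 <- fit_lmm(model_spec("y", c("log_mass", "claw_type")), d2)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
  expect_equal(f1$anova$F, f2$anova$F, tolerance = 1e-6)
})

test_that("slope coverage: truth within 2 SE in most seeded replicates", {
  ## scaled down from a 200-seed coverage study to keep the suite fast
  hits <- vapply(1:25, function(s) {
    d <- make_lmm_data(n_crab = 60, beta_mass = 1.02, seed = 100 + s)
    f <- fit_lmm(model_spec("y", c("log_mass", "sex", "claw_type")), d)
    est <- f$coefficients["log_mass"]
    se <- sqrt(diag(as.matrix(vcov(f$model))))[
      which(names(f$coefficients) == "log_mass")]
    abs(est - 1.02) < 2 * se
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("rank-deficient designs fail loudly", {
  d <- make_lmm_data(seed = 8)
  d$dup <- d$log_mass
  expect_error(fit_lmm(model_spec("y", c("log_mass", "dup")), d),
               "rank-deficient")
})

test_that("log transform drops non-positive outcomes with a message", {
  d <- make_lmm_data(seed = 9)
  d$dens <- exp(d$y)
  d$dens[1:2] <- 0
  expect_message(f <- fit_lmm(model_spec("dens", "log_mass",
                                         transform = "log"), d),
                 "dropping 2")
  expect_equal(f$n_dropped, 2)
})

test_that("icc_random_intercept reproduces the variance-ratio examples", {
  expect_equal(icc_random_intercept(c(0, 0.5)), 0)
  expect_equal(icc_random_intercept(c(0.3, 0.3)), 0.5)
  expect_equal(round(icc_random_intercept(c(0.031, 0.0446)), 2), 0.41)
  expect_warning(v <- icc_random_intercept(c(0, 0)), "zero")
  expect_true(is.na(v))
})

test_that("stepwise_reduce prunes null interactions, keeps protected ones", {
  spec0 <- model_spec("y", c("log_mass", "sex", "claw_type",
                             "sex:claw_type"),
                      protected = "sex:claw_type")
  d <- make_lmm_data(seed = 10)
  ## no prunable interactions: unchanged
  r <- stepwise_reduce(spec0, d)
  expect_length(r$removed, 0)
  ## protected interaction stays even when clearly null
  labs <- r$fit$anova$term
  expect_true("sex:claw_type" %in% labs)
  ## a null mass:claw interaction is pruned, true mass:sex kept
  set.seed(11)
  keep_rate <- vapply(1:15, function(s) {
    d2 <- make_lmm_data(n_crab = 60, seed = 200 + s)
    d2$y <- d2$y + 0.8 * d2$log_mass * (d2$sex == "M")
    sat <- model_spec("y", c("log_mass", "sex", "claw_type",
                             "log_mass:sex", "log_mass:claw_type",
                             "sex:claw_type"),
                      protected = "sex:claw_type")
    r2 <- stepwise_reduce(sat, d2)
    kept <- r2$fit$anova$term
    ("log_mass:sex" %in% kept) && !("log_mass:claw_type" %in% kept)
  }, logical(1))
  expect_gte(mean(keep_rate), 0.75)
})

test_that("run_analysis_suite fits the whole outcome family", {
  pop <- generate_population(sim_params(n_female = 12L, n_male = 12L,
                                        seed = 12, p_scan_mnc = 1,
                                        missing_landmark_rate = 0),
                             landmarks = FALSE)
  spec <- pop$specimens[pop$specimens$has_scan, ]
  prof <- build_profiles(pop$points, spec)
  suite <- suppressMessages(run_analysis_suite(prof, saturated = FALSE))
  expect_setequal(names(suite$fits),
                  c("chelar_area", "absolute_density", "weighted_density",
                    paste0("prop_S", 1:4)))
  ## one row per fixed term per outcome
  for (nm in names(suite$fits)) {
    a <- suite$fits[[nm]]$fit$anova
    expect_setequal(a$term,
                    c(if (nm == "chelar_area") "log_mass" else "mass_g",
                      "sex", "claw_type", "sex:claw_type"))
  }
  ## chelar area: strong mass and claw effects by construction
  a <- suite$fits$chelar_area$fit$anova
  expect_lt(a$p[a$term == "log_mass"], 1e-6)
  expect_lt(a$p[a$term == "claw_type"], 1e-6)
})
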