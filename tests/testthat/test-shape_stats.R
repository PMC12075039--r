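test_that("pillai_trace matches the eigenvalue identity and limits", {
  expect_equal(pillai_trace(matrix(0, 3, 3), diag(3)), 0)
  ## E -> 0 limit: pillai equals rank of H
  H1 <- tcrossprod(c(1, 2, 0))
  expect_equal(pillai_trace(H1, diag(3) * 1e-8), 1, tolerance = 1e-6)
  set.seed(6)
  for (i in 1:5) {
    A <- crossprod(matrix(rnorm(9), 3)); B <- crossprod(matrix(rnorm(9), 3))
    lam <- Re(eigen(solve(B) %*% A)$values)
    expect_equal(pillai_trace(A, B), sum(lam / (1 + lam)),
                 tolerance = 1e-10)
  }
  expect_error(pillai_trace(matrix(0, 2, 2), matrix(0, 2, 2)), "singular")
})

test_that("mahalanobis_between: identity, zero, hand-inverted diagonal", {
  expect_equal(mahalanobis_between(c(1, 2), c(4, 6), diag(2)), 5)
  expect_equal(mahalanobis_between(c(3, 3), c(3, 3), diag(2)), 0)
  expect_equal(mahalanobis_between(c(2, 0), c(0, 0), diag(c(4, 1))), 1)
  expect_error(mahalanobis_between(c(1, 0), c(0, 0), matrix(1, 2, 2)),
               "singular")
})

test_that("goodall_f: zero for identical means, label-symmetric, null mean ~ 1", {
  set.seed(10)
  base <- rand_shape(6)
  shapes <- array(dim = c(6, 2, 8))
  for (i in 1:8) shapes[, , i] <- base + matrix(rnorm(12, 0, 0.05), ncol = 2)
  fit <- align_gpa(shapes)
  g <- factor(rep(c("a", "b"), 4))
  f1 <- goodall_f(fit, g)
  f2 <- goodall_f(fit, factor(rep(c("b", "a"), 4)))
  expect_equal(f1$statistic, f2$statistic, tolerance = 1e-10)
  expect_equal(f1$df1, 2 * 6 - 4)
  ## identical group means: duplicate each shape into both groups
  dup <- array(dim = c(6, 2, 16))
  dup[, , 1:8] <- fit$aligned; dup[, , 9:16] <- fit$aligned
  fit_dup <- align_gpa(dup)
  ## groups a and b hold identical shape sets => identical means, F ~ 0
  fd <- goodall_f(fit_dup, factor(rep(c("a", "b"), each = 8)))
  expect_lt(fd$statistic, 1e-10)
  ## null calibration (scaled down): mean F over replicates near 1
  fs <- replicate(60, {
    arr <- array(dim = c(6, 2, 10))
    for (i in 1:10) arr[, , i] <- base + matrix(rnorm(12, 0, 0.05), ncol = 2)
    goodall_f(align_gpa(arr), factor(rep(c("a", "b"), 5)))$statistic
  })
  expect_gt(mean(fs), 0.75)
  expect_lt(mean(fs), 1.35)
})

test_that("permutation_test conventions and exhaustive agreement", {
  ## label-independent statistic: p = 1
  r <- permutation_test(function(l) 1, rep(c("a", "b"), 5), n_perm = 99,
                        seed = 2)
  expect_equal(r$p, 1)
  ## observed exceeding every permutation: p = 1/(n+1) is the floor
  x <- c(10, 11, 12, 0.1, 0.2, 0.3)
  lab <- rep(c("a", "b"), each = 3)
  stat <- function(l) abs(mean(x[l == "a"]) - mean(x[l == "b"]))
  r2 <- permutation_test(stat, lab, n_perm = 199, seed = 3)
  expect_gte(r2$p, 1 / 200)
  expect_lt(r2$p, 0.12)
  ## exhaustive enumeration oracle on 6 scans
  ex <- permutation_test(stat, lab, exhaustive = TRUE)
  mc <- permutation_test(stat, lab, n_perm = 4999, seed = 9)
  expect_equal(ex$n_perm, 720)
  expect_lt(abs(mc$p - ex$p), 0.03)
  ## reproducibility bit for bit
  a <- permutation_test(stat, lab, n_perm = 199, seed = 11)
  b <- permutation_test(stat, lab, n_perm = 199, seed = 11)
  expect_identical(a, b)
})

test_that("whole-crab permutation keeps within-crab labels intact", {
  unit <- rep(1:4, each = 2)
  lab <- rep(c("F", "F", "M", "M"), each = 2)[1:8]
  seen <- new.env()
  stat <- function(l) {
    ## within every unit the label must be constant
    expect_true(all(tapply(l, unit, function(z) length(unique(z))) == 1))
    sum(l == "F")
  }
  permutation_test(stat, lab, n_perm = 99, seed = 1, unit = unit)
  succeed()
})

test_that("run_cva on a 2-group toy matches longhand MANOVA", {
  ## 6 'shapes' engineered so aligned coordinates are exactly known is
  ## brittle; instead check the CVA internals against the textbook
  ## computation on the projected scores of a real fit
  set.seed(12)
  base <- rand_shape(5)
  arr <- array(dim = c(5, 2, 10))
  for (i in 1:10) arr[, , i] <- base + matrix(rnorm(10, 0, 0.08), ncol = 2)
  fit <- align_gpa(arr)
  grp <- data.frame(g = rep(c("a", "b"), 5))
  cv <- run_cva(fit, grp, "g", n_perm = 199, seed = 5)
  X <- t(apply(fit$aligned, 3, identity))
  pc <- prcomp(X)
  keep <- which(pc$sdev^2 > 1e-12 * pc$sdev[1]^2)[1:cv$q]
  S <- pc$x[, keep, drop = FALSE]
  orc <- oracle_manova(S, grp$g)
  expect_equal(cv$pillai, orc$pillai, tolerance = 1e-8)
  Sw <- orc$E / (10 - 2)
  d <- colMeans(S[grp$g == "a", ]) - colMeans(S[grp$g == "b", ])
  expect_equal(cv$mahalanobis[1, 2],
               sqrt(drop(t(d) %*% solve(Sw) %*% d)), tolerance = 1e-8)
})

test_that("CVA separates disjoint groups and stays null under exchange", {
  set.seed(19)
  a <- rand_shape(6); b <- rand_shape(6)
  arr <- array(dim = c(6, 2, 12))
  for (i in 1:6) arr[, , i] <- a + matrix(rnorm(12, 0, 0.01), ncol = 2)
  for (i in 7:12) arr[, , i] <- b + matrix(rnorm(12, 0, 0.01), ncol = 2)
  fit <- align_gpa(arr)
  grp <- data.frame(g = rep(c("a", "b"), each = 6))
  cv <- run_cva(fit, grp, "g", n_perm = 199, seed = 1)
  expect_gt(cv$pillai, 0.95)
  expect_gt(cv$mahalanobis[1, 2], 5)
  ## near the attainable floor (high-dimensional permutations can tie)
  expect_lte(cv$perm_p$pillai$p, 2 / 200)
  ## same-distribution groups: Pillai small on average, p typically large
  ps <- replicate(20, {
    arr0 <- array(dim = c(6, 2, 12))
    for (i in 1:12) arr0[, , i] <- a + matrix(rnorm(12, 0, 0.05), ncol = 2)
    f0 <- align_gpa(arr0)
    run_cva(f0, grp, "g", n_perm = 99, seed = i)$perm_p$pillai$p
  })
  expect_gt(mean(ps > 0.05), 0.7)
})

test_that("CVA errors on undersized groups", {
  set.seed(4)
  arr <- array(rnorm(5 * 2 * 4), dim = c(5, 2, 4))
  fit <- align_gpa(arr)
  expect_error(run_cva(fit, data.frame(g = c("a", "a", "a", "b")), "g"),
               "fewer than 2")
})

test_that("procrustes_anova decomposes claw/sex/crab strata", {
  pop <- generate_population(tiny_params(seed = 23, n_replicates = 3L,
                                         sex_shape_effect = 0.15))
  harm <- harmonise(pop$configurations)
  fit <- align_gpa(harm)
  base_scan <- sub("_r[0-9]+$", "", fit$scan_ids)
  spec <- pop$specimens[match(base_scan, pop$specimens$scan_id), ]
  design <- data.frame(claw_type = spec$claw_type, sex = spec$sex,
                       crab_id = spec$crab_id)
  tab <- procrustes_anova(fit, design, c("claw_type", "sex", "crab_id"))
  expect_setequal(tab$effect, c("claw_type", "sex", "crab_id", "Residual"))
  expect_true(all(tab$SS >= 0))
  expect_true(all(tab$df > 0))
  ## claw-type displacement is huge by construction
  expect_lt(tab$p[tab$effect == "claw_type"], 1e-6)
  ## pillai per effect within multivariate bounds
  expect_true(all(tab$pillai[!is.na(tab$pillai)] >= 0))
  ## without replicates, individual F is unavailable
  pop1 <- generate_population(tiny_params(seed = 23))
  fit1 <- align_gpa(harmonise(pop1$configurations))
  spec1 <- pop1$specimens[match(fit1$scan_ids, pop1$specimens$scan_id), ]
  d1 <- data.frame(claw_type = spec1$claw_type, sex = spec1$sex,
                   crab_id = spec1$crab_id)
  expect_error(procrustes_anova(fit1, d1, c("claw_type", "sex", "crab_id")),
               "replicate")
})

test_that("shape statistics are invariant to rotating the aligned frame", {
  set.seed(33)
  base <- rand_shape(6)
  arr <- array(dim = c(6, 2, 10))
  for (i in 1:10) arr[, , i] <- base + matrix(rnorm(12, 0, 0.05), ncol = 2)
  fit <- align_gpa(arr)
  grp <- data.frame(g = rep(c("a", "b"), 5))
  cv1 <- run_cva(fit, grp, "g", n_perm = 99, seed = 1)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  fit2 <- fit
  for (i in 1:10) fit2$aligned[, , i] <- fit$aligned[, , i] %*% R
  fit2$mean_shape <- fit$mean_shape %*% R
  cv2 <- run_cva(fit2, grp, "g", n_perm = 99, seed = 1)
  expect_equal(cv1$pillai, cv2$pillai, tolerance = 1e-8)
  expect_equal(cv1$mahalanobis, cv2$mahalanobis, tolerance = 1e-6)
})
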