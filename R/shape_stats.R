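## Group-separation statistics on aligned shapes: CVA, Mahalanobis and
## Procrustes distances, Pillai's trace, Goodall's F, permutation
## inference, and Goodall-style Procrustes ANOVA.

## run code with a temporary RNG state, restoring the caller's
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## flatten a gpa_fit's aligned array to an n x 2k matrix
.shape_matrix <- function(fit) {
  arr <- fit$aligned
  k <- dim(arr)[1]; n <- dim(arr)[3]
  t(matrix(arr, nrow = 2L * k, ncol = n))
}

## project shape coordinates onto non-degenerate principal components
.shape_scores <- function(X, max_dim, tol = 1e-12) {
  Xc <- sweep(X, 2, colMeans(X))
  pc <- prcomp(Xc, center = FALSE)
  ev <- pc$sdev^2
  keep <- which(ev > tol * ev[1])
  keep <- keep[seq_len(min(length(keep), max_dim))]
  list(scores = pc$x[, keep, drop = FALSE],
       rotation = pc$rotation[, keep, drop = FALSE],
       center = colMeans(X))
}

## between (H) and within (E) SSCP matrices for scores S and factor f
.sscp <- function(S, f) {
  f <- factor(f)
  grand <- colMeans(S)
  H <- matrix(0, ncol(S), ncol(S))
  E <- matrix(0, ncol(S), ncol(S))
  for (lv in levels(f)) {
    Si <- S[f == lv, , drop = FALSE]
    mi <- colMeans(Si)
    d <- mi - grand
    H <- H + nrow(Si) * tcrossprod(d)
    E <- E + crossprod(sweep(Si, 2, mi))
  }
  list(H = H, E = E)
}

#' Pillai's trace from between- and within-group SSCP matrices
#'
#' `trace(H (H + E)^{-1})`, bounded by `min(g - 1, p)`.
#'
#' @param H between-group sums-of-squares-and-cross-products matrix.
#' @param E within-group SSCP matrix (same dimension).
#' @return scalar trace statistic.
#' @export
pillai_trace <- function(H, E) {
  if (!all(dim(H) == dim(E))) stop("H and E must have equal dimensions")
  T <- H + E
  if (rcond(T) < 1e-14) stop("pillai_trace: H + E is singular")
  sum(diag(H %*% solve(T)))
}

#' Mahalanobis distance between two group means
#'
#' `sqrt((a - b)' Sigma^{-1} (a - b))` with `Sigma` the pooled
#' within-group covariance in the projected score space.
#'
#' @param mean_a,mean_b numeric mean vectors.
#' @param pooled_cov positive-definite pooled covariance matrix.
#' @return non-negative scalar.
#' @export
mahalanobis_between <- function(mean_a, mean_b, pooled_cov) {
  d <- as.numeric(mean_a - mean_b)
  if (length(d) != nrow(pooled_cov)) stop("dimension mismatch")
  if (rcond(pooled_cov) < 1e-14)
    stop("mahalanobis_between: singular pooled covariance")
  sqrt(max(0, drop(crossprod(d, solve(pooled_cov, d)))))
}

#' Goodall's F for group separation of aligned shapes
#'
#' The ratio of between-group to within-group Procrustes variation,
#' using full Procrustes distances on the unit-size aligned shapes:
#' `F = [sum_g n_g d^2(mean_g, grand) / (g-1)] /
#'      [sum_i d^2(x_i, mean_{g(i)}) / (N-g)]`
#' with degrees of freedom `(g-1) m` and `(N-g) m`, `m = 2k - 4`.
#'
#' @param fit a [align_gpa()] fit.
#' @param groups factor (length = number of aligned scans) with >= 2
#'   levels, each with >= 2 members.
#' @return list with `statistic`, `df1`, `df2`, `p` (F approximation).
#' @export
goodall_f <- function(fit, groups) {
  arr <- fit$aligned
  groups <- factor(groups)
  n <- dim(arr)[3]
  if (length(groups) != n) stop("groups length must match scan count")
  g <- nlevels(groups)
  if (g < 2L) stop("goodall_f: need at least 2 groups")
  if (any(table(groups) < 2L)) stop("goodall_f: every group needs >= 2 members")
  k <- dim(arr)[1]
  m <- 2L * k - 4L
  grand <- apply(arr, c(1, 2), mean)
  ss_b <- 0; ss_w <- 0
  for (lv in levels(groups)) {
    idx <- which(groups == lv)
    gm <- apply(arr[, , idx, drop = FALSE], c(1, 2), mean)
    ss_b <- ss_b + length(idx) * procrustes_distance(gm, grand)^2
    for (i in idx) ss_w <- ss_w + procrustes_distance(arr[, , i], gm)^2
  }
  if (ss_w <= 0) stop("goodall_f: zero within-group variation")
  stat <- (ss_b / (g - 1)) / (ss_w / (n - g))
  df1 <- (g - 1) * m
  df2 <- (n - g) * m
  list(statistic = stat, df1 = df1, df2 = df2,
       p = stats::pf(stat, df1, df2, lower.tail = FALSE))
}

#' Permutation test of a label-dependent statistic
#'
#' Monte-Carlo permutation p-value `(b + 1) / (n_perm + 1)` where `b`
#' counts permuted statistics at least as large as the observed one.
#' Labels are permuted within exchangeable units: when `unit` is given
#' and the label is constant within each unit, whole units swap labels
#' (respecting repeated measures); otherwise labels permute freely.
#'
#' @param statistic function taking a label vector, returning a scalar.
#' @param labels observed labels.
#' @param n_perm number of random permutations (>= 99), ignored when
#'   `exhaustive = TRUE`.
#' @param seed integer seed; the global RNG state is untouched.
#' @param unit optional vector of exchangeability-unit ids (e.g. crab).
#' @param exhaustive enumerate all distinct label arrangements instead
#'   of sampling (only feasible for small problems).
#' @return list with `p`, `observed`, `n_perm`, `mc_se` (binomial
#'   Monte-Carlo standard error of `p`; 0 when exhaustive).
#' @export
permutation_test <- function(statistic, labels, n_perm = 10000L,
                             seed = 1L, unit = NULL, exhaustive = FALSE) {
  obs <- statistic(labels)
  eps <- 1e-12 * max(1, abs(obs))
  unit_mode <- FALSE
  if (!is.null(unit)) {
    per_unit <- tapply(as.character(labels), unit,
                       function(z) length(unique(z)))
    if (all(per_unit == 1L)) unit_mode <- TRUE
  }
  if (unit_mode) {
    uids <- unique(as.character(unit))
    ulab <- vapply(uids, function(u)
      as.character(labels[match(u, as.character(unit))]), character(1))
    expand <- function(pl) pl[match(as.character(unit), uids)]
  }
  if (exhaustive) {
    base_lab <- if (unit_mode) ulab else as.character(labels)
    perms <- .all_permutations(length(base_lab))
    stats <- apply(perms, 1, function(ix) {
      pl <- base_lab[ix]
      statistic(if (unit_mode) expand(pl) else pl)
    })
    p <- mean(stats >= obs - eps)
    return(list(p = p, observed = obs, n_perm = nrow(perms), mc_se = 0))
  }
  if (n_perm < 99L) stop("n_perm must be >= 99")
  b <- .with_seed(seed, {
    cnt <- 0L
    for (i in seq_len(n_perm)) {
      pl <- if (unit_mode) expand(sample(ulab)) else sample(labels)
      if (statistic(pl) >= obs - eps) cnt <- cnt + 1L
    }
    cnt
  })
  p <- (b + 1) / (n_perm + 1)
  list(p = p, observed = obs, n_perm = n_perm,
       mc_se = sqrt(p * (1 - p) / (n_perm + 1)))
}

.all_permutations <- function(n) {
  if (n > 8L) stop("exhaustive enumeration limited to n <= 8")
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 1L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (j in seq_len(nrow(sub))) {
      out[r, ] <- c(i, rest[sub[j, ]])
      r <- r + 1L
    }
  }
  out
}

#' Canonical variate analysis of aligned shapes
#'
#' Projects the aligned coordinates onto their non-degenerate principal
#' subspace (aligned 2-D shapes of k landmarks span at most `2k - 4`
#' dimensions; components with eigenvalues below `1e-12` of the largest
#' are discarded, and at most `N - g` are retained so the pooled
#' within-group covariance is invertible), then computes canonical
#' axes maximising between- relative to within-group variance, pairwise
#' Mahalanobis and Procrustes distances between groups, Pillai's trace,
#' Goodall's F, and permutation p-values for the latter two.
#'
#' Permutations respect the crab as the exchangeable unit whenever a
#' `crab_id` column is present in `groups` and the tested factor is
#' constant within crabs.
#'
#' @param fit a [align_gpa()] fit.
#' @param groups data.frame of per-scan factors (rows in scan order);
#'   must contain `factor`; a `crab_id` column activates whole-crab
#'   permutation.
#' @param factor name of the grouping column to test.
#' @param n_perm permutations for the significance tests.
#' @param seed permutation seed.
#' @param perm_stats which statistics to test by permutation (both by
#'   default; restrict to one to halve the permutation cost).
#' @return object of class `cva_result`: canonical axes and scores,
#'   pairwise `mahalanobis` and `procrustes_dist` group matrices,
#'   `pillai`, `goodall` (list), `perm_p` (named list with Monte-Carlo
#'   SEs), and the retained dimensionality `q`.
#' @export
run_cva <- function(fit, groups, factor, n_perm = 10000L, seed = 1L,
                    perm_stats = c("pillai", "goodall")) {
  perm_stats <- match.arg(perm_stats, several.ok = TRUE)
  f <- base::factor(groups[[factor]])
  n <- dim(fit$aligned)[3]
  if (length(f) != n) stop("groups must have one row per aligned scan")
  tab <- table(f)
  if (nlevels(f) < 2L) stop("run_cva: need >= 2 groups")
  if (any(tab < 2L))
    stop(sprintf("run_cva: group '%s' has fewer than 2 scans",
                 names(tab)[which(tab < 2L)[1]]))
  g <- nlevels(f)
  X <- .shape_matrix(fit)
  proj <- .shape_scores(X, max_dim = n - g)
  S <- proj$scores
  q <- ncol(S)
  sc <- .sscp(S, f)
  Sw <- sc$E / (n - g)
  if (rcond(Sw) < 1e-12)
    stop(sprintf(
      "run_cva: singular pooled covariance in %d retained dimensions", q))
  ## canonical axes: eigenvectors of Sw^{-1} H, scaled to unit
  ## within-group variance of scores
  eig <- eigen(solve(Sw, sc$H))
  n_axes <- min(g - 1L, q)
  axes <- Re(eig$vectors[, seq_len(n_axes), drop = FALSE])
  for (j in seq_len(n_axes)) {
    a <- axes[, j]
    axes[, j] <- a / sqrt(drop(crossprod(a, Sw %*% a)))
  }
  cv_scores <- S %*% axes
  ## pairwise group distances
  lv <- levels(f)
  maha <- matrix(0, g, g, dimnames = list(lv, lv))
  pdist <- matrix(0, g, g, dimnames = list(lv, lv))
  means <- lapply(lv, function(l) colMeans(S[f == l, , drop = FALSE]))
  gm_shapes <- lapply(lv, function(l)
    apply(fit$aligned[, , f == l, drop = FALSE], c(1, 2), mean))
  for (i in seq_len(g)) for (j in seq_len(g)) if (i < j) {
    maha[i, j] <- maha[j, i] <-
      mahalanobis_between(means[[i]], means[[j]], Sw)
    pdist[i, j] <- pdist[j, i] <-
      procrustes_distance(gm_shapes[[i]], gm_shapes[[j]])
  }
  pillai <- pillai_trace(sc$H, sc$E)
  goodall <- goodall_f(fit, f)
  unit <- if ("crab_id" %in% names(groups)) groups$crab_id else NULL
  stat_pillai <- function(lab) {
    s <- .sscp(S, lab)
    pillai_trace(s$H, s$E)
  }
  stat_goodall <- function(lab) goodall_f(fit, lab)$statistic
  perm_p <- list()
  if ("pillai" %in% perm_stats)
    perm_p$pillai <- permutation_test(stat_pillai, f, n_perm = n_perm,
                                      seed = seed, unit = unit)
  if ("goodall" %in% perm_stats)
    perm_p$goodall <- permutation_test(stat_goodall, f, n_perm = n_perm,
                                       seed = seed + 1L, unit = unit)
  structure(list(canonical_axes = axes, scores = cv_scores,
                 pc_rotation = proj$rotation, mahalanobis = maha,
                 procrustes_dist = pdist, pillai = pillai,
                 goodall = goodall, perm_p = perm_p, q = q,
                 factor = factor, levels = lv, n = n),
            class = "cva_result")
}

#' @exportS3Method base::print
print.cva_result <- function(x, ...) {
  cat(sprintf("<cva_result> factor '%s' (%s), n = %d, %d dims retained\n",
              x$factor, paste(x$levels, collapse = " vs "), x$n, x$q))
  pp <- function(z) if (is.null(z)) NA_real_ else z$p
  cat(sprintf("  Pillai's trace = %.4f (perm p = %.4g)\n",
              x$pillai, pp(x$perm_p$pillai)))
  cat(sprintf("  Goodall's F = %.4f (df %d, %d; perm p = %.4g)\n",
              x$goodall$statistic, x$goodall$df1, x$goodall$df2,
              pp(x$perm_p$goodall)))
  if (length(x$levels) == 2L)
    cat(sprintf("  Mahalanobis D = %.4f, Procrustes d = %.4f\n",
                x$mahalanobis[1, 2], x$procrustes_dist[1, 2]))
  invisible(x)
}

#' Goodall-style Procrustes ANOVA
#'
#' Sequential decomposition of the total Procrustes sum of squares of
#' the aligned coordinates over an ordered list of effects, in the
#' repeated-measures claw design: fixed effects (claw type,
#' sex) are tested against the individual-crab mean square, and the
#' individual effect against the digitising-replicate residual.
#' Degrees of freedom follow the Goodall convention (`df x m`, with
#' `m = 2k - 4` shape dimensions).  Pillai's trace is reported per
#' effect from the corresponding multivariate SSCPs in the
#' non-degenerate principal subspace.
#'
#' @param fit a [align_gpa()] fit.
#' @param design data.frame of per-scan factors, containing every name
#'   in `effects` (and `crab_id` if listed).
#' @param effects ordered character vector of effect names; if
#'   `"crab_id"` is included it is treated as the individual (random)
#'   stratum.
#' @return data.frame of class `procrustes_anova` with one row per
#'   effect plus a residual row: SS, df, MS, F, Pillai trace, p.
#' @export
procrustes_anova <- function(fit, design, effects) {
  Y <- .shape_matrix(fit)
  n <- nrow(Y)
  if (nrow(design) != n) stop("design must have one row per aligned scan")
  for (e in effects) if (!e %in% names(design))
    stop(sprintf("effect '%s' not in design", e))
  k <- dim(fit$aligned)[1]
  m <- 2L * k - 4L
  Yc <- sweep(Y, 2, colMeans(Y))
  ss_total <- sum(Yc^2)
  X <- matrix(1, n, 1)
  fit_prev <- qr.fitted(qr(X), Yc)
  ss_prev <- sum(fit_prev^2)
  df_prev <- 1L
  rows <- list()
  sscp_H <- list()
  for (e in effects) {
    X <- cbind(X, model.matrix(~ factor(design[[e]]))[, -1, drop = FALSE])
    qx <- qr(X)
    fit_cur <- qr.fitted(qx, Yc)
    ss_cur <- sum(fit_cur^2)
    rows[[e]] <- data.frame(
      effect = e, SS = ss_cur - ss_prev,
      df = (qx$rank - df_prev) * m, stringsAsFactors = FALSE)
    sscp_H[[e]] <- crossprod(fit_cur - fit_prev)
    ss_prev <- ss_cur; df_prev <- qx$rank
    fit_prev <- fit_cur
  }
  resid <- Yc - fit_prev
  df_resid_units <- n - df_prev
  rows[["Residual"]] <- data.frame(effect = "Residual",
                                   SS = ss_total - ss_prev,
                                   df = df_resid_units * m,
                                   stringsAsFactors = FALSE)
  tab <- do.call(rbind, rows)
  tab$MS <- ifelse(tab$df > 0, tab$SS / tab$df, NA_real_)
  ## error strata: fixed effects vs individual MS (if present), the
  ## individual vs residual
  has_crab <- "crab_id" %in% effects
  if (has_crab && !any(duplicated(design[, effects, drop = FALSE])))
    stop(paste("procrustes_anova: individual F requires replicate",
               "digitisations (no duplicated design rows found)"))
  ms_crab <- if (has_crab) tab$MS[tab$effect == "crab_id"] else NA_real_
  ms_resid <- tab$MS[tab$effect == "Residual"]
  df_crab <- if (has_crab) tab$df[tab$effect == "crab_id"] else NA_real_
  df_resid <- tab$df[tab$effect == "Residual"]
  if (has_crab && df_resid_units <= 0)
    stop("procrustes_anova: individual F requires replicate digitisations")
  tab$F <- NA_real_; tab$den_df <- NA_real_
  for (i in seq_len(nrow(tab))) {
    e <- tab$effect[i]
    if (e == "Residual") next
    if (e == "crab_id") {
      if (df_resid_units > 0) {
        tab$F[i] <- tab$MS[i] / ms_resid
        tab$den_df[i] <- df_resid
      }
    } else if (has_crab) {
      tab$F[i] <- tab$MS[i] / ms_crab
      tab$den_df[i] <- df_crab
    } else if (df_resid_units > 0) {
      tab$F[i] <- tab$MS[i] / ms_resid
      tab$den_df[i] <- df_resid
    }
  }
  tab$p <- ifelse(is.na(tab$F), NA_real_,
                  stats::pf(tab$F, tab$df, tab$den_df, lower.tail = FALSE))
  ## per-effect Pillai trace in the non-degenerate subspace
  proj <- .shape_scores(Yc, max_dim = n - 1L)
  Rm <- proj$rotation
  E_sscp <- crossprod(resid %*% Rm)
  tab$pillai <- NA_real_
  for (e in effects) {
    Hq <- t(Rm) %*% sscp_H[[e]] %*% Rm
    tot <- Hq + E_sscp
    tab$pillai[tab$effect == e] <-
      if (rcond(tot) > 1e-14) sum(diag(Hq %*% solve(tot))) else NA_real_
  }
  rownames(tab) <- NULL
  class(tab) <- c("procrustes_anova", "data.frame")
  tab
}
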