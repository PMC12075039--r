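## Linear mixed-effects models with crab-level random intercepts.
##
## Estimation is REML via lme4; per-term F tests use
## Satterthwaite-approximated denominator degrees of freedom computed
## here from the REML criterion: the covariance of the variance
## parameters is taken as twice the inverse Hessian of the REML
## deviance in (theta, sigma), and the df of a contrast L is
## 2 (L' V L)^2 / Var(L' V L), with the variance obtained by the delta
## method through finite-difference gradients.  Factors are coded with
## sum-to-zero contrasts so the per-term tests are marginal (type III).

#' Model specification for the mixed-effects stage
#'
#' @param outcome name of the outcome column.
#' @param fixed character vector of fixed-effect terms (may include
#'   `a*b` / `a:b` interaction notation).
#' @param random grouping factor for the random intercept.
#' @param transform `"identity"` or `"log"` applied to the outcome;
#'   non-positive outcomes are dropped from log-scale models with a
#'   message.
#' @param protected interaction terms never removed by
#'   [stepwise_reduce()] (e.g. `"sex:claw_type"`, the heterochely-by-
#'   dimorphism hypothesis term).
#' @return list of class `model_spec`.
#' @export
model_spec <- function(outcome, fixed, random = "crab_id",
                       transform = c("identity", "log"),
                       protected = character()) {
  transform <- match.arg(transform)
  structure(list(outcome = outcome, fixed = fixed, random = random,
                 transform = transform,
                 protected = vapply(protected, .norm_term, character(1))),
            class = "model_spec")
}

## canonical form of an interaction label: components sorted
.norm_term <- function(t) paste(sort(strsplit(t, ":", fixed = TRUE)[[1]]),
                                collapse = ":")

.spec_formula <- function(spec) {
  as.formula(paste(".outcome ~", paste(spec$fixed, collapse = " + "),
                   "+ (1 |", spec$random, ")"))
}

## finite-difference gradient and Hessian
.fd_grad <- function(f, x, h = NULL) {
  if (is.null(h)) h <- pmax(abs(x), 1) * 1e-5
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h[i]
    (f(x + e) - f(x - e)) / (2 * h[i])
  }, numeric(1))
}

.fd_hess <- function(f, x, h = NULL) {
  p <- length(x)
  if (is.null(h)) h <- pmax(abs(x), 1) * 1e-4
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- h[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < p) for (j in (i + 1):p) {
      ej <- numeric(p); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
           f(x - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H
}

## pseudo-inverse via SVD (boundary fits can have singular Hessians)
.pinv <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * max(s$d, 1e-300)
  if (!any(pos)) return(matrix(0, nrow(m), ncol(m)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

## REML deviance as a function of varpar = c(theta, sigma), and the
## fixed-effect covariance at given varpar, via lme4's predictor module
.satterthwaite_env <- function(model) {
  devfun <- lme4::lmer(formula(model),
                       data = model.frame(model),
                       REML = TRUE, devFunOnly = TRUE,
                       contrasts = attr(model, ".contrasts"))
  ee <- environment(devfun)
  n <- nrow(ee$pp$V)
  p <- ncol(ee$pp$X)
  dev_vp <- function(varpar) {
    nv <- length(varpar)
    sigma2 <- varpar[nv]^2
    theta <- varpar[-nv]
    devfun(theta)
    dev <- ee$pp$ldL2() +
      (ee$resp$wrss() + ee$pp$sqrL(1)) / sigma2 +
      (n - p) * log(2 * pi * sigma2) + ee$pp$ldRX2()
    dev
  }
  vcov_beta <- function(varpar) {
    nv <- length(varpar)
    devfun(varpar[-nv])
    varpar[nv]^2 * tcrossprod(ee$pp$RXi())
  }
  list(dev_vp = dev_vp, vcov_beta = vcov_beta)
}

## Satterthwaite df for each row of a contrast matrix L, plus the
## F statistic for the joint q-df test (lmerTest-style eigen approach)
.satt_test <- function(beta, varpar, vcov_fun, A, L) {
  L <- rbind(L)
  q <- nrow(L)
  Vb <- vcov_fun(varpar)
  Q <- L %*% Vb %*% t(L)
  eg <- eigen(Q, symmetric = TRUE)
  pos <- eg$values > 1e-12 * max(eg$values)
  P <- t(eg$vectors[, pos, drop = FALSE]) %*% L
  d <- eg$values[pos]
  q_eff <- length(d)
  t2 <- (drop(P %*% beta))^2 / d
  Fstat <- sum(t2) / q
  nu <- vapply(seq_len(q_eff), function(i) {
    l <- P[i, ]
    g <- .fd_grad(function(vp) drop(l %*% vcov_fun(vp) %*% l), varpar)
    denom <- drop(crossprod(g, A %*% g))
    if (denom <= 0) return(Inf)
    2 * d[i]^2 / denom
  }, numeric(1))
  df2 <- if (q_eff == 1L) nu[1] else {
    nu_ok <- nu[nu > 2]
    if (length(nu_ok) == 0L) Inf else {
      E <- sum(nu_ok / (nu_ok - 2))
      if (E <= q_eff) Inf else 2 * E / (E - q_eff)
    }
  }
  list(F = Fstat, df1 = q, df2 = df2,
       p = stats::pf(Fstat, q, df2, lower.tail = FALSE))
}

#' Fit a linear mixed model with Satterthwaite F tests
#'
#' REML fit of `outcome ~ fixed terms + (1 | random)` with sum-to-zero
#' factor contrasts, per-term marginal F tests with Satterthwaite
#' denominator df, and variance components.
#'
#' @param spec a [model_spec()].
#' @param data data.frame containing the outcome, predictors and
#'   grouping factor.
#' @return object of class `lmm_fit`: list with `model` (the lmerMod),
#'   `anova` (data.frame: term, F, df1, df2, p), `coefficients`,
#'   `varcomp` (`sigma2_group`, `sigma2_resid`), `n_dropped`
#'   (non-positive outcomes removed on the log scale), `converged`,
#'   `spec`.
#' @export
fit_lmm <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  if (!spec$outcome %in% names(data))
    stop(sprintf("outcome '%s' not in data", spec$outcome))
  d <- data
  y <- d[[spec$outcome]]
  n_dropped <- 0L
  if (spec$transform == "log") {
    bad <- !is.finite(y) | y <= 0
    n_dropped <- sum(bad)
    if (n_dropped)
      message(sprintf("fit_lmm: dropping %d non-positive outcome(s) %s",
                      n_dropped, "before log transform"))
    d <- d[!bad, , drop = FALSE]
    d$.outcome <- log(d[[spec$outcome]])
  } else d$.outcome <- y
  ## sum-to-zero contrasts on character/factor predictors in the model
  fml <- .spec_formula(spec)
  used <- setdiff(all.vars(fml), c(".outcome", spec$random))
  ctr <- list()
  for (nm in intersect(used, names(d))) {
    if (is.character(d[[nm]])) d[[nm]] <- factor(d[[nm]])
    if (is.factor(d[[nm]])) ctr[[nm]] <- "contr.sum"
  }
  fixed_fml <- lme4::nobars(fml)
  X <- model.matrix(fixed_fml, d,
                    contrasts.arg = if (length(ctr)) ctr else NULL)
  if (qr(X)$rank < ncol(X)) {
    qx <- qr(X)
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop(sprintf("fit_lmm: rank-deficient design; aliased: %s",
                 paste(aliased, collapse = ", ")))
  }
  model <- lme4::lmer(fml, data = d, REML = TRUE,
                      contrasts = if (length(ctr)) ctr else NULL)
  attr(model, ".contrasts") <- if (length(ctr)) ctr else NULL
  conv <- is.null(model@optinfo$conv$lme4$messages)
  vc <- lme4::VarCorr(model)
  s2g <- as.numeric(vc[[spec$random]][1])
  s2r <- attr(vc, "sc")^2
  env <- .satterthwaite_env(model)
  theta <- lme4::getME(model, "theta")
  varpar <- c(theta, sigma = stats::sigma(model))
  H <- .fd_hess(env$dev_vp, varpar)
  A <- 2 * .pinv(H)
  beta <- lme4::fixef(model)
  Xm <- lme4::getME(model, "X")
  asgn <- attr(Xm, "assign")
  labs <- attr(terms(fixed_fml), "term.labels")
  rows <- lapply(seq_along(labs), function(j) {
    idx <- which(asgn == j)
    L <- diag(length(beta))[idx, , drop = FALSE]
    st <- .satt_test(beta, varpar, env$vcov_beta, A, L)
    data.frame(term = labs[j], F = st$F, df1 = st$df1, df2 = st$df2,
               p = st$p, stringsAsFactors = FALSE)
  })
  atab <- do.call(rbind, rows)
  structure(list(model = model, anova = atab, coefficients = beta,
                 varcomp = c(sigma2_group = s2g, sigma2_resid = s2r),
                 n_dropped = n_dropped, converged = conv, spec = spec),
            class = "lmm_fit")
}

#' @exportS3Method base::print
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> %s%s ~ %s + (1 | %s)%s\n",
              if (x$spec$transform == "log") "log " else "",
              x$spec$outcome, paste(x$spec$fixed, collapse = " + "),
              x$spec$random,
              if (!x$converged) "  [convergence warning]" else ""))
  cat(sprintf("  sigma2_group = %.4g, sigma2_resid = %.4g, ICC = %.2f\n",
              x$varcomp[1], x$varcomp[2], icc_random_intercept(x)))
  print(format(x$anova, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Intraclass correlation of the random intercept
#'
#' `sigma2_group / (sigma2_group + sigma2_resid)`: the share of
#' outcome variance attributable to differences between crabs.
#'
#' @param fit an [fit_lmm()] result, or a numeric vector
#'   `c(sigma2_group, sigma2_resid)`.
#' @return scalar in [0, 1]; `NA` (with a warning) when both
#'   components are zero.
#' @export
icc_random_intercept <- function(fit) {
  v <- if (inherits(fit, "lmm_fit")) fit$varcomp else as.numeric(fit)
  if (sum(v) == 0) {
    warning("icc_random_intercept: both variance components are zero")
    return(NA_real_)
  }
  unname(v[1] / (v[1] + v[2]))
}

#' Backward elimination of non-significant interaction terms
#'
#' Starting from the saturated specification, repeatedly removes the
#' non-protected interaction with the largest p-value above `alpha`
#' (one term per refit) until every remaining non-protected interaction
#' is significant or protected.  Main effects and protected terms are
#' never removed, so the key-hypothesis contrasts always stay in the
#' model.
#'
#' @param spec saturated [model_spec()].
#' @param data model data.
#' @param alpha retention threshold (default 0.05).
#' @return list with the reduced `spec`, final `fit`, and `removed`
#'   (character vector, in removal order).
#' @export
stepwise_reduce <- function(spec, data, alpha = 0.05) {
  removed <- character(0)
  cur <- spec
  repeat {
    fit <- fit_lmm(cur, data)
    labs <- fit$anova$term
    inter <- labs[grepl(":", labs)]
    cand <- inter[!vapply(inter, .norm_term, character(1)) %in%
                    cur$protected]
    if (length(cand) == 0L) break
    ps <- fit$anova$p[match(cand, labs)]
    if (max(ps) <= alpha) break
    drop_term <- cand[which.max(ps)]
    removed <- c(removed, drop_term)
    ## rebuild term list without the dropped interaction
    expanded <- attr(terms(lme4::nobars(.spec_formula(cur))),
                     "term.labels")
    keep <- expanded[vapply(expanded, .norm_term, character(1)) !=
                       .norm_term(drop_term)]
    cur <- model_spec(cur$outcome, keep, random = cur$random,
                      transform = cur$transform,
                      protected = cur$protected)
  }
  list(spec = cur, fit = fit, removed = removed)
}

#' Run the full mixed-model analysis family over sensillation profiles
#'
#' Fits the standard model family on a joined profile table: log chelar
#' area against log mass with the sex-by-claw contrast; log absolute
#' and log weighted sensillar density, and each site-type proportion,
#' against mass, sex and claw type — all with a crab-level random
#' intercept, starting saturated in the two-way interactions and
#' pruned by [stepwise_reduce()] with `sex:claw_type` protected.
#'
#' @param profiles output of [build_profiles()] (contains `mass_g`,
#'   `sex`, `claw_type`, `crab_id`, areas, densities, proportions).
#' @param alpha pruning threshold.
#' @param saturated start from all two-way interactions (otherwise the
#'   main-effects-plus-protected model is fitted directly).
#' @return list of class `analysis_suite`: per outcome, the reduced
#'   fit; plus `f_table`, one row per fixed term per outcome.
#' @export
run_analysis_suite <- function(profiles, alpha = 0.05, saturated = TRUE) {
  d <- profiles
  d$log_mass <- log(d$mass_g)
  protected <- "claw_type:sex"
  two_way <- function(mass_term)
    c(mass_term, "sex", "claw_type",
      paste0(mass_term, ":sex"), paste0(mass_term, ":claw_type"),
      "sex:claw_type")
  base_terms <- function(mass_term)
    c(mass_term, "sex", "claw_type", "sex:claw_type")
  mk <- function(outcome, mass_term, transform)
    model_spec(outcome,
               if (saturated) two_way(mass_term) else base_terms(mass_term),
               random = "crab_id", transform = transform,
               protected = protected)
  specs <- list(
    chelar_area = mk("chelar_area_mm2", "log_mass", "log"),
    absolute_density = mk("absolute_density", "mass_g", "log"),
    weighted_density = mk("weighted_density", "mass_g", "log"),
    prop_S1 = mk("p1", "mass_g", "identity"),
    prop_S2 = mk("p2", "mass_g", "identity"),
    prop_S3 = mk("p3", "mass_g", "identity"),
    prop_S4 = mk("p4", "mass_g", "identity"))
  fits <- lapply(specs, function(sp) {
    red <- stepwise_reduce(sp, d, alpha = alpha)
    red
  })
  f_table <- do.call(rbind, lapply(names(fits), function(nm) {
    a <- fits[[nm]]$fit$anova
    cbind(outcome = nm, a, stringsAsFactors = FALSE)
  }))
  rownames(f_table) <- NULL
  structure(list(fits = fits, f_table = f_table),
            class = "analysis_suite")
}

#' @exportS3Method base::print
print.analysis_suite <- function(x, ...) {
  cat("<analysis_suite>\n")
  print(format(x$f_table, digits = 4), row.names = FALSE)
  invisible(x)
}
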