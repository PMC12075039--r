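## Independent oracle implementations used to cross-check the package.
## These deliberately avoid the closed-form SVD machinery of the
## implementation: rotations are found by 1-D numerical optimisation,
## distances by grid search, components by exhaustive graph search.

## -- GPA oracle: alternating optimisation with rotations found by
##    numeric angle search (no SVD) ---------------------------------
oracle_rotate_angle <- function(x, target) {
  obj <- function(a) {
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    sum((x %*% R - target)^2)
  }
  ## coarse grid then refine, avoiding local minima
  grid <- seq(-pi, pi, length.out = 721)
  a0 <- grid[which.min(vapply(grid, obj, numeric(1)))]
  opt <- optimize(obj, c(a0 - 0.02, a0 + 0.02), tol = 1e-14)
  matrix(c(cos(opt$minimum), sin(opt$minimum),
           -sin(opt$minimum), cos(opt$minimum)), 2, 2)
}

oracle_preshape <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  m / sqrt(sum(m^2))
}

oracle_gpa <- function(shapes, tol = 1e-12, max_iter = 500) {
  pre <- lapply(shapes, oracle_preshape)
  consensus <- oracle_preshape(Reduce(`+`, pre) / length(pre))
  for (it in seq_len(max_iter)) {
    pre <- lapply(pre, function(x) x %*% oracle_rotate_angle(x, consensus))
    newc <- oracle_preshape(Reduce(`+`, pre) / length(pre))
    if (sqrt(mean((newc - consensus)^2)) < tol) { consensus <- newc; break }
    consensus <- newc
  }
  list(aligned = pre, consensus = consensus)
}

## residual sum of squares about the raw mean shape (gauge invariant;
## the mean of unit preshapes, not re-normalised, to match the
## mean_shape convention of the fit object)
oracle_gpa_rss <- function(res) {
  mean_raw <- Reduce(`+`, res$aligned) / length(res$aligned)
  sum(vapply(res$aligned, function(x) sum((x - mean_raw)^2),
             numeric(1)))
}

## -- full Procrustes distance oracle: grid search over rotation and
##    scale on unit preshapes ---------------------------------------
oracle_procrustes_distance <- function(a, b, n_angle = 3601,
                                       scales = seq(0, 1.5, by = 1e-3)) {
  pa <- oracle_preshape(a); pb <- oracle_preshape(b)
  best <- Inf
  for (ang in seq(-pi, pi, length.out = n_angle)) {
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    rb <- pb %*% R
    ## optimal scale for this angle has closed form, but grid it anyway
    d2 <- vapply(scales, function(s) sum((pa - s * rb)^2), numeric(1))
    best <- min(best, min(d2))
  }
  sqrt(best)
}

## -- single-linkage components by exhaustive reachability ----------
oracle_components <- function(xy, threshold) {
  n <- nrow(xy)
  adj <- as.matrix(dist(xy)) < threshold
  comp <- rep(0L, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier)) {
      nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) &
                     comp == 0L)
      comp[nxt] <- cur
      frontier <- nxt
    }
  }
  comp
}

## -- textbook MANOVA quantities on a small table -------------------
oracle_manova <- function(X, f) {
  f <- factor(f)
  grand <- colMeans(X)
  H <- matrix(0, ncol(X), ncol(X)); E <- matrix(0, ncol(X), ncol(X))
  for (lv in levels(f)) {
    Xi <- X[f == lv, , drop = FALSE]
    mi <- colMeans(Xi)
    H <- H + nrow(Xi) * outer(mi - grand, mi - grand)
    E <- E + crossprod(sweep(Xi, 2, mi))
  }
  lam <- eigen(solve(E) %*% H)$values
  list(H = H, E = E, pillai = sum(Re(lam) / (1 + Re(lam))))
}

## -- small population shortcuts ------------------------------------
tiny_params <- function(...) {
  sim_params(n_female = 6L, n_male = 6L, n_replicates = 1L,
             missing_landmark_rate = 0, p_scan_mnc = 1, ...)
}

harmonise <- function(configs) {
  lapply(configs, function(cf)
    if (identical(cf$claw_type, "MJC")) drop_landmark(cf, "LM14")
    else reflect_y(cf))
}

groups_for <- function(fit, specimens) {
  idx <- match(fit$scan_ids, specimens$scan_id)
  data.frame(claw_type = specimens$claw_type[idx],
             sex = specimens$sex[idx],
             crab_id = specimens$crab_id[idx],
             stringsAsFactors = FALSE)
}

## random non-degenerate shape
rand_shape <- function(k) {
  repeat {
    m <- matrix(rnorm(2 * k), ncol = 2)
    if (qr(sweep(m, 2, colMeans(m)))$rank == 2) return(m)
  }
}
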