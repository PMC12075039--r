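## Generalised Procrustes analysis and shape distances.
##
## All alignment is similarity-only: translation, isotropic scale and
## proper rotation.  Reflection is never applied implicitly; mirrored
## (minor-claw) configurations must be reflected explicitly with
## reflect_y() before joint alignment, mirroring the digitising
## protocol.

.as_lm_matrix <- function(config) {
  if (inherits(config, "landmark_config")) config$landmarks
  else {
    m <- as.matrix(config)
    if (ncol(m) != 2L) stop("expected a k x 2 coordinate matrix")
    m
  }
}

.rewrap <- function(config, m) {
  if (inherits(config, "landmark_config")) { config$landmarks <- m; config }
  else m
}

#' Reflect a configuration along the y axis
#'
#' Negates every x coordinate (`x -> -x`), the orientation alignment
#' applied to minor-claw scans so that both claw types share chirality
#' before joint superimposition.  An involution: applying it twice is
#' the identity.
#'
#' @param config a [landmark_config()] or k x 2 matrix.
#' @return object of the same kind with x negated.
#' @export
reflect_y <- function(config) {
  m <- .as_lm_matrix(config)
  m[, 1] <- -m[, 1]
  .rewrap(config, m)
}

#' Remove one landmark by label
#'
#' Used to harmonise landmark counts between claw types (the major
#' claw's extra molariform-tooth region landmark is dropped before the
#' combined analysis).  Order of the remaining landmarks is preserved.
#'
#' @param config a [landmark_config()] or row-named k x 2 matrix.
#' @param label landmark label, e.g. `"LM14"`.
#' @return the configuration without that landmark.
#' @export
drop_landmark <- function(config, label) {
  m <- .as_lm_matrix(config)
  if (is.null(rownames(m)) || !label %in% rownames(m))
    stop(sprintf("landmark '%s' not present", label))
  keep <- rownames(m) != label
  m2 <- m[keep, , drop = FALSE]
  if (inherits(config, "landmark_config")) {
    config$landmarks <- m2
    config$missing <- config$missing[keep]
    config$claw_type <- NA_character_   # no longer a canonical scheme
    config
  } else m2
}

#' Centroid size of a configuration
#'
#' The standard morphometric size measure: the square root of the
#' summed squared distances of all landmarks from their centroid.
#' Invariant to translation and rotation; scales linearly with the
#' configuration.
#'
#' @param config a [landmark_config()] or k x 2 matrix (no missing
#'   coordinates).
#' @return positive scalar.
#' @export
centroid_size <- function(config) {
  m <- .as_lm_matrix(config)
  if (any(!is.finite(m))) stop("centroid_size: missing coordinates")
  cs <- sqrt(sum(sweep(m, 2, colMeans(m))^2))
  if (cs <= 0) stop("centroid_size: all landmarks coincident")
  cs
}

## centre at origin and scale to unit centroid size
.preshape <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  m / sqrt(sum(m^2))
}

## optimal proper rotation (det +1) of x onto target y, both k x 2
.opt_rotation <- function(x, y) {
  m <- crossprod(x, y)
  sv <- svd(m)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1  # degenerate rank-1 case: fall back towards identity
  sv$u %*% diag(c(1, d)) %*% t(sv$v)
}

## deterministic gauge: rotate so the consensus' principal axis lies
## along x, sign fixed by the first off-axis landmark
.gauge_rotation <- function(consensus) {
  cc <- sweep(consensus, 2, colMeans(consensus))
  ev <- eigen(crossprod(cc), symmetric = TRUE)
  v1 <- ev$vectors[, 1]
  theta <- atan2(v1[2], v1[1])
  rot <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  R <- rot(-theta)
  z <- cc %*% R
  s <- sign(z[which.max(abs(z[, 1])), 1])
  if (s < 0) R <- R %*% rot(pi)
  R
}

#' Generalised Procrustes alignment of a set of configurations
#'
#' Iterative superimposition: every configuration is centred at the
#' origin and scaled to unit centroid size, then repeatedly rotated
#' (proper rotation only) onto the running consensus, which is
#' re-estimated as the coordinate-wise mean, until the consensus
#' root-mean-square change falls below `tol`.  Configurations with any
#' missing landmark are excluded beforehand (no imputation), matching
#' the digitising protocol's exclusions.  The final solution is put in
#' a deterministic orientation (consensus principal axis along x), so
#' the result does not depend on input order.
#'
#' @param configs list of [landmark_config()]s (equal landmark counts)
#'   or a k x 2 x n array.
#' @param tol convergence tolerance on consensus RMS change.
#' @param max_iter iteration cap; if reached, `converged` is `FALSE`
#'   but the fit is still returned.
#' @return object of class `gpa_fit`: list with `aligned` (k x 2 x n
#'   array, each slice unit centroid size, centred), `mean_shape`
#'   (coordinate-wise mean of the aligned slices), `centroid_sizes`
#'   (original sizes), `scan_ids`, `excluded` (ids dropped for missing
#'   landmarks), `iterations`, `converged`.
#' @export
align_gpa <- function(configs, tol = 1e-10, max_iter = 200L) {
  if (is.array(configs) && length(dim(configs)) == 3L) {
    arr <- configs
    ids <- dimnames(arr)[[3]]
    if (is.null(ids)) ids <- paste0("shape_", seq_len(dim(arr)[3]))
    excluded <- character(0)
  } else {
    complete <- vapply(configs, function(cf) {
      m <- .as_lm_matrix(cf)
      all(is.finite(m))
    }, logical(1))
    excluded <- vapply(configs[!complete], function(cf)
      if (inherits(cf, "landmark_config")) cf$scan_id else "<matrix>",
      character(1))
    configs <- configs[complete]
    if (length(configs) < 2L)
      stop("align_gpa: need at least 2 complete configurations")
    ks <- vapply(configs, function(cf) nrow(.as_lm_matrix(cf)), integer(1))
    if (length(unique(ks)) != 1L)
      stop(sprintf("align_gpa: unequal landmark counts (%s)",
                   paste(unique(ks), collapse = ", ")))
    arr <- array(NA_real_, dim = c(ks[1], 2L, length(configs)))
    for (i in seq_along(configs)) arr[, , i] <- .as_lm_matrix(configs[[i]])
    ids <- vapply(configs, function(cf)
      if (inherits(cf, "landmark_config")) cf$scan_id else NA_character_,
      character(1))
    if (anyNA(ids)) ids <- paste0("shape_", seq_along(configs))
    dimnames(arr) <- list(rownames(.as_lm_matrix(configs[[1]])),
                          c("x", "y"), ids)
  }
  n <- dim(arr)[3]
  if (n < 2L) stop("align_gpa: need at least 2 configurations")
  sizes <- apply(arr, 3, centroid_size)
  pre <- arr
  for (i in seq_len(n)) pre[, , i] <- .preshape(arr[, , i])

  consensus <- .preshape(apply(pre, c(1, 2), mean))
  it <- 0L
  converged <- FALSE
  repeat {
    it <- it + 1L
    for (i in seq_len(n)) pre[, , i] <- pre[, , i] %*%
        .opt_rotation(pre[, , i], consensus)
    new_consensus <- .preshape(apply(pre, c(1, 2), mean))
    delta <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  Rg <- .gauge_rotation(consensus)
  for (i in seq_len(n)) pre[, , i] <- pre[, , i] %*% Rg
  mean_shape <- apply(pre, c(1, 2), mean)
  dimnames(mean_shape) <- dimnames(arr)[1:2]
  structure(list(aligned = pre, mean_shape = mean_shape,
                 centroid_sizes = sizes, scan_ids = ids,
                 excluded = excluded, iterations = it,
                 converged = converged),
            class = "gpa_fit")
}

#' @exportS3Method base::print
print.gpa_fit <- function(x, ...) {
  cat(sprintf(
    "<gpa_fit> %d configurations x %d landmarks; %d iterations (%s)%s\n",
    dim(x$aligned)[3], dim(x$aligned)[1], x$iterations,
    if (x$converged) "converged" else "NOT converged",
    if (length(x$excluded))
      sprintf("; %d excluded for missing landmarks", length(x$excluded))
    else ""))
  invisible(x)
}

#' Full Procrustes distance between two configurations
#'
#' Root summed squared coordinate difference after optimally
#' translating, scaling and rotating `b` onto `a` (both reduced to unit
#' centroid size first, so the measure is symmetric).  Zero exactly
#' when the two shapes are similarity-equivalent (without reflection).
#'
#' @param a,b [landmark_config()]s or k x 2 matrices with equal
#'   landmark counts.
#' @return non-negative scalar, at most 1.
#' @export
procrustes_distance <- function(a, b) {
  ma <- .as_lm_matrix(a); mb <- .as_lm_matrix(b)
  if (nrow(ma) != nrow(mb))
    stop("procrustes_distance: unequal landmark counts")
  pa <- .preshape(ma); pb <- .preshape(mb)
  R <- .opt_rotation(pb, pa)
  pbr <- pb %*% R
  beta <- sum(pa * pbr)                 # cosine of Procrustes angle
  beta <- min(max(beta, 0), 1)          # negative scale not allowed
  ## direct residual norm: equals sqrt(1 - beta^2) analytically but
  ## avoids cancellation for near-identical shapes
  sqrt(sum((pa - beta * pbr)^2))
}
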