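## Standardised frequency maps of sensillar site locations.
##
## Each scan's points are carried into a common reference frame
## (default 5162 x 2947 px) by a landmark-based similarity transform
## onto the frame-registered consensus shape; per-scan binary rasters
## are then summed into frequency maps and tinted composites.

#' Reference frame for frequency maps
#'
#' @param width,height frame dimensions in pixels (defaults match the
#'   standardised micrograph frame, 5162 x 2947).
#' @param scale integer downscale divisor for desk-scale work; the
#'   frame becomes `width/scale` x `height/scale`.
#' @return list of class `reference_frame` with `width`, `height`.
#' @export
reference_frame <- function(width = 5162L, height = 2947L, scale = 1L) {
  width <- as.integer(round(width / scale))
  height <- as.integer(round(height / scale))
  if (width <= 0L || height <= 0L) stop("frame dimensions must be positive")
  structure(list(width = width, height = height),
            class = "reference_frame")
}

## consensus landmarks placed in frame pixels: fit the mean shape into
## the central 65% of the frame, preserving aspect.  The generous
## margin leaves room for sites beyond the landmark hull and for scans
## deviating from the consensus, so radius-0 markers stay in frame.
.frame_consensus <- function(mean_shape, frame, margin = 0.65) {
  m <- sweep(mean_shape, 2, colMeans(mean_shape))
  rng <- apply(m, 2, range)
  span <- rng[2, ] - rng[1, ]
  s <- margin * min(frame$width / span[1], frame$height / span[2])
  sweep(m * s, 2, c(frame$width, frame$height) / 2, "+")
}

## least-squares similarity (scale, proper rotation, translation)
## mapping source k x 2 onto target k x 2
.fit_similarity <- function(src, dst) {
  sc <- colMeans(src); dc <- colMeans(dst)
  s0 <- sweep(src, 2, sc); d0 <- sweep(dst, 2, dc)
  R <- .opt_rotation(s0, d0)
  beta <- sum(d0 * (s0 %*% R)) / sum(s0^2)
  list(R = R, beta = beta, sc = sc, dc = dc,
       apply = function(xy) {
         sweep(sweep(xy, 2, sc) %*% R * beta, 2, dc, "+")
       })
}

#' Map one scan's points into the reference frame
#'
#' Estimates the similarity transform from the scan's landmark
#' configuration (micrometre coordinates) to the frame-registered
#' consensus landmarks, and maps the scan's points through it.  Minor
#' claw scans are reflected along y first so both claw types share the
#' frame's chirality.  Scans with missing landmarks are excluded
#' (`NULL` returned, with a warning).
#'
#' @param points two-column matrix or data.frame (`x_um`, `y_um`) of
#'   one scan's site locations.
#' @param config the scan's [landmark_config()].
#' @param consensus consensus landmark matrix, either already in frame
#'   pixels or a unit-size mean shape (then registered via
#'   [reference_frame()] `frame`).
#' @param frame a [reference_frame()].
#' @param reflect reflect the scan before registration (defaults to
#'   `TRUE` for MNC scans).
#' @return n x 2 matrix of frame pixel coordinates, or `NULL` if the
#'   scan has missing landmarks.
#' @export
to_reference_frame <- function(points, config, consensus, frame,
                               reflect = identical(config$claw_type, "MNC")) {
  if (any(config$missing)) {
    warning(sprintf("scan '%s' excluded: missing landmarks", config$scan_id))
    return(NULL)
  }
  pts <- as.matrix(if (is.data.frame(points))
    points[, c("x_um", "y_um")] else points)
  lm_um <- scaled_coords(config)
  if (reflect) {
    lm_um[, 1] <- -lm_um[, 1]
    pts[, 1] <- -pts[, 1]
  }
  dst <- consensus
  if (max(abs(dst)) < 10)   # unit-size mean shape: register to frame
    dst <- .frame_consensus(dst, frame)
  tr <- .fit_similarity(lm_um, dst)
  tr$apply(pts)
}

#' Rasterise site locations to a binary image
#'
#' Sets a disc of radius `marker_radius_px` (0 = single pixel) at each
#' site; the result is binary (overlaps stay 1).  Out-of-frame points
#' are dropped and counted in the `dropped` attribute.
#'
#' @param points n x 2 matrix of frame pixel coordinates.
#' @param frame a [reference_frame()].
#' @param marker_radius_px marker disc radius in pixels.
#' @return integer `height x width` matrix of 0/1, with attribute
#'   `dropped` (count of out-of-frame points).
#' @export
rasterize_sites <- function(points, frame, marker_radius_px = 0L) {
  g <- matrix(0L, frame$height, frame$width)
  if (is.null(points) || nrow(points) == 0L) {
    attr(g, "dropped") <- 0L
    return(g)
  }
  cx <- round(points[, 1]); cy <- round(points[, 2])
  inb <- cx >= 1 & cx <= frame$width & cy >= 1 & cy <= frame$height
  dropped <- sum(!inb)
  if (dropped) warning(sprintf("rasterize_sites: %d point(s) out of frame",
                               dropped))
  cx <- cx[inb]; cy <- cy[inb]
  r <- as.integer(marker_radius_px)
  if (r <= 0L) {
    g[cbind(cy, cx)] <- 1L
  } else {
    off <- expand.grid(dx = -r:r, dy = -r:r)
    off <- off[off$dx^2 + off$dy^2 <= r^2, ]
    for (i in seq_along(cx)) {
      xx <- cx[i] + off$dx; yy <- cy[i] + off$dy
      ok <- xx >= 1 & xx <= frame$width & yy >= 1 & yy <= frame$height
      g[cbind(yy[ok], xx[ok])] <- 1L
    }
  }
  attr(g, "dropped") <- dropped
  g
}

#' Sum projection of binary rasters
#'
#' Cell-wise integer sum over a stack of equal-sized per-scan binary
#' rasters — the frequency map of site locations across scans.
#'
#' @param rasters list of matrices from [rasterize_sites()].
#' @return list of class `frequency_raster`: `grid` (integer matrix),
#'   `n_scans`.
#' @export
sum_projection <- function(rasters) {
  if (length(rasters) == 0L) stop("sum_projection: no rasters")
  dims <- vapply(rasters, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("sum_projection: raster dimensions differ")
  g <- Reduce(`+`, rasters)
  structure(list(grid = g, n_scans = length(rasters)),
            class = "frequency_raster")
}

## named site-type tints (RGB in [0,1])
.site_tints <- list(S1 = c(1, 0, 1),      # magenta
                    S2 = c(0, 1, 1),      # cyan
                    S3 = c(0.2, 0.8, 0),  # lime green
                    S4 = c(1, 0.84, 0))   # gold

#' Merge per-type frequency rasters into an RGB composite
#'
#' Each type's raster is scaled to [0, 1] by its own maximum, tinted
#' with the conventional colour (S1 magenta, S2 cyan, S3 lime green,
#' S4 gold), additively merged and clipped at 1.
#'
#' @param per_type named list (`S1`..`S4`) of [sum_projection()]
#'   results or plain matrices; equal dimensions required.
#' @return `height x width x 3` numeric array in [0, 1].
#' @export
composite_rgb <- function(per_type) {
  grids <- lapply(per_type, function(r)
    if (inherits(r, "frequency_raster")) r$grid else r)
  dims <- vapply(grids, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("composite_rgb: raster dimensions differ")
  h <- nrow(grids[[1]]); w <- ncol(grids[[1]])
  img <- array(0, c(h, w, 3))
  for (tp in names(grids)) {
    tint <- .site_tints[[tp]]
    if (is.null(tint)) stop(sprintf("unknown site type '%s'", tp))
    g <- grids[[tp]]
    mx <- max(g)
    if (mx > 0) g <- g / mx
    for (ch in 1:3) img[, , ch] <- img[, , ch] + g * tint[ch]
  }
  pmin(img, 1)
}

#' Sequential-colormap rendering of a frequency raster
#'
#' Maps counts through a dark-to-bright sequential lookup (black, blue,
#' magenta, orange, yellow, white) analogous to the lookup tables used
#' for micrograph Z-projections.
#'
#' @param raster a [sum_projection()] result or matrix.
#' @return `height x width x 3` numeric array in [0, 1].
#' @export
heat_rgb <- function(raster) {
  g <- if (inherits(raster, "frequency_raster")) raster$grid else raster
  mx <- max(g)
  v <- if (mx > 0) g / mx else g
  stops <- rbind(c(0, 0, 0), c(0.1, 0.05, 0.5), c(0.75, 0.1, 0.75),
                 c(1, 0.55, 0.1), c(1, 0.9, 0.2), c(1, 1, 1))
  pos <- seq(0, 1, length.out = nrow(stops))
  img <- array(0, c(nrow(g), ncol(g), 3))
  for (ch in 1:3)
    img[, , ch] <- matrix(stats::approx(pos, stops[, ch], xout = v,
                                        rule = 2)$y, nrow(g), ncol(g))
  img
}

#' Write a frequency raster as ASCII PGM (16-bit grayscale)
#'
#' Plain-text portable graymap: deterministic, byte-stable output.
#'
#' @param raster [sum_projection()] result or integer matrix.
#' @param path output `.pgm` path.
#' @param maxval grayscale ceiling (defaults to the raster maximum,
#'   at least 1, capped at 65535).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(raster, path, maxval = NULL) {
  g <- if (inherits(raster, "frequency_raster")) raster$grid else raster
  if (is.null(maxval)) maxval <- min(max(1L, max(g)), 65535L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(g), nrow(g)),
               sprintf("%d", maxval)), con)
  write(t(pmin(g, maxval)), file = con, ncolumns = ncol(g))
  invisible(path)
}

#' Write an RGB array as ASCII PPM (8-bit)
#'
#' @param img `h x w x 3` array in [0, 1] (e.g. [composite_rgb()]).
#' @param path output `.ppm` path.
#' @return `path`, invisibly.
#' @export
write_ppm <- function(img, path) {
  h <- dim(img)[1]; w <- dim(img)[2]
  v <- round(pmin(pmax(img, 0), 1) * 255)
  inter <- matrix(0L, nrow = h, ncol = 3L * w)
  inter[, seq(1, 3 * w, 3)] <- v[, , 1]
  inter[, seq(2, 3 * w, 3)] <- v[, , 2]
  inter[, seq(3, 3 * w, 3)] <- v[, , 3]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", sprintf("%d %d", w, h), "255"), con)
  write(t(inter), file = con, ncolumns = 15)
  invisible(path)
}

#' Build per-type frequency maps for a population
#'
#' Convenience wrapper: aligns each complete scan's landmarks to the
#' consensus of `fit`, maps its points to the frame, rasterises per
#' site type and sum-projects across scans of the requested claw type.
#'
#' @param pop a [generate_population()] result (or a list with
#'   `points` and `configurations`).
#' @param fit [align_gpa()] fit of the corresponding configurations
#'   (already reflected/harmonised as desired).
#' @param frame a [reference_frame()].
#' @param claw_type which scans to stack (`"MJC"` or `"MNC"`).
#' @param marker_radius_px marker radius passed to [rasterize_sites()].
#' @return named list `S1`..`S4` of [sum_projection()] rasters plus
#'   `all` (their cell-wise sum).
#' @export
frequency_maps <- function(pop, fit, frame, claw_type = "MJC",
                           marker_radius_px = 0L) {
  ## minor-claw scans are reflected during registration, so the target
  ## consensus must share the reflected chirality
  mean_shape <- if (identical(claw_type, "MNC")) reflect_y(fit$mean_shape)
                else fit$mean_shape
  consensus <- .frame_consensus(mean_shape, frame)
  types <- paste0("S", 1:4)
  ## accumulate sums per type instead of holding one raster per scan
  acc <- setNames(lapply(types, function(t)
    matrix(0L, frame$height, frame$width)), types)
  n_scans <- 0L
  for (cf in pop$configurations) {
    if (!identical(cf$claw_type, claw_type) || any(cf$missing)) next
    pts <- pop$points[pop$points$scan_id == cf$scan_id, , drop = FALSE]
    if (nrow(pts) == 0L) next
    ## one marker per sensillar site (not per articulation point)
    sites <- group_articulations(pts)
    cent <- t(vapply(sites, `[[`, numeric(2), "centroid_um"))
    stype <- vapply(sites, `[[`, character(1), "site_type")
    mapped <- to_reference_frame(cent, cf, consensus, frame)
    if (is.null(mapped)) next
    n_scans <- n_scans + 1L
    for (tp in types)
      acc[[tp]] <- acc[[tp]] +
        rasterize_sites(mapped[stype == tp, , drop = FALSE], frame,
                        marker_radius_px)
  }
  if (n_scans == 0L) return(list())
  out <- lapply(acc, function(g)
    structure(list(grid = g, n_scans = n_scans),
              class = "frequency_raster"))
  out$all <- structure(list(grid = Reduce(`+`, acc), n_scans = n_scans),
                       class = "frequency_raster")
  out
}
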