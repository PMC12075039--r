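## Mean-shape templates for the two chelipeds.
##
## Coordinates are micrometres in an anatomical frame with the
## carpal-propodal (proximal) joint at low x and the superior margin at
## high y.  Landmark roles follow the standard propodal scheme: LM1 the
## distal tip of the propodal extension, LM3-LM5 / LM6-LM8 the inferior
## and superior marginal tubercles, LM10-LM14 the propodus-dactylus
## articulation border, LM16 (major claw only) the apex of the largest
## molariform tooth.  The minor claw is digitised in mirrored
## orientation, as it appears on the animal, and is reflected along the
## y axis before any joint analysis.

#' Template landmark coordinates for a claw type
#'
#' Returns the package's built-in mean-shape template used by the
#' synthetic-population generator: 16 landmarks for the major cheliped
#' (MJC), 15 for the minor (MNC).  The MNC template is mirrored in x
#' (opposite chirality on the animal), relatively longer and slimmer
#' than the MJC, matching the qualitative heterochely of hermit crabs.
#'
#' @param claw_type `"MJC"` or `"MNC"`.
#' @return k x 2 matrix (micrometres), rows named `LM1`..
#' @export
claw_template <- function(claw_type = c("MJC", "MNC")) {
  claw_type <- match.arg(claw_type)
  mjc <- rbind(
    LM1  = c(3000,  300),   # distal tip, propodal extension
    LM2  = c( 700,   80),   # base of inferior margin curve
    LM3  = c(1100,  120),   # inferior marginal tubercle, inferior emergence
    LM4  = c(1250,   20),   # inferior marginal tubercle apex
    LM5  = c(1400,  130),   # inferior marginal tubercle, superior emergence
    LM6  = c(1200, 1640),   # superior marginal tubercle, inferior emergence
    LM7  = c(1380, 1780),   # superior marginal tubercle apex
    LM8  = c(1560, 1660),   # superior marginal tubercle, superior emergence
    LM9  = c(2050, 1580),   # distal point of superior manus margin
    LM10 = c(2200, 1430),   # superior propodus-dactylus junction
    LM11 = c(2290, 1280),   # superior indentation at dactylus border
    LM12 = c(2380, 1130),   # superior protrusion at dactylus border
    LM13 = c(2330,  940),   # inferior protrusion, articulation base
    LM14 = c(2220,  790),   # inferior indentation, articulation base
    LM15 = c(2520,  600),   # superior margin of propodal extension
    LM16 = c(2720,  480))   # molariform tooth apex (MJC only)
  colnames(mjc) <- c("x", "y")
  if (claw_type == "MJC") return(mjc)
  ## MNC: drop the molariform landmark, elongate distally, slim
  ## dorso-ventrally, and mirror in x (opposite chirality).
  mnc <- mjc[1:15, , drop = FALSE]
  mnc[, 1] <- mnc[, 1] * 1.18
  mnc[, 2] <- (mnc[, 2] - mean(mnc[, 2])) * 0.74 + mean(mnc[, 2]) * 0.9
  mnc["LM1", 1] <- mnc["LM1", 1] * 1.1   # longer propodal extension
  mnc[, 1] <- -mnc[, 1]
  mnc
}

## Point-in-convex-hull test, vectorised over points.
.in_hull <- function(px, py, hx, hy) {
  n <- length(hx)
  inside <- rep(TRUE, length(px))
  ## hull vertices assumed counter-clockwise; flip if signed area < 0
  a2 <- sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)
  if (a2 < 0) { hx <- rev(hx); hy <- rev(hy) }
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cross <- (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
    inside <- inside & cross >= 0
  }
  inside
}

## Padded convex-hull outline of a template (pad expands about centroid).
.claw_outline <- function(template, pad = 1.05) {
  cx <- colMeans(template)
  idx <- chull(template[, 1], template[, 2])
  h <- template[idx, , drop = FALSE]
  h <- sweep(sweep(h, 2, cx, "-") * pad, 2, cx, "+")
  h
}
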