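## Sensillar site classification and density statistics.
##
## Individually digitised setal articulation points are grouped into
## sites by proximity: articulations within one setal diameter
## (about 20 um) of one another belong to the same site.  Site type is
## the member count: S1 single, S2 double, S3 triple, S4 clustered
## (>= 4 articulations; exact counts inside a cluster are not resolved
## from 2-D micrographs and are not used downstream).

#' Group articulation points into sensillar sites
#'
#' Single-linkage grouping: points are joined when their distance is
#' strictly below `threshold_um`, and connected components of the
#' resulting graph form sites.  Chains therefore merge (a-b and b-c
#' within threshold put a, b, c in one site even if a-c is not).  The
#' result is deterministic and independent of input order: members are
#' sorted by coordinate and sites by centroid.
#'
#' @param points data.frame with `x_um`, `y_um` columns (one scan's
#'   points); duplicate coordinates allowed.
#' @param threshold_um linkage distance in micrometres (default 20,
#'   about one setal diameter).
#' @return list of sites, each a list with `members` (row indices into
#'   `points`, sorted), `n` (member count), `site_type` (`"S1"`..`"S4"`),
#'   `centroid_um` (length-2 numeric).  Empty input gives an empty
#'   list.
#' @export
group_articulations <- function(points, threshold_um = 20) {
  if (threshold_um <= 0) stop("threshold_um must be positive")
  n <- nrow(points)
  if (is.null(n) || n == 0L) return(list())
  x <- points$x_um; y <- points$y_um
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("group_articulations: non-finite coordinates")
  ## union-find over pairs closer than the threshold
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1L) {
    d <- as.matrix(dist(cbind(x, y)))
    for (i in seq_len(n - 1L)) {
      near <- which(d[i, (i + 1L):n] < threshold_um)
      for (j in near + i) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- split(seq_len(n), roots)
  sites <- lapply(comp, function(idx) {
    o <- idx[order(x[idx], y[idx])]
    cnt <- length(o)
    list(members = o, n = cnt,
         site_type = paste0("S", min(cnt, 4L)),
         centroid_um = c(mean(x[o]), mean(y[o])))
  })
  cx <- vapply(sites, function(s) s$centroid_um[1], numeric(1))
  cy <- vapply(sites, function(s) s$centroid_um[2], numeric(1))
  unname(sites[order(cx, cy)])
}

#' Site counts by type
#'
#' @param sites output of [group_articulations()].
#' @return named integer vector `c(S1 = , S2 = , S3 = , S4 = )`.
#' @export
site_counts <- function(sites) {
  tt <- vapply(sites, `[[`, character(1), "site_type")
  out <- c(S1 = 0L, S2 = 0L, S3 = 0L, S4 = 0L)
  tb <- table(tt)
  out[names(tb)] <- as.integer(tb)
  out
}

#' Absolute sensillar site density
#'
#' Number of sensillar sites divided by chelar area (sites per mm^2) —
#' the abundance measure of sensory investment.
#'
#' @param sites list of sites (or an integer site count).
#' @param area_mm2 chelar area in mm^2.
#' @return sites per mm^2.
#' @export
compute_absolute_density <- function(sites, area_mm2) {
  if (!is.numeric(area_mm2) || area_mm2 <= 0)
    stop("area_mm2 must be positive")
  n <- if (is.numeric(sites)) sum(sites) else length(sites)
  n / area_mm2
}

#' Area-weighted sensillar site density
#'
#' The coverage measure of sensory investment: each type's count is
#' weighted by its mean site area relative to the mean S1 area
#' (`w_i = abar_i / abar_1`), the weighted counts are summed and
#' divided by the chelar area.  When all sites are S1 this reduces to
#' the absolute density.
#'
#' @param counts numeric length-4 vector of S1..S4 site counts.
#' @param mean_areas length-4 vector of mean site areas (um^2) per
#'   type; may contain `NA` for types with zero count.
#' @param area_mm2 chelar area in mm^2.
#' @return weighted sites per mm^2.
#' @export
compute_weighted_density <- function(counts, mean_areas, area_mm2) {
  if (length(counts) != 4L || length(mean_areas) != 4L)
    stop("counts and mean_areas must have length 4 (S1..S4)")
  if (!is.numeric(area_mm2) || area_mm2 <= 0)
    stop("area_mm2 must be positive")
  if (sum(counts) == 0) return(0)
  if (is.na(mean_areas[1]) || mean_areas[1] <= 0)
    stop("compute_weighted_density: mean S1 area must be positive")
  need <- which(counts > 0 & (is.na(mean_areas) | mean_areas <= 0))
  if (length(need))
    stop(sprintf("compute_weighted_density: missing mean area for S%d",
                 need[1]))
  w <- mean_areas / mean_areas[1]
  sum(counts * w, na.rm = TRUE) / area_mm2
}

#' Proportions of each site type
#'
#' `p_i = c_i / sum(c)`; with all-zero counts the proportions are
#' undefined and returned as `NA` with a warning.
#'
#' @param counts numeric vector of per-type counts.
#' @return numeric vector of proportions (same names as `counts`).
#' @export
compute_proportions <- function(counts) {
  tot <- sum(counts)
  if (tot == 0) {
    warning("compute_proportions: zero total count, proportions undefined")
    return(rep(NA_real_, length(counts)))
  }
  counts / tot
}

## convex-hull area of a point set, with a buffer radius approximating
## the articulation footprint (used when no annotated site area exists)
.hull_area_um2 <- function(x, y, buffer_um = 10) {
  if (length(x) == 1L) return(pi * buffer_um^2)
  idx <- chull(x, y)
  hx <- x[idx]; hy <- y[idx]
  a <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  per <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
  a + per * buffer_um + pi * buffer_um^2
}

#' Per-scan sensillation profiles
#'
#' Combines grouping, counting, densities and proportions into one
#' profile row per scan.  Mean site areas per type are taken from the
#' annotated `site_area_um2` column when present, otherwise from a
#' buffered convex hull of the member points; by default they are
#' pooled per claw type across the whole dataset (stabilising the
#' weights for scans with few sites of a type), optionally per scan.
#'
#' @param points articulation table ([read_site_table()] layout) for
#'   all scans.
#' @param specimens specimen table ([read_specimen_table()] layout)
#'   with one row per scan (`scan_id` column).
#' @param area_choice chelar-area denominator: `"total"` (including
#'   the dactylus, the default) or `"propodus"`.
#' @param threshold_um linkage threshold for [group_articulations()].
#' @param area_pooling `"pooled"` (mean site areas per claw type over
#'   all scans) or `"per_scan"`.
#' @param buffer_um articulation footprint radius for hull-based site
#'   areas.
#' @return data.frame with one row per scan: counts `c1`..`c4`,
#'   `chelar_area_mm2`, `absolute_density`, `weighted_density`,
#'   proportions `p1`..`p4`, mean site areas `abar1`..`abar4`, plus
#'   `crab_id`, `sex`, `mass_g`, `claw_type` copied from the specimen
#'   table.
#' @export
build_profiles <- function(points, specimens, area_choice = c("total",
                           "propodus"), threshold_um = 20,
                           area_pooling = c("pooled", "per_scan"),
                           buffer_um = 10) {
  area_choice <- match.arg(area_choice)
  area_pooling <- match.arg(area_pooling)
  area_col <- if (area_choice == "total") "chelar_area_total_mm2"
              else "chelar_area_propodus_mm2"
  scans <- unique(points$scan_id)
  missing <- setdiff(scans, specimens$scan_id)
  if (length(missing))
    stop(sprintf("build_profiles: no specimen area for scan '%s'",
                 missing[1]))
  per_scan <- lapply(scans, function(sid) {
    pts <- points[points$scan_id == sid, , drop = FALSE]
    sites <- group_articulations(pts, threshold_um = threshold_um)
    tt <- vapply(sites, `[[`, character(1), "site_type")
    areas <- vapply(sites, function(s) {
      ann <- if ("site_area_um2" %in% names(pts))
        pts$site_area_um2[s$members] else NA_real_
      if (any(!is.na(ann))) mean(ann, na.rm = TRUE)
      else .hull_area_um2(pts$x_um[s$members], pts$y_um[s$members],
                          buffer_um)
    }, numeric(1))
    list(scan_id = sid, type = tt, area = areas)
  })
  spec_idx <- match(scans, specimens$scan_id)
  claw <- specimens$claw_type[spec_idx]
  ## mean site areas per type, pooled per claw type if requested
  pooled_means <- NULL
  if (area_pooling == "pooled") {
    pooled_means <- list()
    for (ct in unique(claw)) {
      sel <- which(claw == ct)
      tt <- unlist(lapply(per_scan[sel], `[[`, "type"))
      aa <- unlist(lapply(per_scan[sel], `[[`, "area"))
      pooled_means[[ct]] <- vapply(paste0("S", 1:4), function(s)
        if (any(tt == s)) mean(aa[tt == s]) else NA_real_, numeric(1))
    }
  }
  rows <- lapply(seq_along(scans), function(i) {
    ps <- per_scan[[i]]
    cnt <- c(S1 = sum(ps$type == "S1"), S2 = sum(ps$type == "S2"),
             S3 = sum(ps$type == "S3"), S4 = sum(ps$type == "S4"))
    abar <- if (area_pooling == "pooled") pooled_means[[claw[i]]]
            else vapply(paste0("S", 1:4), function(s)
              if (any(ps$type == s)) mean(ps$area[ps$type == s])
              else NA_real_, numeric(1))
    area <- specimens[[area_col]][spec_idx[i]]
    props <- if (sum(cnt) > 0) cnt / sum(cnt) else rep(NA_real_, 4)
    data.frame(scan_id = ps$scan_id,
               crab_id = specimens$crab_id[spec_idx[i]],
               sex = specimens$sex[spec_idx[i]],
               mass_g = specimens$mass_g[spec_idx[i]],
               claw_type = claw[i],
               c1 = cnt[1], c2 = cnt[2], c3 = cnt[3], c4 = cnt[4],
               chelar_area_mm2 = area,
               absolute_density = compute_absolute_density(sum(cnt), area),
               weighted_density = compute_weighted_density(cnt, abar, area),
               p1 = props[1], p2 = props[2], p3 = props[3], p4 = props[4],
               abar1 = abar[1], abar2 = abar[2], abar3 = abar[3],
               abar4 = abar[4],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
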