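## Seeded synthetic-population generator.
##
## Emulates a field-study structure: ~76 crabs (34 F, 42 M)
## over a wide mass range (0.015-1.088 g, mean 0.508 +/- 0.257), two
## chelipeds per crab with heterochelic shape and size differences,
## log-log chelar-area allometry with a crab-level random intercept,
## sensillar site counts driven by density x area with a sex-by-claw
## density contrast (higher female major-claw density), and spatially
## structured S1-S4 point patterns (S1 proximal, S2 marginal, S3 at
## the distal articulation, S4 at the distal tips).

#' Optimal gastropod shell mass for a crab of given mass
#'
#' The linear shell-preference rule used to house crabs:
#' `OSM = 3.601 * mass + 0.502` (grams).
#'
#' @param mass_g crab mass in grams (non-negative, vectorised).
#' @return predicted optimal shell mass in grams.
#' @export
compute_osm <- function(mass_g) {
  if (any(!is.finite(mass_g)) || any(mass_g < 0))
    stop("compute_osm: mass must be non-negative")
  3.601 * mass_g + 0.502
}

#' Simulation parameters for the synthetic population
#'
#' Defaults encode the emulated study design; override individual
#' entries via `...`.  Noteworthy knobs: `sex_by_claw_density_multiplier`
#' multiplies the sensillar density of female major claws (1 = null);
#' `sex_shape_effect` scales a fixed shape-displacement field applied
#' to male major claws (0 = null); `n_replicates` repeats digitisation
#' of each scan with independent landmark noise.
#'
#' @param ... overrides for any default entry.
#' @return named list of class `sim_params`.
#' @export
sim_params <- function(...) {
  p <- list(
    n_female = 34L, n_male = 42L,
    mass_mean = 0.508, mass_sd = 0.257,
    mass_min = 0.015, mass_max = 1.088,
    mean_shapes = list(MJC = claw_template("MJC"),
                       MNC = claw_template("MNC")),
    shape_noise_sd = 20,        # um, crab-by-claw shape deviation
    digit_noise_sd = 8,         # um, per-replicate digitising error
    n_replicates = 1L,
    sex_shape_effect = 0.03,    # male MJC displacement-field scale
    area_allometry = list(intercept = 1.63, slope = 0.67,
                          claw_mnc = -0.55, sex_male_mjc = 0.12,
                          crab_sd = 0.10, resid_sd = 0.08,
                          propodus_frac = 0.72),
    density_base = 16,          # sites/mm^2 at the 0.5 g reference mass
    density_mass_slope = -0.5,  # d log density / d log mass
    density_claw_mnc = 0.25,    # log uplift of minor-claw density
    sex_by_claw_density_multiplier = 1.2,  # on female MJC
    density_crab_sd = 0.176, density_resid_sd = 0.211,  # ICC ~ 0.41
    type_mix = list(MJC = c(S1 = 0.66, S2 = 0.20, S3 = 0.04, S4 = 0.10),
                    MNC = c(S1 = 0.45, S2 = 0.25, S3 = 0.12, S4 = 0.18)),
    area_means_um2 = c(S1 = 120, S2 = 220, S3 = 330, S4 = 520),
    area_cv = 0.15,
    member_jitter_um = 7,       # members placed within a site footprint
    missing_landmark_rate = 0.005,
    p_scan_mnc = 56 / 76,       # minor-claw scans are more often lost
    scale_um_per_px = c(0.6, 0.9),
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad))
    stop(sprintf("unknown sim_params entr%s: %s",
                 if (length(bad) > 1) "ies" else "y",
                 paste(bad, collapse = ", ")))
  p[names(over)] <- over
  for (ct in names(p$type_mix)) {
    if (abs(sum(p$type_mix[[ct]]) - 1) > 1e-8)
      stop(sprintf("type_mix for %s must sum to 1", ct))
  }
  if (any(diff(p$area_means_um2) <= 0))
    stop("area_means_um2 must be strictly increasing S1 -> S4")
  if (p$mass_min >= p$mass_max) stop("mass_min must be < mass_max")
  for (ct in names(p$mean_shapes)) {
    m <- sweep(p$mean_shapes[[ct]], 2, colMeans(p$mean_shapes[[ct]]))
    if (qr(m)$rank < 2L)
      stop(sprintf("mean shape for %s is degenerate (collinear landmarks)",
                   ct))
  }
  structure(p, class = "sim_params")
}

## truncated-normal draws via inverse CDF
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

.rot2 <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)

## per-type spatial intensity: kernel mixtures anchored at landmarks.
## Returns n site centres inside the padded hull of `template`.
.sample_site_centres <- function(n, type, template) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  lm <- rownames(template)
  anchor_of <- function(labels, bw, w = NULL) {
    labels <- intersect(labels, lm)
    list(xy = template[labels, , drop = FALSE], bw = bw,
         w = if (is.null(w)) rep(1, length(labels)) else w)
  }
  spec <- switch(type,
    S1 = anchor_of(c("LM2", "LM6", "LM3", "LM9"), bw = 520),
    S2 = anchor_of(c("LM3", "LM4", "LM5", "LM7", "LM8", "LM9"), bw = 260),
    S3 = anchor_of(c("LM10", "LM11", "LM12", "LM13"), bw = 200),
    S4 = anchor_of(c("LM1", "LM15", "LM16"), bw = 170))
  hull <- .claw_outline(template)
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  na <- nrow(spec$xy)
  while (got < n) {
    m <- max(32L, 2L * (n - got))
    a <- sample.int(na, m, replace = TRUE, prob = spec$w)
    cand <- spec$xy[a, , drop = FALSE] +
      matrix(rnorm(2 * m, 0, spec$bw), m, 2)
    ok <- .in_hull(cand[, 1], cand[, 2], hull[, 1], hull[, 2])
    take <- min(sum(ok), n - got)
    if (take > 0) {
      out[(got + 1):(got + take), ] <- cand[ok, , drop = FALSE][
        seq_len(take), , drop = FALSE]
      got <- got + take
    }
  }
  out
}

#' Generate a seeded synthetic population
#'
#' Deterministic given `params$seed` (the caller's RNG state is left
#' untouched).  Masses are truncated-normal; chelar areas follow the
#' log-log allometry with a crab random intercept; per-scan site
#' counts are Poisson with mean `density x area`, where log density
#' carries the mass slope, claw contrast, the female-major-claw
#' multiplier, and crab-level noise; site centres follow the per-type
#' spatial fields within the claw outline; member articulations are
#' jittered within a site footprint so the 20-um grouping rule
#' recovers the site structure.
#'
#' @param params a [sim_params()] object.
#' @param landmarks,points generate the landmark configurations and/or
#'   the articulation points (disable for speed when only part of the
#'   population is needed).
#' @return object of class `synthetic_population`: list with
#'   `specimens` (data.frame), `configurations` (list of
#'   [landmark_config()]), `points` (data.frame), `truth` (the params).
#' @export
generate_population <- function(params = sim_params(), landmarks = TRUE,
                                points = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  .with_seed(params$seed, {
    n <- params$n_female + params$n_male
    crab_id <- sprintf("C%03d", seq_len(n))
    sex <- c(rep("F", params$n_female), rep("M", params$n_male))
    mass <- .rtruncnorm(n, params$mass_mean, params$mass_sd,
                        params$mass_min, params$mass_max)
    site <- sample(c("Hannafore", "MountBatten"), n, replace = TRUE)
    crab_u_area <- rnorm(n, 0, params$area_allometry$crab_sd)
    crab_u_dens <- rnorm(n, 0, params$density_crab_sd)

    al <- params$area_allometry
    spec_rows <- list()
    configs <- list()
    pts_rows <- list()
    for (i in seq_len(n)) {
      has_scan <- c(MJC = TRUE,
                    MNC = runif(1) < params$p_scan_mnc)
      for (ct in c("MJC", "MNC")) {
        log_area <- al$intercept + al$slope * log(mass[i]) +
          (ct == "MNC") * al$claw_mnc +
          (ct == "MJC" && sex[i] == "M") * al$sex_male_mjc +
          crab_u_area[i] + rnorm(1, 0, al$resid_sd)
        area_tot <- exp(log_area)
        area_prop <- area_tot * al$propodus_frac * exp(rnorm(1, 0, 0.03))
        scan_id <- paste(crab_id[i], ct, sep = "_")
        spec_rows[[scan_id]] <- data.frame(
          crab_id = crab_id[i], sex = sex[i], mass_g = mass[i],
          site = site[i], claw_type = ct, scan_id = scan_id,
          chelar_area_total_mm2 = area_tot,
          chelar_area_propodus_mm2 = area_prop,
          has_scan = unname(has_scan[ct]), stringsAsFactors = FALSE)

        template <- params$mean_shapes[[ct]]
        ## linear size factor so the claw's hull area matches area_tot
        hull <- .claw_outline(template, pad = 1)
        t_area_mm2 <- abs(sum(hull[, 1] * c(hull[-1, 2], hull[1, 2]) -
                              c(hull[-1, 1], hull[1, 1]) * hull[, 2])) /
          2 / 1e6
        sizef <- sqrt(area_tot / t_area_mm2)
        true_shape <- template * sizef
        if (ct == "MJC" && sex[i] == "M" && params$sex_shape_effect != 0) {
          ctr <- colMeans(true_shape)
          d <- sweep(true_shape, 2, ctr)
          disp <- cbind(-0.4 * d[, 1], d[, 2])  # stouter, taller
          true_shape <- true_shape + params$sex_shape_effect * disp
        }
        true_shape <- true_shape +
          matrix(rnorm(length(true_shape), 0, params$shape_noise_sd * sizef),
                 ncol = 2)
        ## scan placement in the micrograph frame
        ang <- runif(1, -15, 15) * pi / 180
        shift <- runif(2, 200, 600)
        px_scale <- runif(1, params$scale_um_per_px[1],
                          params$scale_um_per_px[2])
        place <- function(xy) sweep(xy %*% .rot2(ang), 2, shift, "+")

        if (landmarks && has_scan[ct]) {
          for (r in seq_len(params$n_replicates)) {
            digit <- true_shape +
              matrix(rnorm(length(true_shape), 0,
                           params$digit_noise_sd * sizef), ncol = 2)
            um <- place(digit)
            px <- um / px_scale
            rownames(px) <- rownames(template)
            miss <- runif(nrow(px)) < params$missing_landmark_rate
            px[miss, ] <- NA_real_
            sid <- if (params$n_replicates > 1L)
              paste0(scan_id, "_r", r) else scan_id
            configs[[sid]] <- landmark_config(sid, px, claw_type = ct,
                                              scale = px_scale,
                                              missing = miss)
          }
        }

        if (points && has_scan[ct]) {
          log_dens <- log(params$density_base) +
            params$density_mass_slope * log(mass[i] / 0.5) +
            (ct == "MNC") * params$density_claw_mnc +
            (ct == "MJC" && sex[i] == "F") *
              log(params$sex_by_claw_density_multiplier) +
            crab_u_dens[i] + rnorm(1, 0, params$density_resid_sd)
          mix <- params$type_mix[[ct]]
          lam <- exp(log_dens) * area_tot * mix
          cnts <- rpois(4, lam)
          names(cnts) <- names(mix)
          for (tp in names(cnts)) {
            nc <- cnts[[tp]]
            if (nc == 0L) next
            centres <- .sample_site_centres(nc, tp, template) * sizef
            k_mem <- switch(tp, S1 = rep(1L, nc), S2 = rep(2L, nc),
                            S3 = rep(3L, nc), S4 = 4L + rpois(nc, 0.8))
            s_area <- params$area_means_um2[[tp]] *
              exp(rnorm(nc, 0, params$area_cv))
            ## expand all sites of this type at once
            idx <- rep.int(seq_len(nc), k_mem)
            mem <- centres[idx, , drop = FALSE]
            jit <- k_mem[idx] > 1L
            mem[jit, ] <- mem[jit, ] +
              matrix(rnorm(2 * sum(jit), 0, params$member_jitter_um),
                     ncol = 2)
            um <- place(mem)
            pts_rows[[length(pts_rows) + 1L]] <- data.frame(
              scan_id = scan_id, x_um = um[, 1], y_um = um[, 2],
              annotated_type = tp, site_area_um2 = s_area[idx],
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    specimens <- do.call(rbind, spec_rows)
    rownames(specimens) <- NULL
    pts <- if (length(pts_rows)) do.call(rbind, pts_rows)
           else data.frame(scan_id = character(0), x_um = numeric(0),
                           y_um = numeric(0),
                           annotated_type = character(0),
                           site_area_um2 = numeric(0))
    rownames(pts) <- NULL
    structure(list(specimens = specimens, configurations = configs,
                   points = pts, truth = params),
              class = "synthetic_population")
  })
}

#' @exportS3Method base::print
print.synthetic_population <- function(x, ...) {
  cat(sprintf(
    "<synthetic_population> %d crabs (%d F / %d M), %d scans, %d points\n",
    length(unique(x$specimens$crab_id)),
    sum(x$specimens$sex == "F" & x$specimens$claw_type == "MJC"),
    sum(x$specimens$sex == "M" & x$specimens$claw_type == "MJC"),
    length(x$configurations), nrow(x$points)))
  invisible(x)
}

#' Write a synthetic population to disk
#'
#' Emits the same file formats the readers consume: one TPS file per
#' claw type, `points.csv`, `specimens.csv`, and `truth.json` recording
#' every simulation parameter including the seed.
#'
#' @param pop a [generate_population()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ct in c("MJC", "MNC")) {
    cfgs <- Filter(function(cf) identical(cf$claw_type, ct),
                   pop$configurations)
    if (length(cfgs))
      write_tps(cfgs, file.path(dir, paste0(tolower(ct), ".tps")))
  }
  write.csv(pop$points, file.path(dir, "points.csv"), row.names = FALSE)
  spec <- pop$specimens[pop$specimens$has_scan, , drop = FALSE]
  spec$has_scan <- NULL
  write.csv(spec, file.path(dir, "specimens.csv"), row.names = FALSE)
  truth <- unclass(pop$truth)
  truth$mean_shapes <- lapply(truth$mean_shapes, function(m)
    as.data.frame(m))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
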