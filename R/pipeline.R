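## End-to-end pipeline: simulate -> align -> shapestats -> sensilla ->
## maps -> models.  Every stage writes plain-text artifacts plus a
## manifest, and reads its inputs back from the output directory, so
## stages can be run in separate invocations.

.default_config <- function() {
  list(seed = 1L, out = "chelamorph_out", threshold_um = 20,
       n_perm = 999L, alpha = 0.05, area_choice = "total",
       frame_scale = 8L, marker_radius_px = 6L,
       frame_width = 5162L, frame_height = 2947L,
       sim = list())
}

#' Assemble a pipeline configuration
#'
#' Defaults, optionally overlaid with a JSON config file and explicit
#' overrides (in that order of precedence).  The `sim` entry holds
#' [sim_params()] overrides for the simulate stage.
#'
#' @param path optional JSON config file.
#' @param ... explicit overrides.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- .default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
    file_cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg[names(file_cfg)] <- file_cfg
  }
  over <- list(...)
  cfg[names(over)] <- over
  num <- c("seed", "threshold_um", "n_perm", "alpha", "frame_scale",
           "frame_width", "frame_height")
  for (nm in num) if (cfg[[nm]] <= 0)
    stop(sprintf("config '%s' must be positive", nm))
  structure(cfg, class = "pipeline_config")
}

.stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[chelamorph] ", fmt), ...))
}

.write_manifest <- function(cfg, stage, inputs, outputs) {
  man <- list(stage = stage, seed = cfg$seed,
              version = as.character(utils::packageVersion("chelamorph")),
              config = unclass(cfg)[setdiff(names(cfg), "sim")],
              inputs = inputs, outputs = outputs)
  jsonlite::write_json(man,
                       file.path(cfg$out, sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.need_artifact <- function(cfg, rel, stage_hint) {
  p <- file.path(cfg$out, rel)
  if (!file.exists(p))
    stop(sprintf("missing artifact '%s': run the '%s' stage first",
                 rel, stage_hint))
  p
}

.load_population_artifacts <- function(cfg) {
  spec <- read_specimen_table(.need_artifact(cfg, "population/specimens.csv",
                                             "simulate"))
  pts <- read_site_table(.need_artifact(cfg, "population/points.csv",
                                        "simulate"))
  configs <- list()
  for (ct in c("MJC", "MNC")) {
    f <- file.path(cfg$out, "population", paste0(tolower(ct), ".tps"))
    if (file.exists(f)) configs <- c(configs, read_tps(f, claw_type = ct))
  }
  list(specimens = spec, points = pts, configurations = configs)
}

## harmonise both claw types to 15 shared landmarks: the major claw
## loses its molariform-region landmark, the minor claw is reflected
.harmonised_configs <- function(configs) {
  lapply(configs, function(cf) {
    if (identical(cf$claw_type, "MJC")) drop_landmark(cf, "LM14")
    else reflect_y(cf)
  })
}

.stage_simulate <- function(cfg, verbose) {
  params <- do.call(sim_params, c(cfg$sim, list(seed = cfg$seed)))
  pop <- generate_population(params)
  dir <- file.path(cfg$out, "population")
  write_population(pop, dir)
  .stage_log(verbose, "simulate: %d scans, %d points",
             length(pop$configurations), nrow(pop$points))
  .write_manifest(cfg, "simulate", inputs = list(),
                  outputs = list.files(dir))
  invisible(pop)
}

.stage_align <- function(cfg, verbose) {
  pop <- .load_population_artifacts(cfg)
  harmonised <- .harmonised_configs(pop$configurations)
  fit <- align_gpa(harmonised)
  ## aligned coordinates and consensus as CSV
  arr <- fit$aligned
  long <- do.call(rbind, lapply(seq_len(dim(arr)[3]), function(i)
    data.frame(scan_id = fit$scan_ids[i],
               landmark = rownames(arr[, , i]),
               x = arr[, 1, i], y = arr[, 2, i],
               centroid_size = fit$centroid_sizes[i],
               stringsAsFactors = FALSE)))
  write.csv(long, file.path(cfg$out, "aligned.csv"), row.names = FALSE)
  cons <- data.frame(landmark = rownames(fit$mean_shape),
                     x = fit$mean_shape[, 1], y = fit$mean_shape[, 2])
  write.csv(cons, file.path(cfg$out, "consensus.csv"), row.names = FALSE)
  .stage_log(verbose, "align: %d scans aligned (%d excluded), %d iters",
             dim(arr)[3], length(fit$excluded), fit$iterations)
  .write_manifest(cfg, "align",
                  inputs = "population",
                  outputs = c("aligned.csv", "consensus.csv"))
  invisible(fit)
}

.load_gpa_fit <- function(cfg) {
  long <- read.csv(.need_artifact(cfg, "aligned.csv", "align"),
                   stringsAsFactors = FALSE)
  ids <- unique(long$scan_id)
  lms <- unique(long$landmark)
  arr <- array(NA_real_, c(length(lms), 2, length(ids)),
               dimnames = list(lms, c("x", "y"), ids))
  for (i in seq_along(ids)) {
    sub <- long[long$scan_id == ids[i], ]
    arr[sub$landmark, 1, i] <- sub$x
    arr[sub$landmark, 2, i] <- sub$y
  }
  sizes <- vapply(ids, function(id)
    long$centroid_size[long$scan_id == id][1], numeric(1))
  structure(list(aligned = arr,
                 mean_shape = apply(arr, c(1, 2), mean),
                 centroid_sizes = sizes, scan_ids = ids,
                 excluded = character(0), iterations = NA_integer_,
                 converged = TRUE),
            class = "gpa_fit")
}

.stage_shapestats <- function(cfg, verbose) {
  fit <- .load_gpa_fit(cfg)
  spec <- read_specimen_table(.need_artifact(cfg, "population/specimens.csv",
                                             "simulate"))
  idx <- match(fit$scan_ids, spec$scan_id)
  groups <- data.frame(claw_type = spec$claw_type[idx],
                       sex = spec$sex[idx],
                       crab_id = spec$crab_id[idx],
                       stringsAsFactors = FALSE)
  res <- list()
  for (fac in c("claw_type", "sex")) {
    cv <- run_cva(fit, groups, fac, n_perm = cfg$n_perm, seed = cfg$seed)
    res[[fac]] <- list(
      pillai = cv$pillai,
      goodall_F = cv$goodall$statistic,
      goodall_df = c(cv$goodall$df1, cv$goodall$df2),
      mahalanobis = cv$mahalanobis[1, 2],
      procrustes_distance = cv$procrustes_dist[1, 2],
      perm_p_pillai = cv$perm_p$pillai$p,
      perm_p_goodall = cv$perm_p$goodall$p,
      n_perm = cfg$n_perm, dims_retained = cv$q)
    write.csv(data.frame(scan_id = fit$scan_ids, groups,
                         cv$scores),
              file.path(cfg$out, sprintf("cva_scores_%s.csv", fac)),
              row.names = FALSE)
  }
  ## centroid-size contrasts (size analysed separately from shape)
  res$centroid_size <- lapply(c(claw_type = "claw_type", sex = "sex"),
                              function(fac) {
    f <- factor(groups[[fac]])
    tt <- stats::t.test(fit$centroid_sizes ~ f)
    list(means = as.list(tapply(fit$centroid_sizes, f, mean)),
         t = unname(tt$statistic), p = tt$p.value)
  })
  jsonlite::write_json(res, file.path(cfg$out, "shape_stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .stage_log(verbose, "shapestats: claw Pillai %.3f, sex Pillai %.3f",
             res$claw_type$pillai, res$sex$pillai)
  .write_manifest(cfg, "shapestats", inputs = "aligned.csv",
                  outputs = c("shape_stats.json",
                              "cva_scores_claw_type.csv",
                              "cva_scores_sex.csv"))
  invisible(res)
}

.stage_sensilla <- function(cfg, verbose) {
  pop <- .load_population_artifacts(cfg)
  profiles <- build_profiles(pop$points, pop$specimens,
                             area_choice = cfg$area_choice,
                             threshold_um = cfg$threshold_um)
  write.csv(profiles, file.path(cfg$out, "profiles.csv"),
            row.names = FALSE)
  .stage_log(verbose, "sensilla: %d profiles, mean density %.2f /mm^2",
             nrow(profiles), mean(profiles$absolute_density))
  .write_manifest(cfg, "sensilla", inputs = "population",
                  outputs = "profiles.csv")
  invisible(profiles)
}

.stage_maps <- function(cfg, verbose) {
  pop <- .load_population_artifacts(cfg)
  frame <- reference_frame(cfg$frame_width, cfg$frame_height,
                           scale = cfg$frame_scale)
  ## marker radius is specified at full frame resolution (default 6 px)
  radius <- max(0L, as.integer(round(cfg$marker_radius_px /
                                       cfg$frame_scale)))
  dir.create(file.path(cfg$out, "maps"), showWarnings = FALSE)
  outputs <- character(0)
  for (ct in c("MJC", "MNC")) {
    cfgs <- Filter(function(cf) identical(cf$claw_type, ct),
                   pop$configurations)
    if (length(cfgs) < 2L) next
    fit <- align_gpa(cfgs)
    maps <- frequency_maps(pop, fit, frame, claw_type = ct,
                           marker_radius_px = radius)
    for (nm in setdiff(names(maps), "all")) {
      f <- sprintf("maps/%s_%s.pgm", tolower(ct), nm)
      write_pgm(maps[[nm]], file.path(cfg$out, f))
      outputs <- c(outputs, f)
    }
    if (!is.null(maps$all)) {
      f <- sprintf("maps/%s_all.pgm", tolower(ct))
      write_pgm(maps$all, file.path(cfg$out, f))
      fc <- sprintf("maps/%s_composite.ppm", tolower(ct))
      write_ppm(composite_rgb(maps[setdiff(names(maps), "all")]),
                file.path(cfg$out, fc))
      fh <- sprintf("maps/%s_heat.ppm", tolower(ct))
      write_ppm(heat_rgb(maps$all), file.path(cfg$out, fh))
      outputs <- c(outputs, f, fc, fh)
    }
    sidecar <- list(claw_type = ct, frame = unclass(frame),
                    marker_radius_px = radius,
                    n_scans = if (length(maps)) maps[[1]]$n_scans else 0L)
    jsonlite::write_json(sidecar,
                         file.path(cfg$out,
                                   sprintf("maps/%s_frame.json",
                                           tolower(ct))),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  .stage_log(verbose, "maps: wrote %d rasters", length(outputs))
  .write_manifest(cfg, "maps", inputs = "population", outputs = outputs)
  invisible(outputs)
}

.stage_models <- function(cfg, verbose) {
  profiles <- read.csv(.need_artifact(cfg, "profiles.csv", "sensilla"),
                       stringsAsFactors = FALSE)
  suite <- run_analysis_suite(profiles, alpha = cfg$alpha)
  write.csv(suite$f_table, file.path(cfg$out, "f_table.csv"),
            row.names = FALSE)
  vcs <- lapply(suite$fits, function(r)
    c(as.list(r$fit$varcomp), icc = icc_random_intercept(r$fit)))
  jsonlite::write_json(vcs, file.path(cfg$out, "varcomp.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  coefs <- do.call(rbind, lapply(names(suite$fits), function(nm)
    data.frame(outcome = nm,
               term = names(suite$fits[[nm]]$fit$coefficients),
               estimate = unname(suite$fits[[nm]]$fit$coefficients),
               stringsAsFactors = FALSE)))
  write.csv(coefs, file.path(cfg$out, "coefficients.csv"),
            row.names = FALSE)
  .stage_log(verbose, "models: %d outcomes fitted", length(suite$fits))
  .write_manifest(cfg, "models", inputs = "profiles.csv",
                  outputs = c("f_table.csv", "varcomp.json",
                              "coefficients.csv"))
  invisible(suite)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order.  Stage names:
#' `simulate`, `align`, `shapestats`, `sensilla`, `maps`, `models`,
#' or `all`.  Rerunning with the same configuration reproduces every
#' stochastic output bit for bit (all randomness flows from
#' `config$seed`).
#'
#' @param config a [pipeline_config()].
#' @param stages character vector of stage names.
#' @param verbose log progress to stderr.
#' @return invisibly, a named list of the stage results.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = "all", verbose = FALSE) {
  order <- c("simulate", "align", "shapestats", "sensilla", "maps",
             "models")
  if ("all" %in% stages) stages <- order
  bad <- setdiff(stages, order)
  if (length(bad))
    stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  stages <- order[order %in% stages]
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  runners <- list(simulate = .stage_simulate, align = .stage_align,
                  shapestats = .stage_shapestats,
                  sensilla = .stage_sensilla, maps = .stage_maps,
                  models = .stage_models)
  results <- list()
  for (st in stages) {
    .stage_log(verbose, "stage %s ...", st)
    results[[st]] <- runners[[st]](config, verbose)
  }
  invisible(results)
}

#' Command-line entry point
#'
#' Parses CLI flags and dispatches to [run_pipeline()].  Usage:
#' `chelamorph <stages> [--config file.json] [--seed N] [--out dir]
#' [--threshold-um X] [--n-perm N] [--frame-scale N] [--verbose]`
#' where `<stages>` is a comma-separated list or `all`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status, 0 on success (invisibly).
#' @export
chela_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  spec <- list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character",
                          default = "chelamorph_out"),
    optparse::make_option("--threshold-um", dest = "threshold_um",
                          type = "double", default = 20),
    optparse::make_option("--n-perm", dest = "n_perm", type = "integer",
                          default = 999L),
    optparse::make_option("--frame-scale", dest = "frame_scale",
                          type = "integer", default = 8L),
    optparse::make_option("--verbose", action = "store_true",
                          default = FALSE))
  parser <- optparse::OptionParser(
    usage = "chelamorph <stages|all> [options]", option_list = spec)
  parsed <- optparse::parse_args(parser, args = args,
                                 positional_arguments = TRUE)
  stages <- if (length(parsed$args)) {
    unlist(strsplit(parsed$args, ","))
  } else "all"
  o <- parsed$options
  cfg <- pipeline_config(o$config, seed = o$seed, out = o$out,
                         threshold_um = o$threshold_um,
                         n_perm = o$n_perm, frame_scale = o$frame_scale)
  status <- tryCatch({
    run_pipeline(cfg, stages = stages, verbose = o$verbose)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
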