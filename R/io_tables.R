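## CSV readers for articulation-point and specimen tables.
##
## The supplementary tables this emulates have no fixed published column
## layout, so both readers accept a column-name mapping from the caller's
## headers onto the canonical names used throughout the package.

.map_columns <- function(df, required, optional, col_map, what) {
  canon <- c(required, optional)
  if (length(col_map)) {
    bad <- setdiff(names(col_map), canon)
    if (length(bad))
      stop(sprintf("unknown canonical column(s) in col_map: %s",
                   paste(bad, collapse = ", ")))
    for (nm in names(col_map)) {
      src <- col_map[[nm]]
      if (!src %in% names(df))
        stop(sprintf("%s: mapped column '%s' (for %s) not present",
                     what, src, nm))
      names(df)[names(df) == src] <- nm
    }
  }
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column %s", what, paste(miss, collapse = ", ")))
  extra <- setdiff(names(df), canon)
  if (length(extra))
    message(sprintf("%s: ignoring unknown column(s): %s",
                    what, paste(extra, collapse = ", ")))
  df[, intersect(canon, names(df)), drop = FALSE]
}

.check_numeric <- function(df, cols, what) {
  for (cl in cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]) & nzchar(trimws(df[[cl]])))
    if (length(bad))
      stop(sprintf("%s: non-numeric value in column '%s' at row %d",
                   what, cl, bad[1L]))
    df[[cl]] <- v
  }
  df
}

#' Read a sensillar articulation-point table
#'
#' Reads a CSV of individually digitised setal articulation coordinates
#' (one row per articulation point, micrometres in the micrograph
#' frame).  Canonical columns: `scan_id`, `x_um`, `y_um` (required),
#' `annotated_type` (`S1`..`S4`) and `site_area_um2` (optional).  Other
#' columns are dropped with a message.
#'
#' @param path CSV path (UTF-8, header row).
#' @param col_map named character vector mapping canonical names to the
#'   file's actual headers, e.g. `c(x_um = "X", y_um = "Y")`.
#' @return data.frame with the canonical columns.
#' @export
read_site_table <- function(path, col_map = character(0)) {
  if (!file.exists(path)) stop(sprintf("file '%s' not found", path))
  ## read as character: 'F' sexes and empty cells must survive intact
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 colClasses = "character")
  df <- .map_columns(df,
                     required = c("scan_id", "x_um", "y_um"),
                     optional = c("annotated_type", "site_area_um2"),
                     col_map = col_map, what = "site table")
  df <- .check_numeric(df, intersect(c("x_um", "y_um", "site_area_um2"),
                                     names(df)), "site table")
  if (!all(is.finite(df$x_um)) || !all(is.finite(df$y_um)))
    stop("site table: non-finite coordinate")
  if ("annotated_type" %in% names(df)) {
    df$annotated_type[!nzchar(trimws(df$annotated_type))] <- NA_character_
    tt <- df$annotated_type
    ok <- is.na(tt) | tt %in% c("S1", "S2", "S3", "S4")
    if (!all(ok))
      stop(sprintf("site table: invalid annotated_type '%s' at row %d",
                   tt[which(!ok)[1L]], which(!ok)[1L]))
  }
  if ("site_area_um2" %in% names(df) &&
      any(!is.na(df$site_area_um2) & df$site_area_um2 <= 0))
    stop("site table: site_area_um2 must be positive where present")
  df$scan_id <- as.character(df$scan_id)
  df
}

#' Read a specimen metadata table
#'
#' One row per (crab, claw type): crab identity, sex, body mass and the
#' two chelar area measurements (total, including the dactylus, and
#' propodus-only), both in mm^2.
#'
#' @inheritParams read_site_table
#' @return data.frame with canonical columns `crab_id`, `sex` (`F`/`M`),
#'   `mass_g`, `claw_type` (`MJC`/`MNC`), `site`,
#'   `chelar_area_total_mm2`, `chelar_area_propodus_mm2`, `scan_id`.
#' @export
read_specimen_table <- function(path, col_map = character(0)) {
  if (!file.exists(path)) stop(sprintf("file '%s' not found", path))
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 colClasses = "character")
  df <- .map_columns(df,
                     required = c("crab_id", "sex", "mass_g", "claw_type",
                                  "chelar_area_total_mm2",
                                  "chelar_area_propodus_mm2"),
                     optional = c("site", "scan_id"),
                     col_map = col_map, what = "specimen table")
  df <- .check_numeric(df, c("mass_g", "chelar_area_total_mm2",
                             "chelar_area_propodus_mm2"), "specimen table")
  if (!all(df$sex %in% c("F", "M")))
    stop("specimen table: sex must be 'F' or 'M'")
  if (!all(df$claw_type %in% c("MJC", "MNC")))
    stop("specimen table: claw_type must be 'MJC' or 'MNC'")
  if (any(df$mass_g <= 0)) stop("specimen table: mass_g must be positive")
  if (any(df$chelar_area_total_mm2 <= 0) ||
      any(df$chelar_area_propodus_mm2 <= 0))
    stop("specimen table: chelar areas must be positive")
  dup <- duplicated(df[, c("crab_id", "claw_type")])
  if (any(dup))
    stop(sprintf("specimen table: duplicate record for crab %s / %s",
                 df$crab_id[dup][1L], df$claw_type[dup][1L]))
  sex_per_crab <- tapply(df$sex, df$crab_id, function(s) length(unique(s)))
  if (any(sex_per_crab > 1L))
    stop("specimen table: a crab_id appears with more than one sex")
  if (!"scan_id" %in% names(df))
    df$scan_id <- paste(df$crab_id, df$claw_type, sep = "_")
  df$crab_id <- as.character(df$crab_id)
  df
}
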