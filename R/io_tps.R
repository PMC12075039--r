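## TPS landmark file reader/writer and the landmark_config container.
##
## Coordinate convention for files: micrograph pixels, origin top-left,
## y increasing downward.  All internal shape mathematics is
## convention-agnostic; the convention only matters when relating
## configurations back to raster images.

#' Landmark configuration for one claw scan
#'
#' Bundles the ordered 2-D landmarks digitised from a single scanning
#' electron micrograph of a cheliped, together with its identity and
#' scale metadata.  Major chelipeds (MJC) carry 16 landmarks
#' (`LM1`..`LM16`), minor chelipeds (MNC) 15 (`LM1`..`LM15`).
#'
#' @param scan_id character scalar identifying the scan.
#' @param landmarks numeric k x 2 matrix of landmark coordinates
#'   (micrograph pixels unless noted otherwise).  Rows may be named
#'   `LM1`.. ; if unnamed, labels are generated.
#' @param claw_type `"MJC"` or `"MNC"`, or `NA` when unknown.
#' @param scale optional positive micrometre-per-pixel scale factor.
#' @param missing logical vector marking landmarks that could not be
#'   digitised; their coordinates are stored as `NA`.
#' @param validate check landmark-count invariants for known claw types.
#'
#' @return An object of class `landmark_config`: a list with elements
#'   `scan_id`, `claw_type`, `landmarks` (k x 2 matrix with `LMi` row
#'   names), `scale` and `missing`.
#' @export
landmark_config <- function(scan_id, landmarks, claw_type = NA_character_,
                            scale = NULL, missing = NULL, validate = TRUE) {
  landmarks <- as.matrix(landmarks)
  if (ncol(landmarks) != 2L)
    stop("landmarks must be a k x 2 matrix")
  storage.mode(landmarks) <- "double"
  k <- nrow(landmarks)
  if (is.null(rownames(landmarks)))
    rownames(landmarks) <- paste0("LM", seq_len(k))
  colnames(landmarks) <- c("x", "y")
  if (is.null(missing)) missing <- !complete.cases(landmarks)
  missing <- as.logical(missing)
  if (length(missing) != k)
    stop("missing mask length must equal landmark count")
  if (validate && !is.na(claw_type)) {
    claw_type <- match.arg(claw_type, c("MJC", "MNC"))
    need <- if (claw_type == "MJC") 16L else 15L
    if (k != need)
      stop(sprintf("%s configuration '%s' must have %d landmarks, found %d",
                   claw_type, scan_id, need, k))
  }
  if (any(!missing & !complete.cases(landmarks)))
    stop(sprintf("scan '%s': non-finite coordinates outside the missing mask",
                 scan_id))
  if (!is.null(scale)) {
    scale <- as.numeric(scale)
    if (!is.finite(scale) || scale <= 0)
      stop(sprintf("scan '%s': scale must be a positive number", scan_id))
  }
  structure(list(scan_id = as.character(scan_id),
                 claw_type = claw_type,
                 landmarks = landmarks,
                 scale = scale,
                 missing = missing),
            class = "landmark_config")
}

#' @exportS3Method base::print
print.landmark_config <- function(x, ...) {
  cat(sprintf("<landmark_config> scan %s (%s), %d landmarks%s%s\n",
              x$scan_id, ifelse(is.na(x$claw_type), "?", x$claw_type),
              nrow(x$landmarks),
              if (!is.null(x$scale)) sprintf(", scale %g um/px", x$scale) else "",
              if (any(x$missing)) sprintf(", %d missing", sum(x$missing)) else ""))
  invisible(x)
}

#' Coordinates of a configuration in scaled (micrometre) units
#'
#' Multiplies pixel coordinates by the stored scale.  Configurations
#' without a scale are returned unchanged (unit scale assumed).
#'
#' @param config a [landmark_config()].
#' @return k x 2 numeric matrix.
#' @export
scaled_coords <- function(config) {
  s <- if (is.null(config$scale)) 1 else config$scale
  config$landmarks * s
}

#' Read a TPS landmark file
#'
#' Parses the standard TPS text format as emitted by the TPS software
#' family: each record starts with `LM=<k>`, followed by k
#' whitespace-separated coordinate pairs, then optional `IMAGE=`, `ID=`
#' and `SCALE=` lines.  `CURVES=`/outline blocks are not supported and
#' other keys are ignored.  Missing landmarks may be encoded as
#' `NA NA` or negative sentinel pairs `-1 -1` are NOT treated as
#' missing (only non-numeric/NA tokens are).
#'
#' @param path path to a TPS file.
#' @param claw_type optional claw type (`"MJC"`/`"MNC"`) to stamp and
#'   validate on every record; by default inferred from the landmark
#'   count (16 = MJC, 15 = MNC, otherwise `NA`).
#' @return a list of [landmark_config()] objects, in file order.
#' @export
read_tps <- function(path, claw_type = NULL) {
  if (!file.exists(path)) stop(sprintf("TPS file '%s' not found", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop(sprintf("TPS file '%s' is empty", path))
  starts <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (length(starts) == 0L)
    stop(sprintf("TPS file '%s': no LM= records found", path))
  ends <- c(starts[-1L] - 1L, length(lines))
  configs <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", block[1L],
                                         ignore.case = TRUE)))
    if (is.na(k) || k < 1L)
      stop(sprintf("record %d: malformed LM= line '%s'", r, block[1L]))
    body <- block[-1L]
    is_key <- grepl("^[A-Za-z]+\\s*=", body)
    coord_lines <- body[!is_key]
    toks <- unlist(strsplit(paste(coord_lines, collapse = " "), "\\s+"))
    toks <- toks[nzchar(toks)]
    if (length(toks) != 2L * k)
      stop(sprintf(
        "record %d: LM=%d but %d coordinate values listed (expected %d)",
        r, k, length(toks), 2L * k))
    vals <- suppressWarnings(as.numeric(toks))
    xy <- matrix(vals, ncol = 2L, byrow = TRUE)
    keys <- body[is_key]
    getkey <- function(name) {
      hit <- grep(paste0("^", name, "\\s*="), keys, ignore.case = TRUE,
                  value = TRUE)
      if (length(hit) == 0L) NULL
      else trimws(sub("^[A-Za-z]+\\s*=\\s*", "", hit[[1L]]))
    }
    id <- getkey("ID")
    if (is.null(id)) id <- sprintf("record_%d", r)
    scale <- getkey("SCALE")
    if (!is.null(scale)) scale <- as.numeric(scale)
    ct <- claw_type
    if (is.null(ct)) ct <- if (k == 16L) "MJC" else if (k == 15L) "MNC"
                           else NA_character_
    configs[[r]] <- landmark_config(id, xy, claw_type = ct, scale = scale)
  }
  configs
}

#' Write configurations to a TPS file
#'
#' Inverse of [read_tps()]: `read_tps(write_tps(x, f))` recovers `x`.
#' Within each claw type the landmark count must be constant.
#'
#' @param configs non-empty list of [landmark_config()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path) {
  if (length(configs) == 0L) stop("configs must be non-empty")
  for (ct in c("MJC", "MNC")) {
    ks <- vapply(configs, function(cf)
      if (identical(cf$claw_type, ct)) nrow(cf$landmarks) else NA_integer_,
      integer(1))
    ks <- ks[!is.na(ks)]
    if (length(unique(ks)) > 1L)
      stop(sprintf("mixed landmark counts within claw type %s: %s",
                   ct, paste(unique(ks), collapse = ", ")))
  }
  out <- character(0)
  for (cf in configs) {
    xy <- cf$landmarks
    out <- c(out,
             sprintf("LM=%d", nrow(xy)),
             paste(format(xy[, 1], trim = TRUE, digits = 15),
                   format(xy[, 2], trim = TRUE, digits = 15)),
             sprintf("ID=%s", cf$scan_id))
    if (!is.null(cf$scale))
      out <- c(out, sprintf("SCALE=%s", format(cf$scale, digits = 15)))
  }
  writeLines(out, path)
  invisible(path)
}
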