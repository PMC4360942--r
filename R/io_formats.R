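## Calibration file (human-readable key-value text with a schema version),
## quantitative output writer (four 32-bit float TIFFs + manifest), and
## histogram export.

CALIBRATION_SCHEMA_VERSION <- "1.0"
CALIBRATION_REQUIRED_KEYS <- c("gain_dn_per_photon", "offset_dn",
                               "read_noise_var_dn2", "modulation_contrast")

fmt_num <- function(x) sprintf("%.17g", x)

parse_kv_file <- function(path) {
  if (!file.exists(path)) ps_io_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  has_colon <- grepl(":", lines, fixed = TRUE)
  if (!all(has_colon)) {
    ps_schema_error(sprintf("malformed line in %s: %s", path,
                            lines[!has_colon][1]))
  }
  keys <- trimws(sub(":.*$", "", lines))
  vals <- trimws(sub("^[^:]*:", "", lines))
  setNames(as.list(vals), keys)
}

#' Write a calibration profile to a calibration file
#'
#' The calibration file is versioned, human-readable key-value text: the
#' four calibration numbers (camera gain, dark offset, read-noise variance,
#' modulation contrast) at full double precision, the camera bit depth, and
#' free-text `meta.*` provenance lines.  It round-trips losslessly through
#' [read_calibration()].
#'
#' @param profile A [calibration_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(profile, path) {
  stopifnot(inherits(profile, "calibration_profile"))
  g <- profile$gain
  lines <- c(
    sprintf("schema_version: %s", CALIBRATION_SCHEMA_VERSION),
    sprintf("gain_dn_per_photon: %s", fmt_num(g$gain_dn_per_photon)),
    sprintf("offset_dn: %s", fmt_num(g$offset_dn)),
    sprintf("read_noise_var_dn2: %s", fmt_num(g$read_noise_var_dn2)),
    sprintf("modulation_contrast: %s",
            fmt_num(profile$contrast$modulation_contrast)),
    if (!is.na(g$bit_depth)) sprintf("bit_depth: %d", g$bit_depth))
  meta <- profile$created_with
  for (k in names(meta)) {
    lines <- c(lines, sprintf("meta.%s: %s", k, as.character(meta[[k]])))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a calibration file
#'
#' Inverse of [write_calibration()].  Unknown schema versions and missing
#' required fields are schema errors -- there is no silent fallback,
#' because processing data against the wrong calibration silently corrupts
#' every downstream photon value.
#'
#' @param path Path to a calibration file.
#' @return A [calibration_profile()].  Fit diagnostics (per-level points,
#'   pixel counts) are not persisted in the file and come back empty.
#' @export
read_calibration <- function(path) {
  kv <- parse_kv_file(path)
  ver <- kv[["schema_version"]]
  if (is.null(ver)) {
    ps_schema_error(sprintf("%s: missing required field `schema_version`.", path))
  }
  if (!identical(ver, CALIBRATION_SCHEMA_VERSION)) {
    ps_schema_error(sprintf(
      "%s: unsupported calibration schema version \"%s\" (this build reads %s).",
      path, ver, CALIBRATION_SCHEMA_VERSION))
  }
  missing <- setdiff(CALIBRATION_REQUIRED_KEYS, names(kv))
  if (length(missing)) {
    ps_schema_error(sprintf("%s: missing required field(s): %s.",
                            path, paste(missing, collapse = ", ")))
  }
  num <- function(k) {
    v <- suppressWarnings(as.numeric(kv[[k]]))
    if (is.na(v)) ps_schema_error(sprintf("%s: field `%s` is not numeric.", path, k))
    v
  }
  bit_depth <- if (!is.null(kv[["bit_depth"]])) as.integer(num("bit_depth"))
               else NA_integer_
  gain <- new_gain_fit(gain_dn_per_photon = num("gain_dn_per_photon"),
                       offset_dn = num("offset_dn"),
                       read_noise_var_dn2 = num("read_noise_var_dn2"),
                       bit_depth = bit_depth)
  if (gain$gain_dn_per_photon <= 0) {
    ps_schema_error(sprintf("%s: gain must be positive.", path))
  }
  meta_keys <- grep("^meta\\.", names(kv), value = TRUE)
  meta <- setNames(lapply(meta_keys, function(k) kv[[k]]),
                   sub("^meta\\.", "", meta_keys))
  calibration_profile(gain, num("modulation_contrast"), created_with = meta)
}

#' Digest of a calibration profile's numeric content
#'
#' MD5 over the canonical full-precision rendering of the four calibration
#' numbers.  Recorded in every output manifest so stale-calibration
#' ambiguity is impossible: any change to any calibration value changes
#' the digest.
#'
#' @param profile A [calibration_profile()].
#' @return A 32-character hex string.
#' @export
calibration_digest <- function(profile) {
  stopifnot(inherits(profile, "calibration_profile"))
  canon <- paste(fmt_num(profile$gain$gain_dn_per_photon),
                 fmt_num(profile$gain$offset_dn),
                 fmt_num(profile$gain$read_noise_var_dn2),
                 fmt_num(profile$contrast$modulation_contrast), sep = "|")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeChar(canon, tmp, eos = NULL)
  unname(tools::md5sum(tmp))
}

#' Write the four quantitative output images and a manifest
#'
#' Writes the photon-calibrated output of one or more depths as four
#' 32-bit float TIFFs -- `widefield.tif`, `sectioned.tif`,
#' `widefield_noise.tif`, `sectioned_noise.tif` (multi-page when more than
#' one depth) -- plus a `manifest.txt` recording the pixel unit
#' ("photons"), the calibration digest, and the depth table.  32-bit float
#' (not integer) output preserves sub-photon noise-map values; each TIFF's
#' description tag also declares the unit so downstream tools never have
#' to guess.
#'
#' @param results A `quant_result` or list of them (consistent sizes).
#' @param out_dir Output directory (created if needed).
#' @param calib Optional [calibration_profile()] whose digest goes into the
#'   manifest.
#' @param prefix Optional file-name prefix.
#' @return Invisibly, a list with `files` (named character vector of the
#'   four image paths) and `manifest`.
#' @export
write_quant_outputs <- function(results, out_dir, calib = NULL, prefix = "") {
  if (inherits(results, "quant_result")) results <- list(results)
  if (!is.list(results) || length(results) == 0L ||
      !all(vapply(results, inherits, TRUE, "quant_result"))) {
    ps_usage_error("`results` must be one or more quant_result objects.")
  }
  dims <- dim(results[[1]])
  for (r in results) {
    if (!identical(dim(r), dims)) {
      ps_stack_error("all depths must share the same image dimensions.")
    }
  }
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    ps_io_error(sprintf("cannot create output directory: %s", out_dir))
  }
  digest <- if (is.null(calib)) "none" else calibration_digest(calib)
  files <- character(0)
  for (nm in quant_images()) {
    field <- switch(nm, widefield = "widefield_photons",
                    sectioned = "sectioned_photons", nm)
    pages <- lapply(results, function(r) r[[field]])
    path <- file.path(out_dir, paste0(prefix, nm, ".tif"))
    write_tiff(pages, path, sample_format = "float",
               description = sprintf("photonsim %s; unit=photons; calibration=%s",
                                     nm, digest))
    files[nm] <- path
  }
  manifest <- file.path(out_dir, paste0(prefix, "manifest.txt"))
  depth_lines <- vapply(results, function(r) {
    sprintf("depth: %d %s", r$depth_index,
            if (is.na(r$depth_um)) "NA" else fmt_num(r$depth_um))
  }, character(1))
  writeLines(c(
    "manifest_version: 1.0",
    "units: photons",
    sprintf("calibration_digest: %s", digest),
    sprintf("image_rows: %d", dims[1]),
    sprintf("image_cols: %d", dims[2]),
    sprintf("n_depths: %d", length(results)),
    sprintf("file.%s: %s", names(files), basename(files)),
    "depth_table: index depth_um",
    depth_lines,
    sprintf("created: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
    manifest)
  invisible(list(files = files, manifest = manifest))
}

#' Export histogram tables as delimited text
#'
#' Writes the tibble produced by [photon_noise_histograms()] as
#' tab-separated text.
#'
#' @param histograms Tibble from [photon_noise_histograms()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_histograms <- function(histograms, path) {
  utils::write.table(histograms, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
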