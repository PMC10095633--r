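# Dataset I/O.  Titration CSV dialect: header `lt_molar,response`; assay
# metadata travels in a sidecar JSON file (keys: pt_molar, alpha_lb,
# mw_gmol, specific_volume, kp_lb_lw, response_kind).

#' Read a titration dataset from CSV
#'
#' Expects a two-column CSV with header `lt_molar,response`.  If a sidecar
#' metadata file exists (either `sidecar`, or `<path>.json` by default),
#' its keys are merged into the dataset metadata.
#'
#' @param path CSV file path.
#' @param sidecar Optional path to a JSON metadata file; defaults to
#'   `<path>.json` when that file exists.
#' @return A [titration_dataset()].
#' @export
read_titration_csv <- function(path, sidecar = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("lt_molar", "response"), names(raw))
  if (length(missing_cols)) {
    stop(sprintf(
      "missing column(s) in %s: %s",
      path, paste(missing_cols, collapse = ", ")
    ), call. = FALSE)
  }
  for (col in c("lt_molar", "response")) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) | !is.finite(vals))
    if (length(bad)) {
      stop(sprintf(
        "non-numeric value in column `%s`, row %d of %s",
        col, bad[1], path
      ), call. = FALSE)
    }
    raw[[col]] <- vals
  }
  bad_lt <- which(raw$lt_molar <= 0)
  if (length(bad_lt)) {
    stop(sprintf(
      "`lt_molar` must be > 0; offending row %d of %s",
      bad_lt[1], path
    ), call. = FALSE)
  }
  if (nrow(raw) < 3L) {
    stop(sprintf("%s has %d data rows; at least 3 required", path, nrow(raw)),
      call. = FALSE
    )
  }
  meta <- list()
  if (is.null(sidecar)) {
    candidate <- paste0(path, ".json")
    if (file.exists(candidate)) sidecar <- candidate
  }
  if (!is.null(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  kind <- if (!is.null(meta$response_kind)) meta$response_kind else "saturation"
  titration_dataset(raw$lt_molar, raw$response,
    response_kind = kind, metadata = meta
  )
}

#' Write a titration dataset to CSV
#'
#' Values are written at full double precision so a write/read roundtrip is
#' the identity.  Metadata, when present, is written to `<path>.json`.
#'
#' @param dataset A [titration_dataset()].
#' @param path Output CSV path.
#' @param write_sidecar Write the metadata sidecar JSON (default TRUE when
#'   metadata is non-empty).
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(dataset, path, write_sidecar = TRUE) {
  stopifnot(is.data.frame(dataset))
  lines <- c(
    "lt_molar,response",
    sprintf("%.17g,%.17g", dataset$lt_molar, dataset$response)
  )
  writeLines(lines, path)
  meta <- attr(dataset, "metadata")
  if (isTRUE(write_sidecar) && length(meta)) {
    meta$response_kind <- attr(dataset, "response_kind")
    jsonlite::write_json(meta, paste0(path, ".json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}
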