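#' Write spectra to an MGF file
#'
#' Minimal Mascot Generic Format writer: one `BEGIN IONS`/`END IONS` block
#' per spectrum with `TITLE` (the spectrum identifier), `RTINSECONDS` and
#' `PEPMASS`, followed by `m/z intensity` peak lines. Peaks with missing
#' intensity are skipped (MGF has no encoding for them).
#'
#' @param spectra List of [spectrum()] objects.
#' @param path Output file.
#' @param pepmass Optional numeric vector of precursor masses; defaults to
#'   the maximum peak m/z as a placeholder.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path, pepmass = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    keep <- !is.na(sp$intensity)
    pm <- if (!is.null(pepmass)) pepmass[i] else max(sp$mz)
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", sp$id),
      sprintf("PEPMASS=%.6f", pm),
      if (!is.na(sp$retention_time)) sprintf("RTINSECONDS=%.3f", sp$retention_time),
      sprintf("%.6f %.6f", sp$mz[keep], sp$intensity[keep]),
      "END IONS", ""
    ), con)
  }
  invisible(path)
}

#' Read spectra from an MGF file
#'
#' Counterpart of [write_mgf()]. `TITLE` becomes the spectrum identifier;
#' `RTINSECONDS` is required for retention-time metrics and left `NA` when
#' absent.
#'
#' @param path MGF file.
#' @return Named list of [spectrum()] objects keyed by identifier.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  stopifnot(length(begins) == length(ends))
  out <- list()
  for (i in seq_along(begins)) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    title <- sub("^TITLE=", "", grep("^TITLE=", block, value = TRUE)[1L])
    rt_line <- grep("^RTINSECONDS=", block, value = TRUE)
    rt <- if (length(rt_line) > 0L) as.numeric(sub("^RTINSECONDS=", "", rt_line[1L])) else NA_real_
    peak_lines <- block[grepl("^[0-9]", block)]
    parts <- strsplit(peak_lines, "[ \t]+")
    mz <- vapply(parts, function(p) as.numeric(p[1L]), numeric(1))
    int <- vapply(parts, function(p) as.numeric(p[2L]), numeric(1))
    out[[title]] <- spectrum(mz, int, retention_time = rt, id = title)
  }
  out
}
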