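# Delimited-text I/O for TCSPC histograms and steady-state spectra.
# Format: '#'-prefixed header lines, then two columns (time_ns + counts,
# or wavelength_nm + intensity), comma or whitespace separated.

parse_two_columns <- function(path, what) {
  lines <- readLines(path)
  is_header <- grepl("^\\s*#", lines)
  header <- lines[is_header]
  data_idx <- which(!is_header & nzchar(trimws(lines)))
  if (!length(data_idx))
    pa_stop("parse_error", "%s: no data rows", path)
  xs <- numeric(length(data_idx))
  ys <- numeric(length(data_idx))
  for (k in seq_along(data_idx)) {
    i <- data_idx[k]
    fields <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    if (length(fields) != 2)
      pa_stop("parse_error", "%s line %d: expected 2 fields, found %d",
              path, i, length(fields))
    v <- suppressWarnings(as.numeric(fields))
    if (any(is.na(v)))
      pa_stop("parse_error", "%s line %d: non-numeric field", path, i)
    xs[k] <- v[1]; ys[k] <- v[2]
  }
  if (is.unsorted(xs, strictly = TRUE)) {
    bad <- data_idx[which(diff(xs) <= 0)[1] + 1]
    pa_stop("parse_error", "%s line %d: %s axis not strictly increasing",
            path, bad, what)
  }
  list(x = xs, y = ys, header = header, lines = data_idx)
}

#' Read / write TCSPC histograms and spectra as delimited text
#'
#' Two-column text files with `#`-prefixed header lines: channel time in
#' ns and integer photon counts for histograms, wavelength in nm and
#' relative intensity for spectra.  Comma or whitespace separated.
#' Writing preserves the header lines verbatim, and counts round-trip
#' exactly; spectra round-trip to 1e-9 relative.
#'
#' @param path file path.
#' @return `read_histogram()` returns a `tcspc_histogram` (with `irf =
#'   NULL`); `read_spectrum()` a [steady_spectrum()].  Writers return
#'   `path` invisibly.
#' @name tcspc_io
#' @export
read_histogram <- function(path) {
  p <- parse_two_columns(path, "time")
  if (any(p$y < 0)) {
    bad <- p$lines[which(p$y < 0)[1]]
    pa_stop("parse_error", "%s line %d: negative count", path, bad)
  }
  if (any(abs(p$y - round(p$y)) > 1e-9)) {
    bad <- p$lines[which(abs(p$y - round(p$y)) > 1e-9)[1]]
    pa_stop("parse_error", "%s line %d: non-integer count", path, bad)
  }
  widths <- diff(p$x)
  if (length(widths) && diff(range(widths)) > 1e-6 * mean(widths)) {
    bad <- p$lines[which.max(abs(widths - mean(widths))) + 1]
    pa_stop("parse_error", "%s line %d: non-uniform channel width",
            path, bad)
  }
  structure(list(times = p$x, counts = as.integer(round(p$y)), irf = NULL,
                 meta = list(header = p$header, path = path)),
            class = "tcspc_histogram")
}

#' @param hist a `tcspc_histogram`.
#' @rdname tcspc_io
#' @export
write_histogram <- function(hist, path) {
  header <- hist$meta$header %||% c("# TCSPC histogram", "# time_ns counts")
  rows <- sprintf("%.12g %d", hist$times, hist$counts)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname tcspc_io
#' @export
read_spectrum <- function(path) {
  p <- parse_two_columns(path, "wavelength")
  if (any(p$y < 0)) {
    bad <- p$lines[which(p$y < 0)[1]]
    pa_stop("parse_error", "%s line %d: negative intensity", path, bad)
  }
  sp <- steady_spectrum(p$x, p$y)
  sp$header <- p$header
  sp
}

#' @param spectrum a [steady_spectrum()].
#' @rdname tcspc_io
#' @export
write_spectrum <- function(spectrum, path) {
  header <- spectrum$header %||%
    c("# steady-state emission spectrum", "# wavelength_nm intensity")
  rows <- sprintf("%.12g %.12e", spectrum$wavelengths, spectrum$intensity)
  writeLines(c(header, rows), path)
  invisible(path)
}
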