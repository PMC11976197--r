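# Experimental peak lists.
#
# A spectrum is a tibble of (mz, intensity) with attributes for compound
# label, MS stage and acquisition mass range.  Intensities are relative
# (% of base peak); absolute counts are normalized on input.

#' Construct a spectrum
#'
#' @param mz numeric m/z values (Th).
#' @param intensity intensities; normalized to % of the base peak if the
#'   maximum exceeds 100 (absolute counts).
#' @param label compound label.
#' @param ms_stage MS stage (2 = one fragmentation stage).
#' @param mass_range acquisition mass range c(lo, hi) in Th, or NULL.
#' @return A tibble of class `ms_spectrum`, sorted by m/z.
#' @export
ms_spectrum <- function(mz, intensity, label = "", ms_stage = 2L,
                        mass_range = NULL) {
  if (length(mz) == 0) {
    abort("empty spectrum", class = "cidfrag_format_error")
  }
  if (any(intensity <= 0)) {
    abort("intensities must be positive", class = "cidfrag_format_error")
  }
  if (max(intensity) > 100) intensity <- 100 * intensity / max(intensity)
  o <- order(mz)
  out <- tibble(mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]))
  structure(out, label = label, ms_stage = as.integer(ms_stage),
            mass_range = mass_range,
            class = c("ms_spectrum", class(out)))
}

spectrum_meta <- function(s) {
  list(label = attr(s, "label"), ms_stage = attr(s, "ms_stage"),
       mass_range = attr(s, "mass_range"))
}

#' Read an experimental peak list
#'
#' Supported formats: two-column whitespace text (`m/z intensity`, `#`
#' comments), MGF (first BEGIN IONS block) and MSP (NIST dialect, first
#' record).  Intensities given as absolute counts are normalized to % of the
#' base peak.
#'
#' @param source file path.
#' @param format "auto" (by extension), "txt", "mgf" or "msp".
#' @param ... passed to [ms_spectrum()] (label, ms_stage, mass_range).
#' @return An `ms_spectrum`.
#' @export
read_peaklist <- function(source, format = c("auto", "txt", "mgf", "msp"), ...) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(source))
    format <- if (ext %in% c("mgf", "msp")) ext else "txt"
  }
  lines <- readLines(source, warn = FALSE)
  parse_peak_lines <- function(pl, where) {
    pl <- trimws(pl)
    pl <- pl[nzchar(pl)]
    if (length(pl) == 0) {
      abort(paste0("empty spectrum in ", source), class = "cidfrag_format_error")
    }
    parts <- strsplit(pl, "[[:space:];]+")
    mz <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
    it <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
    bad <- which(is.na(mz) | is.na(it))
    if (length(bad) > 0) {
      abort(sprintf("cannot parse peak at %s line %d: '%s'", source,
                    where[bad[1]], pl[bad[1]]),
            class = "cidfrag_format_error")
    }
    neg <- which(it <= 0)
    if (length(neg) > 0) {
      abort(sprintf("non-positive intensity at %s line %d", source, where[neg[1]]),
            class = "cidfrag_format_error")
    }
    dup <- which(duplicated(mz))
    if (length(dup) > 0) {
      abort(sprintf("duplicate m/z %.4f at %s line %d", mz[dup[1]], source,
                    where[dup[1]]),
            class = "cidfrag_format_error")
    }
    list(mz = mz, intensity = it)
  }
  if (format == "txt") {
    keep <- which(!grepl("^\\s*(#|$)", lines))
    pk <- parse_peak_lines(lines[keep], keep)
    return(ms_spectrum(pk$mz, pk$intensity, ...))
  }
  if (format == "mgf") {
    beg <- which(lines == "BEGIN IONS")[1]
    end <- which(lines == "END IONS")[1]
    if (is.na(beg) || is.na(end) || end <= beg) {
      abort(paste0("no BEGIN IONS/END IONS block in ", source),
            class = "cidfrag_format_error")
    }
    block <- lines[(beg + 1):(end - 1)]
    idx <- (beg + 1):(end - 1)
    is_peak <- !grepl("=", block, fixed = TRUE)
    pk <- parse_peak_lines(block[is_peak], idx[is_peak])
    title <- sub("^TITLE=", "", grep("^TITLE=", block, value = TRUE)[1])
    args <- list(...)
    if (is.null(args$label) && !is.na(title)) args$label <- title
    return(do.call(ms_spectrum, c(list(pk$mz, pk$intensity), args)))
  }
  # MSP
  np <- grep("^Num [Pp]eaks:", lines)[1]
  if (is.na(np)) {
    abort(paste0("no 'Num Peaks:' record in ", source),
          class = "cidfrag_format_error")
  }
  n <- as.integer(sub("^Num [Pp]eaks:\\s*", "", lines[np]))
  body <- lines[(np + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  toks <- unlist(strsplit(trimws(body), "[;[:space:]]+"))
  toks <- toks[nzchar(toks)]
  vals <- suppressWarnings(as.numeric(toks))
  if (anyNA(vals) || length(vals) < 2 * n) {
    abort(paste0("malformed MSP peak block in ", source),
          class = "cidfrag_format_error")
  }
  mz <- vals[seq(1, 2 * n, by = 2)]
  it <- vals[seq(2, 2 * n, by = 2)]
  if (any(it <= 0)) {
    abort(paste0("non-positive intensity in ", source),
          class = "cidfrag_format_error")
  }
  name <- sub("^Name:\\s*", "", grep("^Name:", lines, value = TRUE)[1])
  args <- list(...)
  if (is.null(args$label) && !is.na(name)) args$label <- name
  do.call(ms_spectrum, c(list(mz, it), args))
}

#' Filter peaks by relative intensity
#'
#' Retains peaks with relative intensity >= `threshold` (% of base peak);
#' the retained count is the denominator N of the absolute score.
#'
#' @param spectrum an `ms_spectrum`.
#' @param threshold relative intensity threshold in %, e.g. 5 or 10.
#' @return The filtered `ms_spectrum` (metadata preserved, `threshold`
#'   attribute recorded).
#' @export
filter_peaks <- function(spectrum, threshold = 5) {
  keep <- spectrum$intensity >= threshold
  out <- spectrum[keep, ]
  meta <- spectrum_meta(spectrum)
  structure(out, label = meta$label, ms_stage = meta$ms_stage,
            mass_range = meta$mass_range, threshold = threshold,
            class = class(spectrum))
}
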