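# Matching fragmentation trees to experimental peaks and scoring.
#
# A filtered peak is annotated when at least one tree ion's m/z lies within
# the match tolerance.  The weighted score s is the sum of the relative
# intensities of the annotated peaks F (s_max: over all filtered peaks); the
# absolute score is n = |F| out of N filtered peaks.

#' Annotate a spectrum with fragmentation-tree ions
#'
#' Every filtered peak is matched against all tree-node m/z values within
#' `tolerance`; the precursor \[M+H\]+ is matchable like any other ion.
#' Ambiguous matches keep all candidate ions ranked by |dm/z|, then heat of
#' formation.  Peaks below the acquisition mass-range lower bound are
#' excluded from the peak set before matching.
#'
#' @param tree a `frag_tree`.
#' @param spectrum an `ms_spectrum` (apply [filter_peaks()] first, or pass
#'   `threshold`).
#' @param tolerance match tolerance; interpreted in Th for `unit = "Th"`
#'   (default 0.5, unit-resolution ion-trap data) or in ppm for
#'   `unit = "ppm"` (high-resolution data).
#' @param threshold optional relative-intensity threshold applied before
#'   matching (otherwise the spectrum is used as given).
#' @param unit "Th" or "ppm".
#' @param include_precursor set FALSE for comparator-style scoring in which
#'   root protomers never annotate the precursor peak.
#' @return An `annotation_result`: list with `peaks` (tibble: mz, intensity,
#'   annotated, matches), `matches` (tibble: peak, ion id, mz, dmz),
#'   `tolerance`, `threshold`, `tree`.
#' @export
annotate <- function(tree, spectrum, tolerance = 0.5, threshold = NULL,
                     unit = c("Th", "ppm"), include_precursor = TRUE) {
  unit <- match.arg(unit)
  if (!is.null(threshold)) spectrum <- filter_peaks(spectrum, threshold)
  thr <- attr(spectrum, "threshold") %||% 0
  mr <- attr(spectrum, "mass_range")
  if (!is.null(mr)) {
    spectrum <- structure(spectrum[spectrum$mz >= mr[1] & spectrum$mz <= mr[2], ],
                          label = attr(spectrum, "label"),
                          ms_stage = attr(spectrum, "ms_stage"),
                          mass_range = mr, threshold = thr,
                          class = class(spectrum))
  }
  nodes <- tree$nodes
  if (!is.null(nodes) && nrow(nodes) > 0 && !include_precursor) {
    nodes <- nodes[!nodes$id %in% tree$roots, , drop = FALSE]
  }
  matches <- list()
  annotated <- logical(nrow(spectrum))
  for (i in seq_len(nrow(spectrum))) {
    if (is.null(nodes) || nrow(nodes) == 0) break
    tol <- if (unit == "Th") tolerance else spectrum$mz[i] * tolerance * 1e-6
    d <- abs(nodes$mz - spectrum$mz[i])
    hit <- which(d <= tol)
    if (length(hit) == 0) next
    annotated[i] <- TRUE
    o <- hit[order(d[hit], nodes$hof[hit], nodes$id[hit])]
    matches[[length(matches) + 1]] <- tibble(
      peak = spectrum$mz[i], intensity = spectrum$intensity[i],
      ion = nodes$id[o], formula = nodes$formula[o],
      ion_mz = nodes$mz[o], dmz = nodes$mz[o] - spectrum$mz[i])
  }
  peaks <- tibble(mz = spectrum$mz, intensity = spectrum$intensity,
                  annotated = annotated)
  structure(list(peaks = peaks,
                 matches = if (length(matches)) dplyr::bind_rows(matches) else
                   tibble(peak = numeric(0), intensity = numeric(0),
                          ion = integer(0), formula = character(0),
                          ion_mz = numeric(0), dmz = numeric(0)),
                 tolerance = tolerance, unit = unit, threshold = thr,
                 label = attr(spectrum, "label"), tree = tree),
            class = "annotation_result")
}

#' @export
print.annotation_result <- function(x, ...) {
  s <- weighted_score(x)
  a <- absolute_score(x)
  cat(sprintf("<annotation> %s: %s\n", x$label %||% "", score_string(x)))
  invisible(x)
}

#' Intensity-weighted annotation score
#'
#' s = sum of the relative intensities of the annotated peaks; s_max = sum
#' over all peaks above the intensity threshold.  Integer-exact when the
#' printed intensities are integers.
#'
#' @param annotation an `annotation_result`.
#' @return Named numeric c(s =, s_max =).
#' @export
weighted_score <- function(annotation) {
  c(s = sum(annotation$peaks$intensity[annotation$peaks$annotated]),
    s_max = sum(annotation$peaks$intensity))
}

#' Absolute annotation score
#'
#' n annotated peaks out of N peaks above the intensity threshold.
#'
#' @param annotation an `annotation_result`.
#' @return Named integer c(n =, N =).
#' @export
absolute_score <- function(annotation) {
  c(n = sum(annotation$peaks$annotated), N = nrow(annotation$peaks))
}

# "determined/maximum (n/N)" string as printed in score tables
score_string <- function(annotation) {
  w <- weighted_score(annotation); a <- absolute_score(annotation)
  fmt <- function(v) formatC(v, format = "fg")
  sprintf("%s/%s (%d/%d)", fmt(w[["s"]]), fmt(w[["s_max"]]), a[["n"]], a[["N"]])
}

#' Tidy an annotation result
#' @param x an `annotation_result`.
#' @param ... unused.
#' @return The per-peak tibble with best-match columns.
#' @export
tidy.annotation_result <- function(x, ...) {
  best <- x$matches |>
    dplyr::group_by(.data$peak) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(mz = "peak", best_ion = "ion", best_formula = "formula",
                  best_dmz = "dmz")
  dplyr::left_join(x$peaks, best, by = "mz")
}

#' One-row summary of an annotation result
#' @param x an `annotation_result`.
#' @param ... unused.
#' @export
glance.annotation_result <- function(x, ...) {
  w <- weighted_score(x); a <- absolute_score(x)
  tibble(s = w[["s"]], s_max = w[["s_max"]], n = a[["n"]], N = a[["N"]],
         tolerance = x$tolerance, threshold = x$threshold,
         score = score_string(x))
}

#' Annotation report
#'
#' Human-readable per-peak table (peak, intensity, matched ion, formula,
#' rule path from a root protomer) plus the "determined/maximum (n/N)" score
#' line; optionally written as machine-readable JSON.
#'
#' @param annotation an `annotation_result`.
#' @param path optional path: writes the JSON form and returns it invisibly.
#' @return Character vector of report lines (invisibly when `path` given).
#' @export
report <- function(annotation, path = NULL) {
  tree <- annotation$tree
  pathto <- function(ion_id) {
    if (is.null(tree) || nrow(tree$edges) == 0) return("")
    steps <- character(0)
    cur <- ion_id
    for (k in seq_len(nrow(tree$nodes))) {
      e <- tree$edges[tree$edges$child == cur, , drop = FALSE]
      if (nrow(e) == 0) break
      e <- e[1, ]
      steps <- c(paste0(e$rule, if (nzchar(e$neutrals)) paste0(" (-", e$neutrals, ")")),
                 steps)
      cur <- e$parent
    }
    paste(steps, collapse = " > ")
  }
  lines <- c(sprintf("compound: %s", annotation$label %||% ""),
             sprintf("tolerance: %.3g %s; intensity threshold: %g%%",
                     annotation$tolerance, annotation$unit, annotation$threshold),
             sprintf("score: %s", score_string(annotation)), "")
  for (i in seq_len(nrow(annotation$peaks))) {
    p <- annotation$peaks[i, ]
    m <- annotation$matches[annotation$matches$peak == p$mz, , drop = FALSE]
    if (nrow(m) == 0) {
      lines <- c(lines, sprintf("%8.2f %5.0f%%  -", p$mz, p$intensity))
    } else {
      lines <- c(lines, sprintf("%8.2f %5.0f%%  %s (m/z %.4f)  %s",
                                p$mz, p$intensity, m$formula[1], m$ion_mz[1],
                                pathto(m$ion[1])))
    }
  }
  if (!is.null(path)) {
    obj <- list(format = "cidfrag_report", version = 1L,
                label = annotation$label,
                tolerance = annotation$tolerance, unit = annotation$unit,
                threshold = annotation$threshold,
                score = score_string(annotation),
                weighted = as.list(weighted_score(annotation)),
                absolute = as.list(absolute_score(annotation)),
                peaks = annotation$peaks, matches = annotation$matches,
                config_hash = if (!is.null(tree)) tree$config_hash else NULL)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(lines))
  }
  lines
}

#' Read back a JSON annotation report
#' @param path JSON file written by [report()].
#' @return A list with score components and the per-peak tables.
#' @export
read_report_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "cidfrag_report")) {
    abort("not a cidfrag report JSON file", class = "cidfrag_format_error")
  }
  obj$peaks <- as_tibble(obj$peaks)
  obj$matches <- as_tibble(obj$matches)
  obj
}
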