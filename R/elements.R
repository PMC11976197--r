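#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# package-local cache (element masses, evaluator caches)
.cidfrag_env <- new.env(parent = emptyenv())

#' Monoisotopic element masses
#'
#' Returns the table of monoisotopic atomic masses shipped with the package
#' (most abundant isotope, IUPAC/CODATA values to at least 6 decimals).
#'
#' @return A tibble with columns `element` and `mass` (u).
#' @export
element_masses <- function() {
  if (is.null(.cidfrag_env$masses)) {
    path <- system.file("extdata", "monoisotopic_masses.csv", package = "cidfrag")
    tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
    .cidfrag_env$masses <- stats::setNames(tab$mass, tab$element)
  }
  tibble(element = names(.cidfrag_env$masses),
         mass = unname(.cidfrag_env$masses))
}

element_mass_vec <- function() {
  element_masses() # ensure cache
  .cidfrag_env$masses
}

# Hill-order element sorting: C, H, then alphabetical
hill_order <- function(elements) {
  rest <- sort(setdiff(elements, c("C", "H")))
  intersect(c("C", "H", rest), elements)
}

#' Construct an elemental formula
#'
#' An elemental formula is a named integer count vector plus the net charge
#' (elementary charges) and a radical (open-shell) flag.  Two formulas are
#' equal iff their count maps, charge and radical flag are identical.
#'
#' @param counts named integer vector of element counts (zero counts dropped).
#' @param charge integer net charge.
#' @param radical logical, open-shell species?
#' @return An object of class `elemental_formula`.
#' @export
elemental_formula <- function(counts, charge = 0L, radical = FALSE) {
  counts <- counts[counts > 0]
  known <- names(element_mass_vec())
  bad <- setdiff(names(counts), known)
  if (length(bad) > 0) {
    abort(paste0("unknown element(s): ", paste(bad, collapse = ", "),
                 "; supported: ", paste(known, collapse = ", ")),
          class = "cidfrag_element_error")
  }
  counts <- counts[hill_order(names(counts))]
  structure(list(counts = as.integer(stats::setNames(counts, names(counts))) |>
                   stats::setNames(names(counts)),
                 charge = as.integer(charge),
                 radical = isTRUE(radical)),
            class = "elemental_formula")
}

#' Parse a formula string such as "C18H24O2"
#'
#' @param x formula string; a trailing "+" or "-" sets the charge.
#' @return An `elemental_formula`.
#' @export
parse_formula <- function(x) {
  charge <- 0L
  radical <- FALSE
  core <- x
  repeat {
    last <- substr(core, nchar(core), nchar(core))
    if (last == "+") charge <- charge + 1L
    else if (last == "-") charge <- charge - 1L
    else if (last == ".") radical <- TRUE
    else break
    core <- substr(core, 1, nchar(core) - 1)
  }
  parts <- regmatches(core, gregexpr("([A-Z][a-z]?)([0-9]*)", core))[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0 && nzchar(core)) {
    abort(paste0("cannot parse formula: ", x), class = "cidfrag_formula_error")
  }
  el <- sub("[0-9]*$", "", parts)
  n <- as.integer(ifelse(grepl("[0-9]+$", parts),
                         sub("^[A-Za-z]+", "", parts), "1"))
  counts <- tapply(n, el, sum)
  elemental_formula(stats::setNames(as.integer(counts), names(counts)),
                    charge = charge, radical = radical)
}

#' @export
format.elemental_formula <- function(x, ...) {
  body <- paste0(names(x$counts),
                 ifelse(x$counts > 1, x$counts, ""), collapse = "")
  if (body == "") body <- "(empty)"
  chg <- if (x$charge > 0) strrep("+", x$charge)
         else if (x$charge < 0) strrep("-", -x$charge) else ""
  rad <- if (x$radical) "." else ""
  paste0(body, rad, chg)
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
`==.elemental_formula` <- function(e1, e2) {
  identical(e1$counts, e2$counts) &&
    e1$charge == e2$charge && e1$radical == e2$radical
}

# sum of formulas (ignores charge/radical of parts unless combine = TRUE)
sum_formulas <- function(fls) {
  all_el <- unique(unlist(lapply(fls, function(f) names(f$counts))))
  counts <- stats::setNames(integer(length(all_el)), all_el)
  for (f in fls) counts[names(f$counts)] <- counts[names(f$counts)] + f$counts
  charge <- sum(vapply(fls, function(f) f$charge, integer(1)))
  nrad <- sum(vapply(fls, function(f) as.integer(f$radical), integer(1)))
  elemental_formula(counts, charge = charge, radical = (nrad %% 2L) == 1L)
}

#' Monoisotopic m/z of a formula
#'
#' Sum of monoisotopic atomic masses divided by |charge|.  Following the
#' convention of unit- and high-resolution ESI(+) ion annotations, no
#' electron-mass correction is applied (e.g. C18H25O2+ gives 273.19 at two
#' decimals, C10H9O+ gives 145.07).  For neutral species (charge 0) the
#' neutral monoisotopic mass is returned.
#'
#' @param formula an `elemental_formula` (or formula string).
#' @return m/z in Th (full precision; round for display).
#' @export
monoisotopic_mz <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  masses <- element_mass_vec()
  m <- sum(masses[names(formula$counts)] * formula$counts)
  if (formula$charge == 0) m else m / abs(formula$charge)
}
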