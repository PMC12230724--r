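#' The eight secondary-structure components
#'
#' Component order used throughout the package: regular mid-helix
#' (`Helix1`), distorted helix ends (`Helix2`), antiparallel beta-sheet in
#' three twist classes (`Anti1` left-hand twisted, `Anti2` relaxed/slightly
#' right-hand twisted, `Anti3` right-hand twisted), parallel beta-sheet
#' (`Parallel`), `Turn`, and everything else (`Others`).
#'
#' @return Character vector of the eight component names, in canonical order.
#' @export
ss_components <- function() {
  c("Helix1", "Helix2", "Anti1", "Anti2", "Anti3", "Parallel", "Turn", "Others")
}

#' Construct a secondary-structure fraction vector
#'
#' A valid secondary-structure vector has eight nonnegative fractions in
#' canonical component order that sum to one.
#'
#' @param x Numeric vector of length 8 (named or unnamed; names, when
#'   present, must match [ss_components()] after reordering).
#' @param normalize If `TRUE`, rescale a nonnegative vector to unit sum
#'   instead of erroring on small deviations.
#' @return Named numeric vector of length 8, class `ss_vector`.
#' @export
ss_vector <- function(x, normalize = FALSE) {
  comps <- ss_components()
  if (length(x) != 8L) abort("a secondary-structure vector has 8 components")
  x <- as.numeric(unlist(x))
  names(x) <- if (!is.null(names(x)) && all(sort(names(x)) == sort(comps))) {
    names(x)
  } else comps
  x <- x[comps]
  if (any(!is.finite(x)) || any(x < -1e-9))
    abort("secondary-structure fractions must be finite and nonnegative")
  x[x < 0] <- 0
  s <- sum(x)
  if (normalize) {
    if (s <= 0) abort("cannot normalize an all-zero fraction vector")
    x <- x / s
  } else if (abs(s - 1) > 1e-9) {
    abort(sprintf("secondary-structure fractions must sum to 1 (got %.12g)", s))
  } else {
    x <- x / s
  }
  structure(x, class = c("ss_vector", "numeric"))
}

#' @export
print.ss_vector <- function(x, ...) {
  cat("<ss_vector>\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Grouped secondary-structure sums
#'
#' Collapses the eight components into the conventional reporting groups:
#' Helix (`Helix1 + Helix2`), Antiparallel (`Anti1 + Anti2 + Anti3`), Beta
#' (antiparallel + parallel) and `Turn + Others`.
#'
#' @param ss An [ss_vector()] (or coercible numeric of length 8).
#' @return A tibble with columns `group` and `fraction`.
#' @export
ss_groups <- function(ss) {
  ss <- ss_vector(ss)
  tibble(
    group = c("Helix", "Antiparallel", "Beta", "Turn+Others"),
    fraction = c(
      ss[["Helix1"]] + ss[["Helix2"]],
      ss[["Anti1"]] + ss[["Anti2"]] + ss[["Anti3"]],
      ss[["Anti1"]] + ss[["Anti2"]] + ss[["Anti3"]] + ss[["Parallel"]],
      ss[["Turn"]] + ss[["Others"]]
    )
  )
}
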