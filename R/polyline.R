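#' Construct a polyline
#'
#' A polyline is an ordered sequence of (x, y) vertices in millimetres in the
#' midsagittal plane. The package-wide coordinate convention is: x increases
#' anterior to posterior, y increases inferior to superior.
#'
#' @param x A two-column numeric matrix (or object coercible to one) of
#'   vertex coordinates, columns x_mm and y_mm.
#' @return A numeric matrix of class `cc_polyline` with columns `x_mm`, `y_mm`.
#' @examples
#' p <- polyline(cbind(c(0, 3), c(0, 4)))
#' arc_length(p)
#' @export
polyline <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 2L)
    stop("a polyline needs exactly two coordinate columns (x_mm, y_mm)")
  storage.mode(x) <- "double"
  colnames(x) <- c("x_mm", "y_mm")
  problems <- polyline_problems(x)
  if (length(problems))
    stop("invalid polyline: ", paste(problems, collapse = "; "))
  structure(x, class = c("cc_polyline", "matrix", "array"))
}

# invariant checks shared by polyline() and validate_contour_pair();
# returns a character vector of violations (empty = valid)
polyline_problems <- function(x) {
  probs <- character()
  if (nrow(x) < 2L) probs <- c(probs, "fewer than 2 vertices")
  if (!all(is.finite(x))) probs <- c(probs, "non-finite coordinates")
  if (nrow(x) >= 2L && all(is.finite(x))) {
    seg <- sqrt(rowSums((x[-1L, , drop = FALSE] - x[-nrow(x), , drop = FALSE])^2))
    if (any(seg == 0))
      probs <- c(probs, sprintf("zero-length segment at vertex %d",
                                which(seg == 0)[1L]))
  }
  probs
}

is_polyline <- function(x) inherits(x, "cc_polyline")

as_polyline <- function(x) {
  if (is_polyline(x)) x else polyline(x)
}

#' Construct a contour pair
#'
#' Bundles one subject's traced upper and lower midsagittal callosal boundary
#' polylines. Both boundaries are stored anterior-first (smaller x first).
#'
#' @param subject_id Subject identifier (string).
#' @param upper,lower Polylines (see [polyline()]) for the upper and lower
#'   callosal boundary.
#' @return An object of class `cc_contour_pair`.
#' @seealso [validate_contour_pair()], [compute_profile()]
#' @export
contour_pair <- function(subject_id, upper, lower) {
  structure(
    list(subject_id = as.character(subject_id),
         upper = as_polyline(upper),
         lower = as_polyline(lower)),
    class = "cc_contour_pair")
}

#' @export
print.cc_contour_pair <- function(x, ...) {
  cat(sprintf("<contour pair> subject %s: upper %d vertices, lower %d vertices\n",
              x$subject_id, nrow(x$upper), nrow(x$lower)))
  invisible(x)
}

#' Validate a contour pair
#'
#' Checks the structural invariants of a traced boundary pair. Hard geometry
#' violations (too few vertices, non-finite coordinates, zero-length segments)
#' are reported as errors. Endpoint coincidence of the upper and lower
#' boundary is reported as a warning only: real tracings meet at the rostral
#' tip and the bottom of the splenium only approximately, and synthetic test
#' shapes need not meet at all.
#'
#' @param pair A [contour_pair()].
#' @param endpoint_tol Coincidence tolerance in mm for the anterior (and,
#'   separately, posterior) endpoints of the two boundaries. Default 2 mm.
#' @return A list with character vectors `errors` and `warnings`; both empty
#'   for a fully valid pair.
#' @export
validate_contour_pair <- function(pair, endpoint_tol = 2.0) {
  stopifnot(inherits(pair, "cc_contour_pair"))
  errors <- character()
  warnings <- character()
  for (side in c("upper", "lower")) {
    probs <- polyline_problems(unclass(pair[[side]]))
    if (length(probs))
      errors <- c(errors, paste0(side, " boundary: ", probs))
  }
  if (!length(errors)) {
    u <- pair$upper; l <- pair$lower
    d_ant <- sqrt(sum((u[1L, ] - l[1L, ])^2))
    d_post <- sqrt(sum((u[nrow(u), ] - l[nrow(l), ])^2))
    if (d_ant > endpoint_tol)
      warnings <- c(warnings, sprintf(
        "anterior endpoints %.2f mm apart (tolerance %.2f mm)", d_ant, endpoint_tol))
    if (d_post > endpoint_tol)
      warnings <- c(warnings, sprintf(
        "posterior endpoints %.2f mm apart (tolerance %.2f mm)", d_post, endpoint_tol))
  }
  list(errors = errors, warnings = warnings)
}
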