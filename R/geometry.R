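#' Arc length of a polyline
#'
#' Sum of Euclidean segment lengths, in mm.
#'
#' @param poly A [polyline()].
#' @return Total arc length (strictly positive for a valid polyline).
#' @export
arc_length <- function(poly) {
  poly <- as_polyline(poly)
  sum(segment_lengths(poly))
}

segment_lengths <- function(poly) {
  d <- poly[-1L, , drop = FALSE] - poly[-nrow(poly), , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Orient a boundary anterior-first
#'
#' Under the package convention x increases anterior to posterior, so the
#' rostral tip (Position 1) is the endpoint with the smaller x. The polyline
#' is reversed iff its first vertex has larger x than its last; an exact tie
#' is returned unchanged.
#'
#' @param poly A [polyline()].
#' @return The polyline, anterior endpoint first.
#' @export
orient_anterior_first <- function(poly) {
  poly <- as_polyline(poly)
  if (poly[1L, 1L] > poly[nrow(poly), 1L])
    poly <- polyline(poly[nrow(poly):1L, , drop = FALSE])
  poly
}

#' Resample a polyline to equidistant points along its arc length
#'
#' Places `n_points` points at equal arc-length spacing along the piecewise
#' linear source curve: the point at index i sits at cumulative arc length
#' (i-1)/(n_points-1) times the total length, obtained by linear
#' interpolation within the segment containing that abscissa. The first and
#' last points equal the source endpoints exactly.
#'
#' @param poly A [polyline()].
#' @param n_points Number of output points (default 100, as in the standard
#'   pointwise thickness protocol); must be at least 2.
#' @return A `cc_polyline` of exactly `n_points` vertices.
#' @export
resample_equidistant <- function(poly, n_points = 100L) {
  poly <- as_polyline(poly)
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2L)
    stop("n_points must be an integer >= 2")
  cum <- c(0, cumsum(segment_lengths(poly)))
  s <- seq(0, cum[length(cum)], length.out = n_points)
  out <- cbind(stats::approx(cum, poly[, 1L], xout = s)$y,
               stats::approx(cum, poly[, 2L], xout = s)$y)
  # endpoints are exact by definition of the parameterization
  out[1L, ] <- poly[1L, ]
  out[n_points, ] <- poly[nrow(poly), ]
  polyline(out)
}

#' Midline between two resampled boundaries
#'
#' The callosal midline is the spatial average of the resampled upper and
#' lower boundaries. Two modes are provided:
#' \describe{
#'   \item{`pointwise_average` (default)}{midline point i is the coordinate
#'     mean of upper point i and lower point i.}
#'   \item{`resampled_average`}{the pointwise average curve is additionally
#'     re-resampled to `n` equidistant points along its own arc length,
#'     for sensitivity analyses of the midline parameterization.}
#' }
#'
#' @param upper,lower Resampled boundaries with the same number of points.
#' @param mode Midline mode, see Details.
#' @return A matrix of midline coordinates, one row per position.
#' @export
compute_midline <- function(upper, lower,
                            mode = c("pointwise_average", "resampled_average")) {
  mode <- match.arg(mode)
  upper <- as_polyline(upper); lower <- as_polyline(lower)
  if (nrow(upper) != nrow(lower))
    stop(sprintf("boundaries have mismatched point counts (%d vs %d)",
                 nrow(upper), nrow(lower)))
  mid <- (unclass(upper) + unclass(lower)) / 2
  if (mode == "resampled_average")
    mid <- unclass(resample_equidistant(mid, nrow(upper)))
  colnames(mid) <- c("x_mm", "y_mm")
  mid
}

#' Pointwise thickness profile of a contour pair
#'
#' Converts one subject's traced boundary pair into the pointwise thickness
#' profile: both boundaries are oriented anterior-first and resampled to
#' `n_points` equidistant surface points, the midline is computed as the
#' spatial average of the resampled boundaries, and the callosal distance
#' value (CDV) at each position is the distance from the upper surface point
#' to the corresponding midline point. Under the default
#' `pointwise_average` midline this equals the distance from the lower point
#' to the midline and half the upper-lower inter-point distance, so one CDV
#' per position summarizes both surfaces; thickness is 2 CDV.
#'
#' @param pair A [contour_pair()].
#' @param n_points Number of positions (default 100).
#' @param midline_mode Passed to [compute_midline()].
#' @return An object of class `cc_thickness_profile`: a list with
#'   `subject_id`, `position` (1-based), resampled `upper` and `lower`
#'   boundaries, `midline`, `cdv` and `thickness` (both in mm).
#' @export
compute_profile <- function(pair, n_points = 100L,
                            midline_mode = c("pointwise_average",
                                             "resampled_average")) {
  stopifnot(inherits(pair, "cc_contour_pair"))
  midline_mode <- match.arg(midline_mode)
  up <- resample_equidistant(orient_anterior_first(pair$upper), n_points)
  lo <- resample_equidistant(orient_anterior_first(pair$lower), n_points)
  mid <- compute_midline(up, lo, midline_mode)
  if (midline_mode == "pointwise_average") {
    # half the inter-point distance; identical to either point-to-midline
    # distance by construction of the pointwise average
    cdv <- sqrt(rowSums((unclass(up) - unclass(lo))^2)) / 2
  } else {
    cdv <- sqrt(rowSums((unclass(up) - mid)^2))
  }
  structure(
    list(subject_id = pair$subject_id,
         position = seq_len(n_points),
         upper = up, lower = lo, midline = mid,
         cdv = cdv, thickness = 2 * cdv),
    class = "cc_thickness_profile")
}

#' @export
print.cc_thickness_profile <- function(x, ...) {
  cat(sprintf(
    "<thickness profile> subject %s: %d positions, mean thickness %.2f mm\n",
    x$subject_id, length(x$cdv), mean(x$thickness)))
  invisible(x)
}

#' Compute thickness profiles for a collection of contour pairs
#'
#' @param pairs List of [contour_pair()] objects.
#' @inheritParams compute_profile
#' @return A named list of `cc_thickness_profile` objects.
#' @export
compute_profiles <- function(pairs, n_points = 100L,
                             midline_mode = "pointwise_average") {
  out <- lapply(pairs, compute_profile, n_points = n_points,
                midline_mode = midline_mode)
  names(out) <- vapply(out, `[[`, character(1), "subject_id")
  out
}

#' Subjects-by-positions CDV matrix
#'
#' @param profiles A list of `cc_thickness_profile` objects, or an existing
#'   numeric matrix (returned unchanged).
#' @return Numeric matrix, one row per subject (rownames = subject ids), one
#'   column per position.
#' @export
cdv_matrix <- function(profiles) {
  if (is.matrix(profiles)) return(profiles)
  stopifnot(all(vapply(profiles, inherits, logical(1), "cc_thickness_profile")))
  m <- do.call(rbind, lapply(profiles, `[[`, "cdv"))
  rownames(m) <- unname(vapply(profiles, `[[`, character(1), "subject_id"))
  m
}

#' Write thickness profiles to CSV
#'
#' Long-format export, header
#' `subject_id,position,mid_x_mm,mid_y_mm,cdv_mm,thickness_mm`, position
#' 1-based.
#'
#' @param profiles List of `cc_thickness_profile` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p)
    data.frame(subject_id = p$subject_id, position = p$position,
               mid_x_mm = p$midline[, 1L], mid_y_mm = p$midline[, 2L],
               cdv_mm = p$cdv, thickness_mm = p$thickness)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a thickness-profile CSV into a CDV matrix
#'
#' Reads the format written by [write_profiles()].
#'
#' @param path Profile CSV path.
#' @return A subjects-by-positions CDV matrix (see [cdv_matrix()]).
#' @export
read_profile_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  check_header(df, c("subject_id", "position", "cdv_mm"), path)
  subjects <- unique(df$subject_id)
  n_points <- max(df$position)
  m <- matrix(NA_real_, length(subjects), n_points,
              dimnames = list(subjects, NULL))
  m[cbind(match(df$subject_id, subjects), df$position)] <- df$cdv_mm
  if (anyNA(m)) stop(sprintf("profile table '%s' has missing positions", path))
  m
}
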