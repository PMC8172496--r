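# CSV dialects
# contours:   subject_id,boundary,vertex_index,x_mm,y_mm
#             boundary in {upper, lower}; vertex_index 0-based contiguous
# covariates: subject_id,diagnosis,sex,age_years,education_years,tiv_ml,
#             illness_duration_years,cpz_mg_day  (empty cell = absent)

CONTOUR_HEADER <- c("subject_id", "boundary", "vertex_index", "x_mm", "y_mm")
COVARIATE_HEADER <- c("subject_id", "diagnosis", "sex", "age_years",
                      "education_years", "tiv_ml", "illness_duration_years",
                      "cpz_mg_day")

#' Diagnostic group labels
#'
#' The diagnostic groups handled by the package: obsessive-compulsive
#' disorder, schizophrenia, bipolar disorder, major depressive disorder and
#' healthy controls.
#' @export
DIAGNOSES <- c("OCD", "SZ", "BD", "MDD", "HC")

check_header <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("format error in '%s': missing required column(s) %s",
                 path, paste(sQuote(missing), collapse = ", ")), call. = FALSE)
}

#' Read traced callosal boundary contours from CSV
#'
#' Reads a contour CSV (header `subject_id,boundary,vertex_index,x_mm,y_mm`)
#' into a list of [contour_pair()] objects. Rows may appear in any order:
#' vertices are sorted by `vertex_index` within each (subject, boundary).
#'
#' @param path Path to the contour CSV file.
#' @param endpoint_tol Endpoint coincidence tolerance in mm passed to
#'   [validate_contour_pair()]; violations are raised as warnings.
#' @return A named list of `cc_contour_pair` objects, one per subject, in
#'   order of first appearance in the file.
#' @export
read_contours <- function(path, endpoint_tol = 2.0) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  check_header(df, CONTOUR_HEADER, path)
  bad <- setdiff(unique(df$boundary), c("upper", "lower"))
  if (length(bad))
    stop(sprintf("format error in '%s': unknown boundary label(s) %s",
                 path, paste(sQuote(bad), collapse = ", ")))
  key <- paste(df$subject_id, df$boundary, df$vertex_index)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop(sprintf("duplicate (subject, boundary, vertex_index) row in '%s': %s",
                 path, d))
  }
  subjects <- unique(df$subject_id)
  pairs <- lapply(subjects, function(s) {
    sub <- df[df$subject_id == s, , drop = FALSE]
    sides <- lapply(c("upper", "lower"), function(b) {
      rows <- sub[sub$boundary == b, , drop = FALSE]
      if (!nrow(rows))
        stop(sprintf("incomplete subject '%s': missing %s boundary", s, b))
      rows <- rows[order(rows$vertex_index), , drop = FALSE]
      if (!identical(rows$vertex_index, seq_len(nrow(rows)) - 1L))
        stop(sprintf(
          "subject '%s' %s boundary: vertex_index not 0-based contiguous", s, b))
      cbind(rows$x_mm, rows$y_mm)
    })
    p <- contour_pair(s, sides[[1L]], sides[[2L]])
    rep_ <- validate_contour_pair(p, endpoint_tol)
    for (w in rep_$warnings) warning(sprintf("subject '%s': %s", s, w),
                                     call. = FALSE)
    p
  })
  names(pairs) <- subjects
  pairs
}

#' Write contour pairs to CSV
#'
#' Writes contours in the dialect read by [read_contours()]. Coordinates are
#' serialized with full double precision (`%.17g`) so that a write/read round
#' trip is coordinate-exact.
#'
#' @param pairs A list of [contour_pair()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(pairs, path) {
  stopifnot(all(vapply(pairs, inherits, logical(1), "cc_contour_pair")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(CONTOUR_HEADER, collapse = ","), con)
  for (p in pairs) {
    for (b in c("upper", "lower")) {
      m <- p[[b]]
      writeLines(sprintf("%s,%s,%d,%.17g,%.17g",
                         p$subject_id, b, seq_len(nrow(m)) - 1L,
                         m[, 1L], m[, 2L]), con)
    }
  }
  invisible(path)
}

#' Read the subject covariate table
#'
#' Reads the covariate CSV (header
#' `subject_id,diagnosis,sex,age_years,education_years,tiv_ml,illness_duration_years,cpz_mg_day`)
#' into a data frame of subject records. Empty clinical cells (illness
#' duration, chlorpromazine-equivalent dose) map to `NA` meaning "absent";
#' they must be absent for healthy controls, for whom these quantities are
#' undefined rather than zero.
#'
#' @param path Path to the covariate CSV file.
#' @return A data frame with one row per subject; `diagnosis` is a factor
#'   with levels `r paste(DIAGNOSES, collapse = ", ")`.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  check_header(df, COVARIATE_HEADER, path)
  validate_covariates(df, path)
}

validate_covariates <- function(df, origin = "covariate table") {
  bad <- setdiff(unique(df$diagnosis), DIAGNOSES)
  if (length(bad))
    stop(sprintf("unknown diagnosis label(s) in %s: %s", origin,
                 paste(sQuote(bad), collapse = ", ")))
  bad_sex <- setdiff(unique(df$sex), c("M", "F"))
  if (length(bad_sex))
    stop(sprintf("unknown sex label(s) in %s: %s", origin,
                 paste(sQuote(bad_sex), collapse = ", ")))
  if (anyDuplicated(df$subject_id))
    stop(sprintf("duplicate subject_id in %s: %s", origin,
                 df$subject_id[duplicated(df$subject_id)][1L]))
  num <- c("age_years", "education_years", "tiv_ml",
           "illness_duration_years", "cpz_mg_day")
  for (v in num) df[[v]] <- as.numeric(df[[v]])
  hc <- df$diagnosis == "HC"
  offending <- hc & (!is.na(df$illness_duration_years) | !is.na(df$cpz_mg_day))
  if (any(offending))
    stop(sprintf(
      "consistency error in %s: HC subject '%s' has clinical covariates; they must be absent",
      origin, df$subject_id[offending][1L]))
  chk <- function(cond, msg) {
    if (any(cond, na.rm = TRUE))
      stop(sprintf("invalid value in %s for subject '%s': %s", origin,
                   df$subject_id[which(cond)[1L]], msg))
  }
  chk(df$age_years < 0, "age must be >= 0")
  chk(df$education_years < 0, "education must be >= 0")
  chk(df$tiv_ml <= 0, "TIV must be > 0")
  chk(df$illness_duration_years < 0, "illness duration must be >= 0")
  chk(df$cpz_mg_day < 0, "chlorpromazine equivalent must be >= 0")
  df$diagnosis <- factor(df$diagnosis, levels = DIAGNOSES)
  df
}

#' Write the subject covariate table
#'
#' Inverse of [read_covariates()]; `NA` clinical values are written as empty
#' cells.
#'
#' @param records Data frame of subject records (see [read_covariates()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(records, path) {
  out <- records[, COVARIATE_HEADER]
  out$diagnosis <- as.character(out$diagnosis)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
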