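#' Default post-hoc contrast set
#'
#' Each patient group against HC, then all patient-group pairs: 10 contrasts
#' for the five standard groups.
#'
#' @param groups Group labels (default the five diagnoses).
#' @return List of length-2 character vectors.
#' @export
default_contrasts <- function(groups = DIAGNOSES) {
  patients <- setdiff(groups, "HC")
  out <- list()
  if ("HC" %in% groups)
    out <- lapply(patients, function(g) c(g, "HC"))
  if (length(patients) >= 2) {
    cmb <- utils::combn(patients, 2, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Run the full morphometry study
#'
#' Orchestrates one reproducible analysis run: simulate or ingest contours
#' and covariates, compute thickness profiles, fit the omnibus
#' mass-univariate ANCOVA, fit post-hoc pairwise contrasts (by default only
#' if the omnibus family has at least one FDR-significant position, matching
#' the study protocol), compute adjusted group means, and optionally write
#' all result tables plus a run manifest.
#'
#' @param contours List of [contour_pair()] objects, or a path to a contour
#'   CSV. Mutually exclusive with `sim_config`.
#' @param covariates Subject records data frame, or a path to a covariate
#'   CSV. Required with `contours`.
#' @param sim_config A [simulation_config()]; when given, the cohort is
#'   simulated (with `effects`) instead of read.
#' @param effects Effect map for simulation (see [preset_effectmaps()]).
#' @param config An [analysis_config()].
#' @param contrasts List of group pairs (default [default_contrasts()] over
#'   the observed groups).
#' @param gate_posthoc Fit post-hoc contrasts only when the omnibus shows at
#'   least one FDR-significant position (default `TRUE`).
#' @param midline_mode Passed to [compute_profile()].
#' @param endpoint_tol Endpoint-coincidence warning tolerance (mm) used when
#'   reading contours from file; see [read_contours()].
#' @param out_dir Optional output directory; when given, writes per-contrast
#'   and combined pointwise TSVs, the adjusted-means TSV, profile CSV and a
#'   JSON manifest.
#' @return List of class `cc_study_run`: `profiles`, `omnibus`, `posthoc`
#'   (named list of data frames), `adjusted_means`, `results` (combined data
#'   frame), `manifest`.
#' @export
run_study <- function(contours = NULL, covariates = NULL, sim_config = NULL,
                      effects = NULL, config = analysis_config(),
                      contrasts = NULL, gate_posthoc = TRUE,
                      midline_mode = "pointwise_average", out_dir = NULL,
                      endpoint_tol = 2.0) {
  if (is.null(sim_config) == is.null(contours))
    stop("provide exactly one of 'contours' (+ 'covariates') or 'sim_config'")
  if (!is.null(sim_config)) {
    cohort <- simulate_cohort(sim_config, effects)
    contours <- cohort$contours
    records <- cohort$records
    seed <- sim_config$seed
  } else {
    if (is.character(contours))
      contours <- read_contours(contours, endpoint_tol = endpoint_tol)
    if (is.null(covariates)) stop("'covariates' required with 'contours'")
    records <- if (is.character(covariates)) read_covariates(covariates)
               else validate_covariates(covariates)
    seed <- NA_integer_
  }
  stage <- "profiles"
  result <- tryCatch({
    profiles <- compute_profiles(contours, config$n_points, midline_mode)
    Y <- cdv_matrix(profiles)

    stage <- "design"
    design <- build_design(records, config)

    stage <- "omnibus"
    omnibus <- fit_pointwise_omnibus(Y, design, config)
    adj_means <- adjusted_group_means(Y, design, config)

    stage <- "posthoc"
    gate_open <- any(omnibus$significant)
    posthoc <- list()
    if (!gate_posthoc || gate_open) {
      if (is.null(contrasts))
        contrasts <- default_contrasts(levels(design$group))
      for (ct in contrasts) {
        res <- fit_pointwise_posthoc(Y, records, ct[1L], ct[2L], config)
        posthoc[[res$comparison[1L]]] <- res
      }
    }

    combined <- if (length(posthoc)) {
      rbind(omnibus, do.call(rbind, c(posthoc, list(make.row.names = FALSE))))
    } else omnibus
    manifest <- list(
      package_version = as.character(utils::packageVersion("ccmorph")),
      seed = seed,
      n_points = config$n_points, q = config$q,
      fdr_method = config$fdr_method, covariates = config$covariates,
      midline_mode = midline_mode,
      n_subjects = length(profiles), n_design_rows = nrow(design$X),
      posthoc_gate = gate_posthoc, posthoc_gate_open = gate_open,
      n_posthoc_contrasts = length(posthoc),
      counts = list(contours_in = length(contours),
                    profiles_out = length(profiles),
                    results_rows = nrow(combined)))
    structure(list(profiles = profiles, design = design, omnibus = omnibus,
                   posthoc = posthoc, adjusted_means = adj_means,
                   results = combined, manifest = manifest),
              class = "cc_study_run")
  }, error = function(e) {
    stop(sprintf("study run failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!is.null(out_dir)) write_study_run(result, out_dir)
  result
}

#' @export
print.cc_study_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<study run> %d subjects, %d positions\n", m$n_subjects,
              m$n_points))
  cat(sprintf("  omnibus: %d/%d FDR-significant positions (q = %g)\n",
              sum(x$omnibus$significant), nrow(x$omnibus), m$q))
  cat(sprintf("  post-hoc: %d contrasts (gate %s)\n", m$n_posthoc_contrasts,
              if (m$posthoc_gate_open) "open" else "closed"))
  invisible(x)
}

write_study_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  wt(run$omnibus, "pointwise_omnibus.tsv")
  for (nm in names(run$posthoc))
    wt(run$posthoc[[nm]], sprintf("pointwise_%s.tsv", nm))
  wt(run$results, "pointwise_all.tsv")
  wt(run$adjusted_means, "adjusted_means.tsv")
  write_profiles(run$profiles, file.path(out_dir, "profiles.csv"))
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Map pointwise results back onto the callosal outlines
#'
#' Joins one comparison's pointwise results to the resampled boundary
#' coordinates, mirroring each position's statistic onto both the upper and
#' lower outline (the single CDV per position summarizes both surfaces), as
#' used for significance maps drawn on the callosal outline.
#'
#' @param results Pointwise result data frame for one comparison.
#' @param upper,lower Resampled boundaries (e.g. from a representative
#'   subject's `cc_thickness_profile`), with as many points as `results`
#'   has positions.
#' @return Data frame with one row per (position, boundary): `comparison`,
#'   `position`, `boundary`, `x_mm`, `y_mm`, `p_fdr`, `significant`.
#' @export
export_pointwise_map <- function(results, upper, lower) {
  stopifnot(length(unique(results$comparison)) == 1L)
  upper <- as_polyline(upper); lower <- as_polyline(lower)
  if (nrow(upper) != nrow(results) || nrow(lower) != nrow(results))
    stop(sprintf("boundary point count (%d/%d) does not match %d positions",
                 nrow(upper), nrow(lower), nrow(results)))
  one <- function(b, m)
    data.frame(comparison = results$comparison, position = results$position,
               boundary = b, x_mm = m[, 1L], y_mm = m[, 2L],
               p_fdr = results$p_fdr, significant = results$significant)
  out <- rbind(one("upper", upper), one("lower", lower))
  rownames(out) <- NULL
  out
}
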