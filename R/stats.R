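#' Analysis configuration
#'
#' Collects the tunable parameters of the mass-univariate analysis.
#'
#' @param n_points Number of callosal positions (default 100).
#' @param q Maximum allowable false discovery rate (default 0.05).
#' @param covariates Ordered subset of `age`, `education`, `tiv`,
#'   `illness_duration`, `cpz` entered as model covariates. Sex is never
#'   included: the design is fully sex-matched and sex is strongly
#'   correlated with TIV.
#' @param alpha Significance level used by power computations (default 0.05).
#' @param fdr_method `"BH"` (Benjamini-Hochberg step-up, default) or `"BY"`
#'   (Benjamini-Yekutieli, valid under arbitrary dependence).
#' @return A list of class `cc_analysis_config`.
#' @export
analysis_config <- function(n_points = 100L, q = 0.05,
                            covariates = c("age", "education", "tiv",
                                           "illness_duration", "cpz"),
                            alpha = 0.05, fdr_method = c("BH", "BY")) {
  stopifnot(q > 0, q < 1, alpha > 0, alpha < 1, n_points >= 2)
  if (length(covariates)) covariates <- match.arg(covariates, several.ok = TRUE)
  structure(list(n_points = as.integer(n_points), q = q,
                 covariates = covariates, alpha = alpha,
                 fdr_method = match.arg(fdr_method)),
            class = "cc_analysis_config")
}

CLINICAL_COVARIATES <- c("illness_duration", "cpz")
COVARIATE_COLUMNS <- c(age = "age_years", education = "education_years",
                       tiv = "tiv_ml", illness_duration = "illness_duration_years",
                       cpz = "cpz_mg_day")

#' Center a clinical covariate within patient groups
#'
#' Illness duration and medication dose are defined only for patients; to
#' enter them in models that include healthy controls they are standardized
#' by centering each patient's value on the patient's own group mean, with
#' the group mean itself mapped to 0 — the value assigned to every control.
#' This retains within-group inter-individual variability while removing the
#' artefactual patient-vs-control offset. A patient with an absent value is
#' imputed at the own-group mean, i.e. centered 0.
#'
#' @param values Numeric vector, `NA` = absent.
#' @param groups Group label per subject.
#' @param control_label Label of the control group (its subjects map to 0
#'   unconditionally). Default `"HC"`.
#' @return Numeric vector of centered values; per-group means of the present
#'   values are 0 to numerical precision.
#' @export
center_within_group <- function(values, groups, control_label = "HC") {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  out <- numeric(length(values))
  for (g in setdiff(unique(groups), control_label)) {
    idx <- which(groups == g)
    present <- idx[!is.na(values[idx])]
    if (!length(present))
      stop(sprintf("degenerate group '%s': all values absent, cannot center", g))
    out[present] <- values[present] - mean(values[present])
    # absent values sit at the group mean, i.e. centered 0 (already 0)
  }
  out
}

#' Build the ANCOVA design matrix
#'
#' Constructs the mass-univariate model design: an intercept, reference-coded
#' diagnosis indicators (HC is the reference when present, otherwise the
#' alphabetically first group), and the configured covariates. Clinical
#' covariates (illness duration, chlorpromazine equivalent) are centered
#' within patient groups via [center_within_group()] whenever HC is among
#' the modelled groups; in patient-only contrasts they enter as raw values
#' (absent values imputed at the own-group mean).
#'
#' @param records Subject records (see [read_covariates()]).
#' @param config An [analysis_config()].
#' @param contrast_groups Optional character vector restricting the design to
#'   a subset of diagnoses (e.g. `c("OCD", "HC")` for a post-hoc contrast).
#' @param center Override the clinical-covariate centering rule: `NULL`
#'   (default) centers iff HC is among the groups.
#' @return A list of class `cc_design`: `X` (model matrix), `group`
#'   (diagnosis factor), `group_cols` (column indices of the diagnosis
#'   contrasts), `covariate_cols`, `subject_id`, `centered` flag.
#' @export
build_design <- function(records, config = analysis_config(),
                         contrast_groups = NULL, center = NULL) {
  if (!is.null(contrast_groups)) {
    unknown <- setdiff(contrast_groups, as.character(records$diagnosis))
    if (length(unknown))
      stop(sprintf("contrast group(s) not present in records: %s",
                   paste(unknown, collapse = ", ")))
    records <- records[records$diagnosis %in% contrast_groups, , drop = FALSE]
  }
  groups <- droplevels(factor(records$diagnosis))
  if (nlevels(groups) < 2L) stop("design needs at least two diagnostic groups")
  ref <- if ("HC" %in% levels(groups)) "HC" else sort(levels(groups))[1L]
  groups <- stats::relevel(groups, ref = ref)
  if (is.null(center)) center <- "HC" %in% levels(groups)
  if ("HC" %in% levels(groups) && !center)
    stop("clinical covariates must be centered when HC is among the groups ",
         "(controls carry no raw clinical values)")

  n <- nrow(records)
  X <- stats::model.matrix(~groups)
  colnames(X) <- c("(Intercept)", paste0("diag", levels(groups)[-1L]))
  group_cols <- 2L:nlevels(groups)

  for (cv in config$covariates) {
    col <- COVARIATE_COLUMNS[[cv]]
    v <- records[[col]]
    if (cv %in% CLINICAL_COVARIATES) {
      if (center) {
        v <- center_within_group(v, groups, control_label = "HC")
      } else {
        # raw values; absent patients imputed at own-group mean
        for (g in levels(groups)) {
          idx <- which(groups == g)
          if (all(is.na(v[idx])))
            stop(sprintf("degenerate group '%s': no %s values", g, cv))
          v[idx][is.na(v[idx])] <- mean(v[idx], na.rm = TRUE)
        }
      }
    } else if (anyNA(v)) {
      stop(sprintf("missing values in covariate '%s'", cv))
    }
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  if (nrow(X) < ncol(X) + 1L)
    stop("fewer subjects than model parameters + 1; design under-determined")
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    dep <- colnames(X)[qr_$pivot[(qr_$rank + 1L):ncol(X)]]
    stop(sprintf("rank-deficient design: collinear column(s) %s",
                 paste(sQuote(dep), collapse = ", ")))
  }
  structure(list(X = X, group = groups, group_cols = group_cols,
                 covariate_cols = setdiff(seq_len(ncol(X)),
                                          c(1L, group_cols)),
                 subject_id = records$subject_id, centered = center),
            class = "cc_design")
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment over one family of p-values: with the m p-values
#' sorted ascending, adjusted p at rank i is `min over j >= i of m p(j)/j`,
#' clipped at 1; hypotheses with adjusted p at or below `q` are rejected.
#' Input order is preserved in the output.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param q Maximum allowable FDR (default 0.05).
#' @param method `"BH"` (default) or `"BY"`.
#' @return List with `p_adjusted` and logical `reject`, both aligned to `p`.
#' @export
bh_fdr <- function(p, q = 0.05, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stopifnot(q > 0, q < 1)
  adj <- stats::p.adjust(p, method = method)
  list(p_adjusted = adj, reject = adj <= q)
}

# Extra-sum-of-squares F tests of the diagnosis contrasts at every position:
# one OLS fit per position (shared QR across positions), F = joint test of
# the group columns against the covariate-only reduced model.
fit_pointwise <- function(Y, design, config, comparison) {
  X <- design$X
  n <- nrow(X); p <- ncol(X)
  if (nrow(Y) != n) stop("profiles and design cover different subject counts")
  qr_full <- qr(X)
  rss_full <- colSums(qr.resid(qr_full, Y)^2)
  Xr <- X[, -design$group_cols, drop = FALSE]
  rss_red <- colSums(qr.resid(qr(Xr), Y)^2)
  df1 <- length(design$group_cols)
  df2 <- n - p
  Fstat <- ((rss_red - rss_full) / df1) / (rss_full / df2)
  p_raw <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  fdr <- bh_fdr(p_raw, config$q, config$fdr_method)
  data.frame(comparison = comparison, position = seq_along(Fstat),
             statistic = Fstat, df1 = df1, df2 = df2, p_raw = p_raw,
             p_fdr = fdr$p_adjusted, significant = fdr$reject,
             row.names = NULL)
}

align_cdv <- function(profiles, design) {
  Y <- cdv_matrix(profiles)
  missing <- setdiff(design$subject_id, rownames(Y))
  if (length(missing))
    stop(sprintf("no thickness profile for subject(s) %s",
                 paste(missing, collapse = ", ")))
  Y[design$subject_id, , drop = FALSE]
}

#' Mass-univariate omnibus ANCOVA across all diagnostic groups
#'
#' At each callosal position independently, fits ordinary least squares of
#' the CDV on the design and tests the joint nullity of the diagnosis
#' contrasts with an extra-sum-of-squares F test (df1 = number of groups -
#' 1, df2 = n - number of model columns). The family of all positions of
#' this comparison is FDR-adjusted together.
#'
#' @param profiles List of `cc_thickness_profile` objects or a CDV matrix
#'   (see [cdv_matrix()]).
#' @param design A [build_design()] result covering the same subjects.
#' @param config An [analysis_config()].
#' @return A data frame of pointwise results: `comparison`, `position`,
#'   `statistic` (F), `df1`, `df2`, `p_raw`, `p_fdr`, `significant`.
#' @export
fit_pointwise_omnibus <- function(profiles, design,
                                  config = analysis_config()) {
  fit_pointwise(align_cdv(profiles, design), design, config, "omnibus")
}

#' Pointwise post-hoc contrast between two diagnostic groups
#'
#' Restricts the model to two groups, keeping the same covariate set. When
#' HC is one of the groups the clinical covariates are centered within the
#' patient group; in patient-vs-patient contrasts they enter as raw values.
#' The F statistic has df1 = 1 (it is the square of the corresponding t);
#' FDR adjustment is applied within this contrast's own family of positions.
#'
#' @inheritParams fit_pointwise_omnibus
#' @param records Subject records for all subjects.
#' @param groupA,groupB The two diagnoses to contrast.
#' @return A pointwise result data frame (comparison label
#'   `"<groupA>_vs_<groupB>"`).
#' @export
fit_pointwise_posthoc <- function(profiles, records, groupA, groupB,
                                  config = analysis_config()) {
  if (identical(groupA, groupB)) stop("groupA and groupB must differ")
  design <- build_design(records, config, contrast_groups = c(groupA, groupB))
  fit_pointwise(align_cdv(profiles, design), design, config,
                paste0(groupA, "_vs_", groupB))
}

#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the one-way ANOVA F test from per-group means, standard
#' deviations and sizes, as used for demographic/clinical table comparisons:
#' the between-group mean square comes from the group means about the
#' size-weighted grand mean, the within-group mean square pools the group
#' variances.
#'
#' @param means,sds,ns Numeric vectors of per-group means, SDs and sizes.
#' @return List with `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
anova_from_summary <- function(means, sds, ns) {
  k <- length(means)
  stopifnot(length(sds) == k, length(ns) == k, k >= 2,
            all(ns >= 2), all(sds >= 0))
  N <- sum(ns)
  grand <- sum(ns * means) / N
  msb <- sum(ns * (means - grand)^2) / (k - 1)
  msw <- sum((ns - 1) * sds^2) / (N - k)
  if (msw == 0) {
    if (msb == 0) stop("undefined F: all SDs zero and all means equal")
    return(list(statistic = Inf, df1 = k - 1, df2 = N - k, p_value = 0))
  }
  Fstat <- msb / msw
  list(statistic = Fstat, df1 = k - 1, df2 = N - k,
       p_value = stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE))
}

#' Covariate-adjusted (least-squares) group means per position
#'
#' Model-predicted mean CDV per group and position with covariates fixed at
#' their sample means; centered clinical covariates are fixed at 0, their
#' defined reference level. With no covariates this reduces to the raw group
#' means.
#'
#' @inheritParams fit_pointwise_omnibus
#' @return Data frame with `group`, `position`, `adjusted_mean_cdv_mm`.
#' @export
adjusted_group_means <- function(profiles, design,
                                 config = analysis_config()) {
  Y <- align_cdv(profiles, design)
  X <- design$X
  B <- qr.coef(qr(X), Y)                       # p x n_points
  lv <- levels(design$group)
  X0 <- matrix(0, length(lv), ncol(X), dimnames = list(lv, colnames(X)))
  X0[, 1L] <- 1
  for (g in lv[-1L]) X0[g, paste0("diag", g)] <- 1
  if (length(design$covariate_cols))
    X0[, design$covariate_cols] <-
      rep(colMeans(X[, design$covariate_cols, drop = FALSE]),
          each = length(lv))
  pred <- X0 %*% B                              # groups x positions
  data.frame(group = rep(lv, times = ncol(pred)),
             position = rep(seq_len(ncol(pred)), each = length(lv)),
             adjusted_mean_cdv_mm = as.vector(pred), row.names = NULL)
}

#' Power of the k-group (AN)COVA omnibus F test
#'
#' Noncentral-F power for detecting a standardized effect size f (Cohen's f)
#' in a fixed-effects one-way analysis with optional covariates: with df1 =
#' k - 1, df2 = N - k - c and noncentrality lambda = f^2 N, power is the
#' probability that a noncentral F exceeds the central-F critical value at
#' level `alpha`.
#'
#' @param n_groups Number of groups k.
#' @param total_n Total sample size N.
#' @param effect_size_f Cohen's f (>= 0).
#' @param alpha Test size (default 0.05).
#' @param n_covariates Number of covariate columns c (default 0).
#' @return Power in `[0, 1]`; equals `alpha` exactly at f = 0.
#' @export
anova_power <- function(n_groups, total_n, effect_size_f, alpha = 0.05,
                        n_covariates = 0L) {
  stopifnot(n_groups >= 2, effect_size_f >= 0, alpha > 0, alpha < 1)
  df1 <- n_groups - 1
  df2 <- total_n - n_groups - n_covariates
  if (df2 < 1) stop("invalid degrees of freedom: total_n too small")
  if (effect_size_f == 0) return(alpha)  # null case: power equals test size
  fcrit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(fcrit, df1, df2, ncp = effect_size_f^2 * total_n,
            lower.tail = FALSE)
}
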