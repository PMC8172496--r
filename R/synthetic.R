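# Stylized midsagittal callosal geometry: a circular-arc centerline (constant
# curvature keeps the arc-length correspondence between the offset boundaries
# and the centerline tight) with upper/lower boundaries offset along the local
# normal by a position-dependent half-thickness. No claim of anatomical
# realism beyond gross proportions: chord ~72 mm, arch height ~22 mm, genu and
# splenium bulges, thinner body.

#' Baseline half-thickness template
#'
#' Smooth strictly positive half-thickness (CDV) profile over positions 1 to
#' `n_points`: a constant base plus Gaussian bulges in the anterior (genu)
#' and posterior (splenium) fifths and a Gaussian dip in the middle body.
#' All terms scale with `amplitude`, so doubling it doubles every value.
#'
#' @param n_points Number of positions (default 100).
#' @param params List of shape parameters (mm unless noted): `amplitude`
#'   (global multiplier, 1), `base` (2.8), `genu_amp` (1.6), `genu_center`
#'   (0.12, arc fraction), `genu_width` (0.09), `splenium_amp` (2.0),
#'   `splenium_center` (0.88), `splenium_width` (0.10), `body_dip` (0.9),
#'   `body_center` (0.5), `body_width` (0.16). Defaults give thickness
#'   (2 CDV) of roughly 9 mm at the genu/splenium and 4 mm in the body.
#' @return Numeric vector of `n_points` half-thickness values, mm.
#' @export
template_profile <- function(n_points = 100L, params = list()) {
  stopifnot(n_points >= 2)
  p <- utils::modifyList(list(
    amplitude = 1, base = 2.8,
    genu_amp = 1.6, genu_center = 0.12, genu_width = 0.09,
    splenium_amp = 2.0, splenium_center = 0.88, splenium_width = 0.10,
    body_dip = 0.9, body_center = 0.5, body_width = 0.16), params)
  t <- seq(0, 1, length.out = n_points)
  h <- p$amplitude * (p$base +
    p$genu_amp * exp(-((t - p$genu_center) / p$genu_width)^2) +
    p$splenium_amp * exp(-((t - p$splenium_center) / p$splenium_width)^2) -
    p$body_dip * exp(-((t - p$body_center) / p$body_width)^2))
  if (any(h <= 0))
    stop("template parameters yield non-positive half-thickness")
  h
}

# circular-arc centerline through chord `span` with apex height `height`;
# returns positions and outward unit normals at the requested arc fractions
arch_centerline <- function(frac, span = 72, height = 22) {
  R <- height / 2 + span^2 / (8 * height)
  th0 <- asin((span / 2) / R)
  ang <- pi / 2 + th0 - frac * 2 * th0       # anterior (x=0) to posterior
  list(xy = cbind(x_mm = span / 2 + R * cos(ang),
                  y_mm = height - R + R * sin(ang)),
       normal = cbind(cos(ang), sin(ang)))
}

#' Synthesize one subject's contour pair
#'
#' Offsets the arch centerline by `subject_scale * effect * template` along
#' the local outward normal on each side, evaluated at `n_vertices`
#' equidistant arc fractions, then perturbs every vertex with isotropic
#' Gaussian coordinate noise. If the noise produces a degenerate tracing
#' (zero-length segment, or a vertex pushed across the midline) the pair is
#' regenerated, with a warning, up to `max_retries` times.
#'
#' @param subject_id Subject identifier.
#' @param template Baseline half-thickness per position
#'   (see [template_profile()]).
#' @param effect Per-position multiplicative thickness factors (same length
#'   as `template`; 1 = no effect, 0.8 = 20% thinning).
#' @param subject_scale Subject-level multiplicative thickness factor.
#' @param point_noise_sd SD of the additive coordinate noise, mm.
#' @param span,height Arch dimensions, mm.
#' @param n_vertices Number of emitted vertices per boundary (default 200;
#'   denser than the analysis resolution so the traced polylines behave like
#'   manual outlines rather than pre-resampled curves).
#' @param max_retries Regeneration attempts under excessive noise.
#' @return A valid [contour_pair()].
#' @export
synth_contour_pair <- function(subject_id, template, effect = 1,
                               subject_scale = 1, point_noise_sd = 0,
                               span = 72, height = 22, n_vertices = 200L,
                               max_retries = 10L) {
  n <- length(template)
  effect <- rep_len(effect, n)
  stopifnot(all(effect > 0), subject_scale > 0, point_noise_sd >= 0)
  frac <- seq(0, 1, length.out = n_vertices)
  cl <- arch_centerline(frac, span, height)
  # baseline half-thickness varies smoothly: linear interpolation onto the
  # emitted vertex fractions; effect factors are per-position quantities and
  # are held constant over each position's arc-length cell (nearest-position
  # lookup) so an injected window covers exactly its stated positions
  h_base <- stats::approx(seq(0, 1, length.out = n), subject_scale * template,
                          xout = frac)$y
  eff_v <- effect[pmin(pmax(round(frac * (n - 1)) + 1L, 1L), n)]
  h <- h_base * eff_v
  for (attempt in seq_len(max_retries + 1L)) {
    noise_u <- matrix(stats::rnorm(2L * n_vertices, 0, point_noise_sd), ncol = 2L)
    noise_l <- matrix(stats::rnorm(2L * n_vertices, 0, point_noise_sd), ncol = 2L)
    up <- cl$xy + cl$normal * h + noise_u
    lo <- cl$xy - cl$normal * h + noise_l
    # signed offset along the local normal must stay positive on each side
    ok <- !length(polyline_problems(up)) && !length(polyline_problems(lo)) &&
      all(rowSums((up - cl$xy) * cl$normal) > 0) &&
      all(rowSums((lo - cl$xy) * cl$normal) < 0)
    if (ok)
      return(contour_pair(subject_id, up, lo))
    if (attempt <= max_retries)
      warning(sprintf(
        "subject '%s': degenerate noisy tracing, regenerating (attempt %d)",
        subject_id, attempt), call. = FALSE)
  }
  stop(sprintf("subject '%s': noise SD %.3g mm too large for the template",
               subject_id, point_noise_sd))
}

#' Simulation configuration
#'
#' Study-design parameters of the synthetic cohort generator. Defaults
#' emulate the target study design: five diagnostic groups of 30 subjects,
#' one-to-one age matching and exact sex matching (15 M / 15 F per group),
#' and covariate distributions matching the reported group summaries.
#'
#' @param n_per_group Subjects per group (default 30).
#' @param groups Group labels (default the five diagnoses).
#' @param n_points Positions in the thickness template (default 100).
#' @param template_params Passed to [template_profile()].
#' @param span,height Arch dimensions, mm.
#' @param subject_scale_sd SD of the residual log-normal subject-level
#'   thickness scale (default 0.03). The subject scale also carries a
#'   head-size component, `(TIV / 1450)^tiv_exponent`, so part of the
#'   inter-subject thickness variability is explained by the TIV covariate —
#'   mirroring the head-size dependence that motivates entering TIV in the
#'   ANCOVA. Total global thickness variability is ~5%.
#' @param tiv_exponent Exponent coupling the subject thickness scale to
#'   relative TIV (default 0.5).
#' @param point_noise_sd Coordinate tracing noise SD, mm (default 0.25,
#'   i.e. quarter-voxel jitter at 1 mm isotropic resolution).
#' @param age_mean,age_sd Age distribution, years (default 40.4 / 11,
#'   truncated to 18-65).
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   configuration. Per-subject substreams are derived from it so cohorts
#'   are reproducible under subsetting.
#' @return A list of class `cc_sim_config`.
#' @export
simulation_config <- function(n_per_group = 30L,
                              groups = c("OCD", "SZ", "BD", "MDD", "HC"),
                              n_points = 100L, template_params = list(),
                              span = 72, height = 22,
                              subject_scale_sd = 0.03, tiv_exponent = 0.5,
                              point_noise_sd = 0.25,
                              age_mean = 40.4, age_sd = 11, seed = 1L) {
  stopifnot(n_per_group >= 2, subject_scale_sd >= 0, point_noise_sd >= 0,
            all(groups %in% DIAGNOSES))
  structure(list(n_per_group = as.integer(n_per_group), groups = groups,
                 n_points = as.integer(n_points),
                 template_params = template_params,
                 span = span, height = height,
                 subject_scale_sd = subject_scale_sd,
                 tiv_exponent = tiv_exponent,
                 point_noise_sd = point_noise_sd,
                 age_mean = age_mean, age_sd = age_sd,
                 seed = as.integer(seed)),
            class = "cc_sim_config")
}

# group-wise covariate generators; means/SDs follow the reported group
# summaries (education, illness duration, chlorpromazine equivalents)
COVARIATE_PRIORS <- list(
  education = list(OCD = c(13.03, 3.5), SZ = c(12.43, 3.4), BD = c(14.7, 2.7),
                   MDD = c(13.17, 3.9), HC = c(15.97, 3.3)),
  duration = list(OCD = c(19.21, 12.3), SZ = c(24.1, 9), BD = c(12, 10),
                  MDD = c(9.57, 9.7)),
  cpz = list(OCD = c(61.1, 105.7), SZ = c(118.54, 209.4), BD = c(80.9, 116.4),
             MDD = c(23.21, 53.5)))

rnorm_trunc <- function(n, mean, sd, lower) {
  pmax(stats::rnorm(n, mean, sd), lower)
}

#' Named effect-map presets
#'
#' Effect maps are per-group vectors of multiplicative thickness factors
#' over positions (1 = unaffected). Presets:
#' \describe{
#'   \item{`null`}{all groups 1 everywhere.}
#'   \item{`ocd_global`}{OCD thinned at every position except a middle-body
#'     exemption window.}
#'   \item{`sz_focal`}{SZ thinned only in the rostrum and isthmus windows.}
#'   \item{`paper_like`}{`ocd_global` and `sz_focal` combined; BD and MDD
#'     null — the qualitative pattern of widespread obsessive-compulsive
#'     thinning, focal schizophrenia thinning, and unaffected mood
#'     disorders.}
#' }
#'
#' @param n_points Number of positions (default 100).
#' @param groups Group labels.
#' @param thinning Multiplicative factor inside affected windows
#'   (default 0.8, i.e. 20% thinning).
#' @param rostrum,isthmus,midbody Position windows (defaults 1-8, 70-80,
#'   40-60 at 100 positions); the window boundaries are design choices, the
#'   source protocol defines no numeric ranges.
#' @return Named list of effect maps; each is a groups-by-positions matrix.
#' @export
preset_effectmaps <- function(n_points = 100L,
                              groups = c("OCD", "SZ", "BD", "MDD", "HC"),
                              thinning = 0.8,
                              rostrum = 1:8, isthmus = 70:80,
                              midbody = 40:60) {
  stopifnot(thinning > 0)
  base <- matrix(1, length(groups), n_points,
                 dimnames = list(groups, NULL))
  ocd <- base
  if ("OCD" %in% groups) ocd["OCD", -midbody] <- thinning
  sz <- base
  if ("SZ" %in% groups) sz["SZ", c(rostrum, isthmus)] <- thinning
  paper_like <- base
  if ("OCD" %in% groups) paper_like["OCD", ] <- ocd["OCD", ]
  if ("SZ" %in% groups) paper_like["SZ", ] <- sz["SZ", ]
  list(null = base, ocd_global = ocd, sz_focal = sz, paper_like = paper_like)
}

# Per-subject substream seeds are drawn from a single master stream seeded by
# the global seed (arithmetic seed derivations leave detectable correlations
# in the first draws of nearby streams). The table depends only on the
# configuration, so cohorts are reproducible under subsetting.
substream_seeds <- function(seed, n) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(2147483646L, n)
}

#' Simulate a synthetic study cohort
#'
#' Generates contour pairs and subject records for `n_per_group` subjects in
#' each group. Ages are drawn once per within-group index and shared across
#' groups (emulating one-to-one age matching); sex alternates M/F within
#' each group (15/15 at n = 30); education, TIV, illness duration and
#' chlorpromazine equivalents are drawn from group-specific truncated
#' normals; HC clinical covariates are absent. Each subject's contour pair
#' is generated from a per-subject substream of the global seed.
#'
#' @param config A [simulation_config()].
#' @param effects An effect map (groups-by-positions matrix, see
#'   [preset_effectmaps()]); default `null`.
#' @return List with `contours` (list of [contour_pair()]) and `records`
#'   (subject covariate data frame).
#' @export
simulate_cohort <- function(config = simulation_config(), effects = NULL) {
  stopifnot(inherits(config, "cc_sim_config"))
  if (is.null(effects))
    effects <- preset_effectmaps(config$n_points, config$groups)$null
  stopifnot(is.matrix(effects), all(config$groups %in% rownames(effects)),
            ncol(effects) == config$n_points, all(effects > 0))
  if ("HC" %in% config$groups && any(effects["HC", ] != 1))
    stop("HC effect factors must all be 1")
  template <- template_profile(config$n_points, config$template_params)
  n <- config$n_per_group
  G <- length(config$groups)
  seeds <- substream_seeds(config$seed, 1L + G + G * n)

  set.seed(seeds[1L])
  ages <- round(pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd),
                          18), 65), 1)

  records <- list(); contours <- list()
  idx <- 0L
  for (g in config$groups) {
    set.seed(seeds[1L + match(g, config$groups)])
    edu <- rnorm_trunc(n, COVARIATE_PRIORS$education[[g]][1],
                       COVARIATE_PRIORS$education[[g]][2], 5)
    tiv <- rnorm_trunc(n, 1450, 130, 900)
    if (g == "HC") {
      dur <- rep(NA_real_, n); cpz <- rep(NA_real_, n)
    } else {
      dur <- rnorm_trunc(n, COVARIATE_PRIORS$duration[[g]][1],
                         COVARIATE_PRIORS$duration[[g]][2], 0)
      cpz <- rnorm_trunc(n, COVARIATE_PRIORS$cpz[[g]][1],
                         COVARIATE_PRIORS$cpz[[g]][2], 0)
    }
    for (j in seq_len(n)) {
      idx <- idx + 1L
      sid <- sprintf("%s%03d", tolower(g), j)
      set.seed(seeds[1L + G + idx])
      scale <- (tiv[j] / 1450)^config$tiv_exponent *
        exp(stats::rnorm(1, 0, config$subject_scale_sd))
      contours[[sid]] <- synth_contour_pair(
        sid, template, effects[g, ], subject_scale = scale,
        point_noise_sd = config$point_noise_sd,
        span = config$span, height = config$height)
      records[[sid]] <- data.frame(
        subject_id = sid, diagnosis = g,
        sex = if (j %% 2L == 1L) "M" else "F",
        age_years = ages[j],
        education_years = round(edu[j], 1), tiv_ml = round(tiv[j], 1),
        illness_duration_years = round(dur[j], 1),
        cpz_mg_day = round(cpz[j], 1))
    }
  }
  records <- do.call(rbind, c(records, list(make.row.names = FALSE)))
  records$diagnosis <- factor(records$diagnosis, levels = DIAGNOSES)
  list(contours = contours, records = records)
}
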