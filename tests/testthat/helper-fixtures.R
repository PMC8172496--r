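# Shared fixtures built in code.

quarter_circle <- function(n = 10001, r = 1) {
  th <- seq(0, pi / 2, length.out = n)
  cbind(r * cos(th), r * sin(th))
}

# a wavy open pair of boundaries, reproducible given seed
random_smooth_pair <- function(seed, n_src = 400) {
  set.seed(seed)
  x <- seq(0, 60, length.out = n_src)
  base <- 5 * sin(x / 12) + cumsum(rnorm(n_src, 0, 0.02))
  half <- 2 + 0.8 * sin(x / 9 + runif(1, 0, pi))
  contour_pair(paste0("rnd", seed),
               cbind(x, base + half),
               cbind(x, base - half))
}

# smooth noise-free curved pair: concentric circular arcs
smooth_arc_pair <- function(r_upper = 30, r_lower = 26, n_src = 2000) {
  th <- seq(pi * 0.75, pi * 0.25, length.out = n_src)
  contour_pair("arc",
               cbind(r_upper * cos(th), r_upper * sin(th) - 10),
               cbind(r_lower * cos(th), r_lower * sin(th) - 10))
}

# small covariate table: n per group, deterministic values
toy_records <- function(groups = c("OCD", "SZ", "BD", "MDD", "HC"), n = 6) {
  set.seed(20260930 + n + length(groups))
  rows <- lapply(groups, function(g) {
    hc <- g == "HC"
    j <- seq_len(n)
    data.frame(
      subject_id = sprintf("%s%02d", tolower(g), j),
      diagnosis = g,
      sex = rep(c("M", "F"), length.out = n),
      age_years = round(runif(n, 20, 60), 1),
      education_years = sample(8:18, n, replace = TRUE),
      tiv_ml = round(runif(n, 1250, 1650), 1),
      illness_duration_years = if (hc) NA_real_ else round(runif(n, 1, 25), 1),
      cpz_mg_day = if (hc) NA_real_ else round(runif(n, 0, 300), 1))
  })
  out <- do.call(rbind, rows)
  out$diagnosis <- factor(out$diagnosis, levels = DIAGNOSES)
  out
}

two_group_effectmap <- function(window, factor = 0.8, n_points = 100) {
  eff <- matrix(1, 2, n_points, dimnames = list(c("OCD", "HC"), NULL))
  eff["OCD", window] <- factor
  eff
}
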