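# Synthetic cohorts with planted, score-correlated connectome structure.
#
# The real datasets behind this kind of analysis are observational; the
# generator states the structure the downstream model assumes: a bimodal
# score distribution (healthy controls near the floor of the scale, patients
# high), and a small planted edge set whose coupling weights move linearly
# with the standardized score on top of i.i.d. Gaussian edge noise. Defaults
# mirror the reference cohort: HC scores 1.6 +/- 0.75, MDD 22 +/- 2.7 on
# BDI; 33 positively and 5 negatively score-correlated edges out of 2278.

#' Generate a synthetic two-group cohort
#'
#' Draws healthy-control (HC) and depressed (MDD) raw scores from group
#' normals, truncates to the scale's range and rounds to integers
#' (psychometric scores are integer-valued). Age and gender are drawn from
#' configurable demographic distributions.
#'
#' @param n_hc,n_mdd Non-negative group sizes.
#' @param scale `"BDI"` (default) or `"HDRS"`. Group means/SDs are stated in
#'   BDI units and rescaled by `range/63` for other scales.
#' @param hc_mean,hc_sd,mdd_mean,mdd_sd Group score moments in BDI units
#'   (defaults 1.6/0.75 and 22/2.7).
#' @param age_mean,age_sd Age distribution in years (default 19 +/- 0.6).
#' @param gender_p Probability of gender code 1 (default 0.4).
#' @param seed Optional integer; fixes the random stream.
#' @return `data.frame` with columns `subject_id`, `score`, `scale`,
#'   `group`, `age`, `gender`.
#' @export
#' @examples
#' cohort <- gen_cohort(76, 45, seed = 1)
#' tapply(cohort$score, cohort$group, mean)
gen_cohort <- function(n_hc, n_mdd, scale = "BDI",
                       hc_mean = 1.6, hc_sd = 0.75,
                       mdd_mean = 22, mdd_sd = 2.7,
                       age_mean = 19, age_sd = 0.6,
                       gender_p = 0.4, seed = NULL) {
  if (!is.numeric(n_hc) || !is.numeric(n_mdd) || n_hc < 0 || n_mdd < 0) {
    stop("n_hc and n_mdd must be non-negative counts")
  }
  n_hc <- as.integer(n_hc); n_mdd <- as.integer(n_mdd)
  rng <- scale_ranges()
  if (!scale %in% names(rng)) stop("unknown scale '", scale, "'")
  range_max <- rng[[scale]]
  f <- range_max / rng[["BDI"]]   # group moments are stated in BDI units
  n <- n_hc + n_mdd
  draw <- function() {
    group <- rep(c("HC", "MDD"), c(n_hc, n_mdd))
    mu <- ifelse(group == "HC", hc_mean, mdd_mean) * f
    sg <- ifelse(group == "HC", hc_sd, mdd_sd) * f
    score <- round(pmin(pmax(stats::rnorm(n, mu, sg), 0), range_max))
    data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      score = score,
      scale = rep(scale, n),
      group = group,
      age = round(stats::rnorm(n, age_mean, age_sd), 1),
      gender = stats::rbinom(n, 1L, gender_p),
      stringsAsFactors = FALSE
    )
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (n == 0L) out[0L, ] else out
}

#' Planted linear edge-score model
#'
#' Defines which connectome edges carry score signal and how strongly.
#' Edge locations are drawn uniformly without replacement from the
#' upper-triangle edge indices (counts are stated by the model, locations
#' are not).
#'
#' @param n_regions Number of regions (default 68, i.e. 2278 edges).
#' @param n_pos,n_neg Planted positively / negatively score-correlated edge
#'   counts (defaults 33 and 5).
#' @param effect_size Slope of edge weight per unit z-score (default 0.1).
#' @param noise_sd SD of i.i.d. Gaussian edge noise (default 0.05).
#' @param base Baseline coupling, a constant in `[0, 1]` (default 0.3) or a
#'   full symmetric `n_regions` x `n_regions` matrix.
#' @param seed Optional integer; fixes edge placement.
#' @return Object of class `planted_model` with fields `pos_edges`,
#'   `neg_edges` (edge indices), `effect_size`, `noise_sd`, `base_edges`.
#' @export
planted_model <- function(n_regions = 68, n_pos = 33, n_neg = 5,
                          effect_size = 0.1, noise_sd = 0.05,
                          base = 0.3, seed = NULL) {
  stopifnot(n_regions >= 2, n_pos >= 0, n_neg >= 0, noise_sd > 0)
  m <- n_edges(n_regions)
  if (n_pos + n_neg > m) stop("more planted edges than edges available")
  pick <- function() sample.int(m, n_pos + n_neg)
  sel <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
  base_edges <- if (is.matrix(base)) vectorize_connectome(base)
                else rep(as.numeric(base), m)
  if (any(base_edges < 0 | base_edges > 1)) stop("base couplings outside [0,1]")
  structure(list(
    n_regions = as.integer(n_regions),
    pos_edges = sort(sel[seq_len(n_pos)]),
    neg_edges = sort(sel[n_pos + seq_len(n_neg)]),
    effect_size = as.numeric(effect_size),
    noise_sd = as.numeric(noise_sd),
    base_edges = base_edges
  ), class = "planted_model")
}

#' Per-edge signal sign of a planted model
#' @param model A [planted_model()].
#' @return Vector over edges: +1 on positive, -1 on negative, 0 elsewhere.
#' @export
planted_signs <- function(model) {
  stopifnot(inherits(model, "planted_model"))
  s <- numeric(length(model$base_edges))
  s[model$pos_edges] <- 1
  s[model$neg_edges] <- -1
  s
}

#' Generate connectomes carrying planted score signal
#'
#' For each subject, edge weight = base + sign * effect_size * z + noise,
#' where z is the subject's score standardized against the cohort sample
#' moments, sign is +1/-1/0 from the planted model, and noise is
#' i.i.d. Gaussian on every edge. Results are clipped to `[0, 1]` and
#' returned as symmetric zero-diagonal matrices.
#'
#' @param cohort Cohort `data.frame` from [gen_cohort()] (non-empty).
#' @param model A [planted_model()].
#' @param seed Optional integer; fixes the noise stream.
#' @return List of `cpm_connectome` matrices, one per subject, each with a
#'   `subject_id` attribute; names are subject ids.
#' @export
gen_connectomes <- function(cohort, model, seed = NULL) {
  stopifnot(inherits(model, "planted_model"))
  if (!is.data.frame(cohort) || nrow(cohort) == 0L) {
    stop("cohort must be a non-empty data.frame")
  }
  n <- nrow(cohort)
  s <- stats::sd(cohort$score)
  z <- if (n >= 2L && s > 0) (cohort$score - mean(cohort$score)) / s
       else rep(0, n)
  sign_vec <- planted_signs(model)
  m <- length(model$base_edges)
  gen_one <- function(k) {
    w <- model$base_edges + sign_vec * model$effect_size * z[k] +
      stats::rnorm(m, 0, model$noise_sd)
    w <- pmin(pmax(w, 0), 1)
    mat <- connectome_from_edges(w, model$n_regions)
    structure(mat, subject_id = cohort$subject_id[k], class = "cpm_connectome")
  }
  run <- function() lapply(seq_len(n), gen_one)
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  names(out) <- cohort$subject_id
  out
}

#' Coupled-oscillator regional time series with score-dependent phase locking
#'
#' Every region carries a 10 Hz (alpha) oscillation with a slowly diffusing
#' phase plus broadband noise. For each planted edge the two member regions
#' mix a shared phase driver into their own phase with weight
#' `w = clamp(mixing_base + sign * mixing_slope * z, 0.02, 1)`, so the
#' alpha-band phase locking of that pair increases (positive edges) or
#' decreases (negative edges) with the standardized score, and downstream
#' PLV correlates with the score. A region belonging to several planted
#' edges follows the first; overlapping planted pairs are a documented
#' simplification.
#'
#' @param z Standardized depression score of the subject (z units); see
#'   [standardize_scores()].
#' @param model A [planted_model()].
#' @param fs Sampling rate in Hz (>= 100).
#' @param n_epochs,epoch_len Recording length as epochs x seconds
#'   (defaults 4 x 40 s, generated as one continuous recording).
#' @param mixing_base,mixing_slope Baseline shared-phase weight and its
#'   slope per unit z (defaults 0.5 and 0.15).
#' @param mixing Optional length-`n_edges(model)` vector of explicit mixing
#'   weights in `[0, 1]` for the planted edges (in `c(pos_edges, neg_edges)`
#'   order), overriding the score-based rule; used for calibration.
#' @param alpha_amp,noise_amp Oscillation and broadband-noise amplitudes in
#'   microvolts (defaults 20 and 5, safely inside the +/-100 uV artifact
#'   threshold).
#' @param phase_diffusion Phase random-walk diffusion rate in rad^2/s
#'   (default 2; sets the oscillator linewidth well inside the alpha band).
#' @param seed Optional integer; fixes the stream.
#' @return A [regional_ts()] object (`n_regions` x samples, `fs`, labels).
#' @export
gen_coupled_timeseries <- function(z, model, fs = 256, n_epochs = 4,
                                   epoch_len = 40, mixing_base = 0.5,
                                   mixing_slope = 0.15, mixing = NULL,
                                   alpha_amp = 20, noise_amp = 5,
                                   phase_diffusion = 2, seed = NULL) {
  stopifnot(inherits(model, "planted_model"), is.numeric(z), length(z) == 1L)
  if (fs < 100) stop("fs must be >= 100 Hz")
  if (fs < 2 * 45) stop("fs below twice the highest band edge (45 Hz)")
  n_reg <- model$n_regions
  n_samp <- round(fs * epoch_len * n_epochs)
  planted <- c(model$pos_edges, model$neg_edges)
  signs <- rep(c(1, -1), c(length(model$pos_edges), length(model$neg_edges)))
  if (is.null(mixing)) {
    mixing <- pmin(pmax(mixing_base + signs * mixing_slope * z, 0.02), 1)
  } else {
    stopifnot(length(mixing) == length(planted), all(mixing >= 0 & mixing <= 1))
  }
  idx <- edge_index(n_reg)
  step_sd <- sqrt(phase_diffusion / fs)
  carrier <- 2 * pi * 10 * (seq_len(n_samp) - 1) / fs
  gen <- function() {
    own <- matrix(stats::rnorm(n_reg * n_samp, 0, step_sd), n_reg, n_samp)
    own <- t(apply(own, 1L, cumsum))
    # shared drivers, one per planted edge
    shared <- matrix(stats::rnorm(length(planted) * n_samp, 0, step_sd),
                     length(planted), n_samp)
    if (length(planted)) shared <- t(apply(shared, 1L, cumsum))
    w_region <- numeric(n_reg)          # mixing weight per region
    drv <- rep(NA_integer_, n_reg)      # which driver a region follows
    for (e in seq_along(planted)) {
      for (r in idx[planted[e], ]) {
        if (is.na(drv[r])) { drv[r] <- e; w_region[r] <- mixing[e] }
      }
    }
    phase <- own
    for (r in which(!is.na(drv))) {
      phase[r, ] <- (1 - w_region[r]) * own[r, ] + w_region[r] * shared[drv[r], ]
    }
    x <- alpha_amp * cos(sweep(phase, 2L, carrier, `+`)) +
      matrix(stats::rnorm(n_reg * n_samp, 0, noise_amp), n_reg, n_samp)
    x
  }
  dat <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  regional_ts(dat, fs = fs)
}
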