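# Default cohort presets calibrated to the published summary statistics of
# the motivating clinical study (a 1.5 T DTI study of high-grade glioma
# patients before/after partial brain radiation therapy and healthy
# controls). No imaging data were deposited, so the simulator reproduces the
# printed cohort-level quantities.

#' Study presets for the glioma radiation cohort
#'
#' Returns the calibration constants the synthetic cohort generator uses by
#' default:
#' \itemize{
#'   \item cross-sectional groups: pre/without-radiation global delta-FA
#'     ~ N(0.007, 0.008) with n = 10; post-radiation ~ N(0.021, 0.013) with
#'     n = 11; 13 control sessions define the noise level (reported bound
#'     0.005, max-abs convention).
#'   \item longitudinal model: delta-FA = intercept + slope * delta-t +
#'     noise. The intercept is the pre-radiation mean (0.007); the slope is
#'     fixed by the two group means at the mean scan interval of 24 months,
#'     (0.021 - 0.007) / 24 per month; the post-radiation residual SD is
#'     chosen so the post marginal SD matches 0.013 given delta-t spread 11
#'     months; delta-t follows a gamma distribution with mean 24 and SD 11
#'     months, clipped to the observed range [2, 111]; 12 scans at
#'     delta-t = 0 and 38 after radiation (50 patient scans).
#'   \item `patients`: the published patient-level scan table (scan counts,
#'     scans without radiation, tumor hemisphere) used as the default
#'     longitudinal layout.
#' }
#'
#' @return named list of constants (see Details).
#' @export
glioma_study_presets <- function() {
  slope <- (0.021 - 0.007) / 24
  list(
    pre_mean = 0.007, pre_sd = 0.008, n_pre = 10L,
    post_mean = 0.021, post_sd = 0.013, n_post = 11L,
    n_controls = 13L,
    control_noise_level = 0.005,
    n_scans_pre = 12L, n_scans_post = 38L,
    dt_mean = 24, dt_sd = 11, dt_range = c(2, 111),
    progression_slope = slope,
    longitudinal_intercept = 0.007,
    resid_sd_pre = 0.008,
    resid_sd_post = sqrt(0.013^2 - (slope * 11)^2),
    fa_threshold = 0.2,
    fwhm = 8, alpha = 0.05, min_cluster = 512L,
    reported_p_crosssection = 0.01,
    reported_spearman_C = 0.48,
    patients = data.frame(
      patient = 1:18,
      scans = c(1, 1, 1, 1, 1, 1, 1, 1, 2, 2, 2, 2, 2, 2, 4, 11, 10, 5),
      scans_without_rt = c(0, 1, 0, 1, 1, 0, 1, 1, 2, 0, 0, 2, 0, 0, 0, 1, 1, 1),
      tumor_hemisphere = c("left", "right", "left", "left", "left", "right",
                           "left", "left", "left", "left", "left", "left",
                           "left", "right", "left", "right", "left", "right"),
      stringsAsFactors = FALSE
    )
  )
}

#' Scalar-level cross-sectional cohort draw
#'
#' Draws the two cross-sectional groups' global delta-FA values directly
#' from the preset normal distributions, without imaging. Used for
#' calibration and significance checks.
#'
#' @param n_pre,n_post group sizes (defaults from the presets).
#' @param presets list from [glioma_study_presets()].
#' @return list with numeric vectors `pre` and `post`.
#' @export
simulate_crosssection_deltas <- function(n_pre = NULL, n_post = NULL,
                                         presets = glioma_study_presets()) {
  if (is.null(n_pre)) n_pre <- presets$n_pre
  if (is.null(n_post)) n_post <- presets$n_post
  list(pre = stats::rnorm(n_pre, presets$pre_mean, presets$pre_sd),
       post = stats::rnorm(n_post, presets$post_mean, presets$post_sd))
}

# draw post-radiation scan intervals (months) from the preset distribution
draw_delta_t <- function(n, presets = glioma_study_presets()) {
  shape <- (presets$dt_mean / presets$dt_sd)^2
  scale <- presets$dt_sd^2 / presets$dt_mean
  pmin(pmax(stats::rgamma(n, shape = shape, scale = scale),
            presets$dt_range[1]), presets$dt_range[2])
}

#' Scalar-level longitudinal session draw
#'
#' Simulates (delta-t, delta-FA) pairs for all patient scans: `n_pre` scans
#' before/without radiation at delta-t = 0 with delta-FA ~ N(intercept,
#' resid_sd_pre), and `n_post` scans after radiation with delta-t from the
#' preset gamma interval distribution and delta-FA = intercept + slope *
#' delta-t + N(0, resid_sd_post).
#'
#' @param n_pre,n_post scan counts (defaults 12 and 38 from the presets).
#' @param presets list from [glioma_study_presets()].
#' @return data.frame with columns `delta_t_months`, `delta_FA`, `rt_status`.
#' @export
simulate_longitudinal_deltas <- function(n_pre = NULL, n_post = NULL,
                                         presets = glioma_study_presets()) {
  if (is.null(n_pre)) n_pre <- presets$n_scans_pre
  if (is.null(n_post)) n_post <- presets$n_scans_post
  dt <- c(rep(0, n_pre), draw_delta_t(n_post, presets))
  dfa <- c(stats::rnorm(n_pre, presets$longitudinal_intercept, presets$resid_sd_pre),
           presets$longitudinal_intercept +
             presets$progression_slope * dt[-seq_len(n_pre)] +
             stats::rnorm(n_post, 0, presets$resid_sd_post))
  data.frame(delta_t_months = dt, delta_FA = dfa,
             rt_status = rep(c("pre", "post"), c(n_pre, n_post)),
             stringsAsFactors = FALSE)
}
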