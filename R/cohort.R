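# Longitudinal synthetic cohort generation: per-session phantoms with
# calibrated effect sizes, written to disk as NIfTI + gradient tables +
# manifest + ground-truth table.

#' Specify a longitudinal synthetic cohort
#'
#' Counts are session counts. The per-session true (noiseless) global
#' delta-FA is drawn from the configured distributions: pre-radiation
#' sessions at delta-t = 0 from N(`target_pre_mean`, `target_pre_sd`);
#' post-radiation sessions from `target_pre_mean + progression_slope *
#' delta_t + N(0, resid SD)`; control sessions are symmetric (factor 0).
#'
#' @param n_controls,n_pre_rt,n_post_rt session counts (>= 0).
#' @param post_rt_delta_t optional fixed vector of post-radiation intervals
#'   (months, length `n_post_rt`); drawn from the preset gamma distribution
#'   when `NULL`.
#' @param target_pre_mean,target_pre_sd,target_post_mean,target_post_sd
#'   group distribution of true delta-FA (defaults from
#'   [glioma_study_presets()]).
#' @param progression_slope delta-FA per month after radiation.
#' @param seed integer RNG seed for the cohort draw.
#' @param phantom template [phantom_spec()] giving grid, voxel size, tensor
#'   eigenvalues, noise and signal levels.
#' @param use_study_layout when `TRUE` (default) and the patient session
#'   counts match the published table (12 pre + 38 post), sessions are
#'   allocated to 18 patients with the published per-patient scan counts and
#'   tumor sides; otherwise each patient session becomes its own subject.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_controls = 13L, n_pre_rt = 12L, n_post_rt = 38L,
                        post_rt_delta_t = NULL,
                        target_pre_mean = NULL, target_pre_sd = NULL,
                        target_post_mean = NULL, target_post_sd = NULL,
                        progression_slope = NULL,
                        seed = 1L,
                        phantom = phantom_spec(),
                        use_study_layout = TRUE) {
  p <- glioma_study_presets()
  if (is.null(target_pre_mean)) target_pre_mean <- p$pre_mean
  if (is.null(target_pre_sd)) target_pre_sd <- p$pre_sd
  if (is.null(target_post_mean)) target_post_mean <- p$post_mean
  if (is.null(target_post_sd)) target_post_sd <- p$post_sd
  if (is.null(progression_slope)) progression_slope <- p$progression_slope
  if (min(n_controls, n_pre_rt, n_post_rt) < 0) stop("counts must be >= 0")
  if (!is.null(post_rt_delta_t) && length(post_rt_delta_t) != n_post_rt)
    stop("post_rt_delta_t must have one entry per post-RT session")
  structure(list(n_controls = as.integer(n_controls),
                 n_pre_rt = as.integer(n_pre_rt),
                 n_post_rt = as.integer(n_post_rt),
                 post_rt_delta_t = post_rt_delta_t,
                 target_pre_mean = target_pre_mean, target_pre_sd = target_pre_sd,
                 target_post_mean = target_post_mean, target_post_sd = target_post_sd,
                 progression_slope = progression_slope,
                 seed = as.integer(seed), phantom = phantom,
                 use_study_layout = isTRUE(use_study_layout)),
            class = "cohort_spec")
}

# allocate patient sessions to subjects; returns data.frame of subject,
# rt_status, tumor_hemisphere per session
allocate_sessions <- function(spec, presets) {
  if (spec$use_study_layout &&
      spec$n_pre_rt == sum(presets$patients$scans_without_rt) &&
      spec$n_post_rt == sum(presets$patients$scans -
                            presets$patients$scans_without_rt)) {
    rows <- do.call(rbind, lapply(seq_len(nrow(presets$patients)), function(i) {
      pt <- presets$patients[i, ]
      data.frame(subject_id = sprintf("P%02d", pt$patient),
                 rt_status = rep(c("pre", "post"),
                                 c(pt$scans_without_rt, pt$scans - pt$scans_without_rt)),
                 tumor_hemisphere = pt$tumor_hemisphere,
                 stringsAsFactors = FALSE)
    }))
  } else {
    n <- spec$n_pre_rt + spec$n_post_rt
    sides <- rep(c("left", "right"), length.out = max(n, 1L))
    rows <- data.frame(subject_id = sprintf("P%02d", seq_len(n)),
                       rt_status = rep(c("pre", "post"),
                                       c(spec$n_pre_rt, spec$n_post_rt)),
                       tumor_hemisphere = sides[seq_len(n)],
                       stringsAsFactors = FALSE)
  }
  rows
}

#' Generate a longitudinal synthetic cohort on disk
#'
#' For every session, draws the true global delta-FA from the configured
#' group model, calibrates the phantom's FA-reduction factor to realize it
#' exactly in the noiseless tensor field, simulates the diffusion-weighted
#' acquisition with Rician noise, and writes: 4D DWI NIfTI, FSL-dialect
#' bvec/bval files, a binary tumor-mask NIfTI, a TSV manifest, and a JSON
#' ground-truth table recording each session's true delta-FA. Tumor
#' location is randomized per subject (fixed across that subject's
#' sessions) within its hemisphere.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory (created if needed).
#' @param scheme gradient scheme (default: 48 directions at b = 800 s/mm2
#'   plus 4 b0).
#' @param write_dwi write the 4D DWI volumes (default `TRUE`); with
#'   `FALSE` only masks, manifest and ground truth are written and sessions
#'   carry empty DWI paths (fast, for statistics-only work).
#' @return list with `manifest` (data.frame, also written as
#'   `manifest.tsv`), `ground_truth` (data.frame, also written as
#'   `ground_truth.json`), `out_dir`.
#' @export
make_longitudinal_cohort <- function(spec, out_dir,
                                     scheme = make_gradient_scheme(),
                                     write_dwi = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  presets <- glioma_study_presets()
  set.seed(spec$seed)

  pat <- allocate_sessions(spec, presets)
  ctl <- if (spec$n_controls > 0)
    data.frame(subject_id = sprintf("C%02d", seq_len(spec$n_controls)),
               rt_status = "none", tumor_hemisphere = "none",
               stringsAsFactors = FALSE) else NULL
  sessions <- rbind(pat, ctl)
  # session ids per subject
  sessions$session_id <- stats::ave(seq_len(nrow(sessions)), sessions$subject_id,
                                    FUN = seq_along)
  sessions$session_id <- sprintf("%s_S%02d", sessions$subject_id, sessions$session_id)
  sessions$group <- ifelse(sessions$rt_status == "none", "control", "patient")

  # delta-t: pre and controls at 0; post drawn (or fixed), sorted per subject
  sessions$delta_t_months <- 0
  is_post <- sessions$rt_status == "post"
  dts <- if (is.null(spec$post_rt_delta_t)) draw_delta_t(sum(is_post), presets)
         else spec$post_rt_delta_t
  sessions$delta_t_months[is_post] <- dts
  for (s in unique(sessions$subject_id)) {
    i <- which(sessions$subject_id == s & is_post)
    if (length(i) > 1L) sessions$delta_t_months[i] <- sort(sessions$delta_t_months[i])
  }

  # true delta-FA per session
  resid_post <- sqrt(max(spec$target_post_sd^2 -
                           (spec$progression_slope * presets$dt_sd)^2, 1e-12))
  tgt <- numeric(nrow(sessions))
  pre_i <- sessions$rt_status == "pre"
  tgt[pre_i] <- stats::rnorm(sum(pre_i), spec$target_pre_mean, spec$target_pre_sd)
  tgt[is_post] <- spec$target_pre_mean +
    spec$progression_slope * sessions$delta_t_months[is_post] +
    stats::rnorm(sum(is_post), 0, resid_post)
  tgt[sessions$rt_status == "none"] <- 0

  # per-subject tumor geometry (fixed across sessions)
  ph0 <- spec$phantom
  dm <- ph0$grid_shape; vs <- ph0$voxel_size
  mid_x <- (dm[1] - 1) / 2
  subj <- unique(sessions$subject_id)
  geom <- list()
  for (s in subj) {
    side <- sessions$tumor_hemisphere[sessions$subject_id == s][1L]
    if (side == "none") { geom[[s]] <- NULL; next }
    min_off <- ph0$tumor_radius / vs[1] + 1.5
    max_off <- 0.32 * dm[1]
    if (min_off > max_off)
      stop("tumor_radius ", ph0$tumor_radius, " mm cannot fit inside one ",
           "hemisphere of a ", dm[1], "-voxel grid at ", vs[1],
           " mm; reduce the radius or enlarge the grid")
    off <- stats::runif(1, min_off, min(max_off, min_off + 6))
    cx <- if (side == "left") mid_x - off else mid_x + off
    geom[[s]] <- c(cx,
                   (dm[2] - 1) / 2 + stats::runif(1, -2, 2),
                   (dm[3] - 1) / 2 + stats::runif(1, -1, 1))
  }
  noise_seeds <- sample.int(1e6, nrow(sessions))

  rows <- vector("list", nrow(sessions))
  truth <- vector("list", nrow(sessions))
  for (i in seq_len(nrow(sessions))) {
    sid <- sessions$session_id[i]
    side <- sessions$tumor_hemisphere[i]
    target_delta <- tgt[i]
    if (side == "none") {
      ps <- phantom_spec(grid_shape = dm, voxel_size = vs,
                         wm_eigenvalues = ph0$wm_eigenvalues,
                         tumor_hemisphere = "none",
                         noise_sigma = ph0$noise_sigma, s0 = ph0$s0)
    } else {
      cal <- calibrate_fa_reduction(target_delta, ph0$wm_eigenvalues)
      red_side <- if (cal$hemisphere_sign > 0) side
                  else setdiff(c("left", "right"), side)
      ps <- phantom_spec(grid_shape = dm, voxel_size = vs,
                         wm_eigenvalues = ph0$wm_eigenvalues,
                         tumor_hemisphere = side,
                         tumor_center = geom[[sessions$subject_id[i]]],
                         tumor_radius = ph0$tumor_radius,
                         fa_reduction_factor = cal$factor,
                         reduction_hemisphere = red_side,
                         noise_sigma = ph0$noise_sigma, s0 = ph0$s0)
    }
    phantom <- build_phantom(ps)
    dwi_path <- file.path(out_dir, paste0(sid, "_dwi.nii.gz"))
    bval_path <- file.path(out_dir, paste0(sid, ".bval"))
    bvec_path <- file.path(out_dir, paste0(sid, ".bvec"))
    mask_path <- file.path(out_dir, paste0(sid, "_tumor.nii.gz"))
    if (write_dwi) {
      dwi <- simulate_dwi(phantom, scheme, seed = noise_seeds[i])
      write_nifti(dwi, dwi_path, voxel_size = vs)
      write_gradient_table(scheme, bval_path, bvec_path)
    } else {
      dwi_path <- bval_path <- bvec_path <- ""
    }
    write_nifti(array(as.numeric(phantom$tumor_mask), dim = dm), mask_path,
                voxel_size = vs)
    rows[[i]] <- data.frame(subject_id = sessions$subject_id[i],
                            session_id = sid,
                            group = sessions$group[i],
                            rt_status = sessions$rt_status[i],
                            delta_t_months = sessions$delta_t_months[i],
                            tumor_hemisphere = side,
                            dwi = dwi_path, bval = bval_path, bvec = bvec_path,
                            tumor_mask = mask_path,
                            stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(session_id = sid,
                             target_delta_fa = target_delta,
                             true_delta_fa = phantom$true_global_delta_fa,
                             fa_reduction_factor = ps$fa_reduction_factor,
                             noise_seed = noise_seeds[i],
                             stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  ground_truth <- do.call(rbind, truth)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(ground_truth, file.path(out_dir, "ground_truth.json"),
                       digits = NA, dataframe = "rows")
  list(manifest = manifest, ground_truth = ground_truth, out_dir = out_dir)
}
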