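# Manifest handling, configuration and the end-to-end pipeline.

MANIFEST_COLUMNS <- c("subject_id", "session_id", "group", "rt_status",
                      "delta_t_months", "tumor_hemisphere",
                      "dwi", "bval", "bvec", "tumor_mask")

#' Load and validate a cohort manifest
#'
#' Reads a TSV manifest (one row per scan session) and validates the schema:
#' required columns, unique (subject, session) pairs, known `rt_status` and
#' hemisphere labels, the control/patient consistency rules (`rt_status
#' "none"` iff `group "control"`; `delta_t_months` 0 unless post-radiation),
#' and existence of referenced files. Violations raise errors naming the row
#' and column.
#'
#' @param path path to the TSV manifest.
#' @param check_files verify that referenced files exist (default `TRUE`;
#'   empty path strings are allowed and skipped).
#' @return data.frame of validated sessions.
#' @export
load_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(MANIFEST_COLUMNS, names(m))
  if (length(missing_cols))
    stop("manifest is missing column(s): ", paste(missing_cols, collapse = ", "))
  key <- paste(m$subject_id, m$session_id)
  if (anyDuplicated(key))
    stop("duplicate session in manifest row ", which(duplicated(key))[1L])
  bad <- which(!m$rt_status %in% c("none", "pre", "post"))
  if (length(bad))
    stop("manifest row ", bad[1L], ", column rt_status: unknown value '",
         m$rt_status[bad[1L]], "'")
  bad <- which(!m$tumor_hemisphere %in% c("none", "left", "right"))
  if (length(bad))
    stop("manifest row ", bad[1L], ", column tumor_hemisphere: unknown value '",
         m$tumor_hemisphere[bad[1L]], "'")
  bad <- which((m$rt_status == "none") != (m$group == "control"))
  if (length(bad))
    stop("manifest row ", bad[1L], ": rt_status 'none' must coincide with ",
         "group 'control'")
  bad <- which(m$rt_status %in% c("none", "pre") & m$delta_t_months != 0)
  if (length(bad))
    stop("manifest row ", bad[1L], ", column delta_t_months: must be 0 for ",
         "rt_status '", m$rt_status[bad[1L]], "'")
  if (check_files) {
    paths <- unlist(m[, c("dwi", "bval", "bvec", "tumor_mask")])
    paths <- paths[nzchar(paths)]
    gone <- paths[!file.exists(paths)]
    if (length(gone))
      stop("manifest references missing file(s): ",
           paste(utils::head(gone, 5), collapse = ", "))
  }
  m
}

#' Pipeline configuration
#'
#' Bundles all stage defaults into one object with a stable hash used to tag
#' outputs. Serializable to/from JSON.
#'
#' @param fa_threshold white-matter FA threshold (default 0.2).
#' @param fwhm WBSS smoothing FWHM in mm (default 8).
#' @param alpha FDR level (default 0.05).
#' @param min_cluster cluster threshold at full grid (default 512; scaled to
#'   the analysis grid at run time).
#' @param radii local-ROI radii in mm.
#' @param halfway halfway-registration mode (`"symmetric"` or
#'   `"moving-only"`).
#' @param weighting tensor-fit weighting (`"signal2"` or `"none"`).
#' @param seed base RNG seed.
#' @param register whether to run per-subject b0 template alignment for
#'   subjects with multiple sessions (default `FALSE`: the synthetic
#'   phantoms are generated pre-aligned; enable for perturbed data).
#' @return object of class `pipeline_config` with a `hash` field.
#' @export
pipeline_config <- function(fa_threshold = 0.2, fwhm = 8, alpha = 0.05,
                            min_cluster = 512L, radii = seq(10, 60, by = 10),
                            halfway = "symmetric", weighting = "signal2",
                            seed = 1L, register = FALSE) {
  cfg <- list(fa_threshold = fa_threshold, fwhm = fwhm, alpha = alpha,
              min_cluster = as.integer(min_cluster), radii = radii,
              halfway = halfway, weighting = weighting,
              seed = as.integer(seed), register = isTRUE(register),
              version = as.character(utils::packageVersion("hemidti")))
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "pipeline_config")
}

# order-independent content hash of the configuration (no digest dependency)
config_hash <- function(cfg) {
  cfg$hash <- NULL
  s <- jsonlite::toJSON(cfg[order(names(cfg))], digits = NA, auto_unbox = TRUE)
  raw <- utils::tail(charToRaw(as.character(s)), 10000L)
  h <- 0
  for (b in as.integer(raw)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Read/write a pipeline configuration as JSON
#' @param cfg a `pipeline_config`.
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` a
#'   `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, j[setdiff(names(j), c("hash", "version"))])
}

log_stage <- function(log, stage, subject, t0, note = "") {
  rec <- data.frame(stage = stage, subject = subject,
                    seconds = round(as.numeric(Sys.time()) - t0, 3),
                    note = note, stringsAsFactors = FALSE)
  message(sprintf("[%s] %s %s (%.2fs) %s", format(Sys.time(), "%H:%M:%S"),
                  stage, subject, rec$seconds, note))
  rbind(log, rec)
}

#' Run the full interhemispheric delta-FA pipeline on a cohort
#'
#' Per subject: (optionally) per-subject b0 template alignment for subjects
#' with >= 2 sessions, then per session tensor fit, scalar maps, and global
#' interhemispheric differences; then cohort-level statistics: control noise
#' level, cross-sectional pre-vs-post comparison, and the longitudinal
#' delta-FA versus delta-t Spearman correlation. Stage failures are isolated
#' per subject and recorded. Outputs (results TSV, statistics JSON) are
#' tagged with the configuration hash.
#'
#' @param manifest data.frame from [load_manifest()] or the generator.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for result files; `NULL` writes nothing.
#' @return list with `deltas` (per-session data.frame), `noise`
#'   (`noise_level` or NULL), `crosssection` (list of `group_comparison`),
#'   `longitudinal`, `wbss` (named list of within-subject `wbss_result`s for
#'   subjects with at least two pre- and two post-radiation sessions),
#'   `failures` (named list of error messages), `log`, `config`.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(), out_dir = NULL) {
  log <- data.frame()
  failures <- list()
  delta_rows <- list()
  wbss_results <- list()
  for (s in unique(manifest$subject_id)) {
    t0 <- as.numeric(Sys.time())
    rows <- manifest[manifest$subject_id == s, , drop = FALSE]
    res <- tryCatch({
      maps_list <- vector("list", nrow(rows))
      b0_list <- vector("list", nrow(rows))
      scheme <- NULL
      vs <- NULL
      for (i in seq_len(nrow(rows))) {
        nii <- read_nifti(rows$dwi[i])
        vs <- nii$voxel_size
        scheme <- read_gradient_table(rows$bval[i], rows$bvec[i])
        fit <- dwi_to_maps(nii$data, scheme, voxel_size = vs,
                           weighting = config$weighting)
        maps_list[[i]] <- fit
        b0_list[[i]] <- fit$b0
      }
      if (config$register && nrow(rows) >= 2L) {
        tpl <- build_b0_template(b0_list, voxel_size = vs,
                                 halfway = config$halfway)
        for (i in seq_len(nrow(rows))) {
          tr <- tpl$transforms[[i]]
          maps_list[[i]]$maps <- lapply(maps_list[[i]]$maps, function(m)
            scalar_map(resample_volume(m$data, tr, vs), m$metric, m$voxel_size))
          maps_list[[i]]$mask <-
            resample_volume(array(as.numeric(maps_list[[i]]$mask),
                                  dim = dim(maps_list[[i]]$mask)), tr, vs) > 0.5
        }
      }
      # within-subject voxelwise statistics when both RT states are sampled
      # at least twice (the voxelwise test needs >= 2 maps per group)
      pre_i <- which(rows$rt_status == "pre")
      post_i <- which(rows$rt_status == "post")
      wb <- NULL
      if (length(pre_i) >= 2L && length(post_i) >= 2L) {
        common <- Reduce(`&`, lapply(maps_list, `[[`, "mask"))
        wb <- wbss(lapply(maps_list[pre_i], function(m) m$maps$FA),
                   lapply(maps_list[post_i], function(m) m$maps$FA),
                   common, fwhm = config$fwhm, alpha = config$alpha,
                   min_cluster = scaled_min_cluster(dim(common),
                                                    config$min_cluster))
      }
      out <- vector("list", nrow(rows))
      for (i in seq_len(nrow(rows))) {
        tumor <- read_nifti(rows$tumor_mask[i])$data > 0.5
        hemis <- hemisphere_masks(maps_list[[i]]$mask)
        dr <- global_delta(maps_list[[i]]$maps, hemis,
                           tumor_hemisphere = rows$tumor_hemisphere[i],
                           fa_threshold = config$fa_threshold,
                           tumor_mask = tumor,
                           session_id = rows$session_id[i])
        out[[i]] <- cbind(rows[i, c("subject_id", "session_id", "group",
                                    "rt_status", "delta_t_months",
                                    "tumor_hemisphere")],
                          as.data.frame(as.list(dr$delta)),
                          n_healthy = dr$n_healthy,
                          n_tumor_side = dr$n_tumor_side,
                          valid = dr$valid)
      }
      list(deltas = do.call(rbind, out), wbss = wb)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[s]] <- conditionMessage(res)
      log <- log_stage(log, "subject", s, t0, paste("FAILED:", failures[[s]]))
    } else {
      delta_rows[[s]] <- res$deltas
      if (!is.null(res$wbss)) wbss_results[[s]] <- res$wbss
      log <- log_stage(log, "subject", s, t0)
    }
  }
  deltas <- do.call(rbind, delta_rows)
  rownames(deltas) <- NULL

  noise <- NULL
  ctl <- deltas[deltas$group == "control", , drop = FALSE]
  if (nrow(ctl) >= 2L) noise <- noise_level(ctl$delta_FA)
  cs <- tryCatch(crosssection(deltas), error = function(e) NULL)
  lg <- tryCatch(longitudinal_correlation(deltas), error = function(e) NULL)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(deltas, file.path(out_dir,
                       sprintf("deltas_%s.tsv", config$hash)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report <- list(config = unclass(config),
                   noise = if (is.null(noise)) NULL else unclass(noise),
                   crosssection = if (is.null(cs)) NULL else
                     lapply(cs, function(g) unclass(g)),
                   longitudinal = if (is.null(lg)) NULL else
                     list(overall = unclass(lg$overall)),
                   failures = failures)
    jsonlite::write_json(report, file.path(out_dir,
                         sprintf("report_%s.json", config$hash)),
                         digits = NA, auto_unbox = TRUE, force = TRUE)
  }
  list(deltas = deltas, noise = noise, crosssection = cs, longitudinal = lg,
       wbss = wbss_results, failures = failures, log = log, config = config)
}
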