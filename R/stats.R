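# Nonparametric cohort statistics: exact/approximate Mann-Whitney, Spearman
# rank correlation, control noise level, cross-sectional and longitudinal
# cohort analyses.

# U statistic (number of (a, b) pairs with a > b, ties counted 1/2) and tie
# profile from two samples.
u_statistic <- function(a, b) {
  r <- rank(c(a, b))
  n1 <- length(a)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  list(u = u, ties = table(r), has_ties = anyDuplicated(c(a, b)) > 0L)
}

#' Wilcoxon-Mann-Whitney two-sample test
#'
#' Two-sided rank-sum test. When the pooled sample has at most 20
#' observations and no ties, the p-value is exact (full null distribution of
#' U, equivalent to enumerating all group labelings); otherwise a
#' tie-corrected normal approximation with continuity correction is used.
#' Identical constant samples give p = 1 with a degeneracy flag.
#'
#' @param a,b numeric vectors (both nonempty).
#' @return object of class `group_comparison`: `n` (per group), `mean`, `sd`,
#'   `u` (Mann-Whitney U of the first sample), `p`, `method`
#'   (`"exact"`/`"normal-approximation"`), `degenerate`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p  # 0.1
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be nonempty")
  n1 <- length(a); n2 <- length(b)
  st <- u_statistic(a, b)
  u <- st$u
  degenerate <- length(unique(c(a, b))) == 1L
  if (degenerate) {
    p <- 1; method <- "degenerate"
  } else if (n1 + n2 <= 20L && !st$has_ties) {
    u_low <- min(u, n1 * n2 - u)
    p <- min(1, 2 * stats::pwilcox(u_low, n1, n2))
    method <- "exact"
  } else {
    m <- n1 * n2 / 2
    tie_sizes <- as.numeric(st$ties)
    N <- n1 + n2
    corr <- sum(tie_sizes^3 - tie_sizes) / (N * (N - 1))
    v <- n1 * n2 / 12 * ((N + 1) - corr)
    if (v <= 0) {
      p <- 1; method <- "degenerate"
    } else {
      z <- (u - m - sign(u - m) * 0.5) / sqrt(v)   # continuity correction
      p <- min(1, 2 * stats::pnorm(-abs(z)))
      method <- "normal-approximation"
    }
  }
  structure(list(n = c(a = n1, b = n2),
                 mean = c(a = mean(a), b = mean(b)),
                 sd = c(a = stats::sd(a), b = stats::sd(b)),
                 u = u, p = p, method = method, degenerate = degenerate),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> n = %d vs %d; mean +/- SD: %.4g +/- %.4g vs %.4g +/- %.4g\n",
              x$n[1], x$n[2], x$mean[1], x$sd[1], x$mean[2], x$sd[2]))
  cat(sprintf("  U = %g, two-sided p = %.4g (%s)\n", x$u, x$p, x$method))
  invisible(x)
}

# all permutations of 1..n as an n! x n matrix (small n only)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L), deparse.level = 0)
  }))
}

#' Spearman rank correlation
#'
#' Rank-transforms both vectors (mid-ranks for ties) and takes the Pearson
#' correlation of the ranks. The two-sided p-value is exact by full
#' permutation of one rank vector for n < 10, and a t-approximation with
#' n - 2 degrees of freedom otherwise. Constant input yields an undefined
#' correlation flag.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return object of class `correlation_result`: `n`, `C` (coefficient), `p`,
#'   `method`, `ties` (logical), `undefined` (logical).
#' @examples
#' spearman_cor(c(1, 2, 3), c(2, 1, 3))$C  # 0.5
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(structure(list(n = n, C = NA_real_, p = NA_real_,
                          method = "undefined", ties = TRUE, undefined = TRUE),
                     class = "correlation_result"))
  rx <- rank(x); ry <- rank(y)
  C <- stats::cor(rx, ry)
  has_ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (n < 10L) {
    P <- all_perms(n)
    rxc <- rx - mean(rx); ryc <- ry - mean(ry)
    # permutation correlations via one matrix product on centered ranks
    num <- matrix(ryc[P], nrow(P), n) %*% rxc
    Cs <- as.numeric(num) / sqrt(sum(rxc^2) * sum(ryc^2))
    p <- mean(abs(Cs) >= abs(C) - 1e-12)
    method <- "exact-permutation"
  } else {
    tstat <- C * sqrt((n - 2) / max(1 - C^2, .Machine$double.eps))
    p <- min(1, 2 * stats::pt(-abs(tstat), df = n - 2))
    method <- "t-approximation"
  }
  structure(list(n = n, C = C, p = p, method = method, ties = has_ties,
                 undefined = FALSE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (x$undefined) cat("<correlation_result> undefined (constant input)\n")
  else cat(sprintf("<correlation_result> n = %d, C = %.4f, two-sided p = %.4g (%s)\n",
                   x$n, x$C, x$p, x$method))
  invisible(x)
}

#' Control noise level of delta-FA
#'
#' Summaries of the signed interhemispheric FA differences observed in
#' control sessions (where the true difference is zero): the maximum absolute
#' value (primary summary, since the reported bound covers both FA reduction
#' and FA increase), the standard deviation, and the 95th percentile of the
#' absolute values.
#'
#' @param control_deltas numeric vector of signed control delta-FA values
#'   (>= 2 values).
#' @return object of class `noise_level`: `values`, `max_abs`, `sd`, `q95_abs`.
#' @export
noise_level <- function(control_deltas) {
  if (length(control_deltas) < 2L) stop("need at least 2 control sessions")
  structure(list(values = control_deltas,
                 max_abs = max(abs(control_deltas)),
                 sd = stats::sd(control_deltas),
                 q95_abs = stats::quantile(abs(control_deltas), 0.95, names = FALSE)),
            class = "noise_level")
}

#' @export
print.noise_level <- function(x, ...) {
  cat(sprintf("<noise_level> n = %d controls: max |dFA| = %.5f, SD = %.5f, q95 = %.5f\n",
              length(x$values), x$max_abs, x$sd, x$q95_abs))
  invisible(x)
}

#' Cross-sectional group comparison of interhemispheric differences
#'
#' Forms the pre/without-radiation and post-radiation groups from a session
#' table, enforcing at most one scan per patient per group (the earliest
#' available by time since radiation, then by session order), and compares
#' them with [mann_whitney()] for each delta metric present.
#'
#' @param sessions data.frame with columns `subject_id`, `rt_status`
#'   (`"none"`/`"pre"`/`"post"`), `delta_t_months`, and one or more
#'   `delta_*` columns (at least `delta_FA`). Control rows (`rt_status
#'   "none"` for `group "control"`) are ignored here.
#' @return named list of `group_comparison` objects, one per delta metric,
#'   plus attribute `selection` (the selected rows).
#' @export
crosssection <- function(sessions) {
  stopifnot(all(c("subject_id", "rt_status", "delta_FA") %in% names(sessions)))
  pat <- sessions[sessions$rt_status %in% c("pre", "post"), , drop = FALSE]
  pick_one <- function(d) {
    d[order(d$delta_t_months, seq_len(nrow(d)))[1L], , drop = FALSE]
  }
  sel <- do.call(rbind, lapply(split(pat, list(pat$subject_id, pat$rt_status),
                                     drop = TRUE), pick_one))
  pre <- sel[sel$rt_status == "pre", , drop = FALSE]
  post <- sel[sel$rt_status == "post", , drop = FALSE]
  if (nrow(pre) == 0L) stop("cross-sectional analysis: empty pre/without-RT group")
  if (nrow(post) == 0L) stop("cross-sectional analysis: empty post-RT group")
  metrics <- grep("^delta_", names(sessions), value = TRUE)
  out <- lapply(metrics, function(m) mann_whitney(pre[[m]], post[[m]]))
  names(out) <- metrics
  attr(out, "selection") <- sel
  out
}

#' Longitudinal delta-FA versus time since radiation
#'
#' Pairs every patient scan's global delta-FA with its time interval to
#' radiation therapy (0 for scans before or without radiation) and computes
#' the Spearman correlation over all scans; optionally per-subject
#' correlations for subjects with at least `min_scans` sessions.
#'
#' @param sessions data.frame as in [crosssection()].
#' @param per_subject_min minimum session count for per-subject correlations
#'   (default 5).
#' @return list with `overall` (`correlation_result`) and `per_subject`
#'   (named list of `correlation_result`).
#' @export
longitudinal_correlation <- function(sessions, per_subject_min = 5L) {
  pat <- sessions[sessions$rt_status %in% c("pre", "post"), , drop = FALSE]
  if (nrow(pat) < 3L) stop("need at least 3 patient sessions")
  dt <- ifelse(pat$rt_status == "pre", 0, pat$delta_t_months)
  overall <- spearman_cor(dt, pat$delta_FA)
  per_subject <- list()
  for (s in unique(pat$subject_id)) {
    rows <- pat[pat$subject_id == s, , drop = FALSE]
    if (nrow(rows) >= per_subject_min) {
      dts <- ifelse(rows$rt_status == "pre", 0, rows$delta_t_months)
      per_subject[[s]] <- spearman_cor(dts, rows$delta_FA)
    }
  }
  list(overall = overall, per_subject = per_subject)
}
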