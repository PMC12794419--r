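#' Extract peak voxels from an average difference map
#'
#' Finds local maxima (26-connectivity) of the cohort-average
#' within-minus-between difference inside the FDR-significant mask. Maxima
#' closer together than `min_distance_mm` are merged, keeping the voxel
#' with the larger difference. Coordinates are reported in mm through the
#' affine.
#'
#' @param average_diff Per-voxel vector of the average difference (masked
#'   voxel order).
#' @param significant Logical per-voxel significance mask (same order).
#' @param voxel_ijk Voxel index matrix (voxels x 3, 1-based).
#' @param affine 4x4 voxel-to-mm affine.
#' @param min_distance_mm Minimum separation between reported peaks.
#' @param p_values Optional per-voxel p-values to report alongside each
#'   peak.
#' @param narrative Provenance label stored in the table
#'   (`"all"`/`"pro"`/`"anti"`).
#' @return Data frame of class `"peak_table"`, one row per peak: `x_mm`,
#'   `y_mm`, `z_mm`, `i`, `j`, `k`, `voxel` (index into the masked vector),
#'   `d` (average difference), `p`, `source`. Empty mask gives an empty
#'   table.
#' @export
extract_peaks <- function(average_diff, significant, voxel_ijk, affine,
                          min_distance_mm = 10, p_values = NULL,
                          narrative = "all") {
  empty <- data.frame(x_mm = numeric(0), y_mm = numeric(0), z_mm = numeric(0),
                      i = integer(0), j = integer(0), k = integer(0),
                      voxel = integer(0), d = numeric(0), p = numeric(0),
                      source = character(0), stringsAsFactors = FALSE)
  class(empty) <- c("peak_table", class(empty))
  sig <- which(significant & is.finite(average_diff))
  if (length(sig) == 0) return(empty)
  if (diff(range(average_diff[sig])) == 0 && length(sig) > 1) {
    stop("average difference map is flat inside the mask; peaks undefined")
  }

  # local maxima under 26-connectivity, restricted to the significant mask
  key <- function(ijk) paste(ijk[, 1], ijk[, 2], ijk[, 3], sep = ",")
  val <- stats::setNames(average_diff, key(voxel_ijk))
  in_sig <- stats::setNames(seq_along(average_diff) %in% sig, key(voxel_ijk))
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  is_peak <- vapply(sig, function(v) {
    here <- average_diff[v]
    nb <- sweep(offs, 2, as.numeric(voxel_ijk[v, ]), `+`)
    nbk <- key(nb)
    nbv <- val[nbk]
    nbv <- nbv[!is.na(nbv)]
    all(here >= nbv)
  }, logical(1))
  cand <- sig[is_peak]
  cand <- cand[order(average_diff[cand], decreasing = TRUE)]

  mm <- .ijk_to_mm(voxel_ijk, affine)
  kept <- integer(0)
  for (v in cand) {
    if (length(kept) == 0) {
      kept <- v
      next
    }
    dists <- sqrt(rowSums((mm[kept, , drop = FALSE] -
                             matrix(mm[v, ], length(kept), 3,
                                    byrow = TRUE))^2))
    if (all(dists >= min_distance_mm)) kept <- c(kept, v)
  }

  out <- data.frame(
    x_mm = mm[kept, 1], y_mm = mm[kept, 2], z_mm = mm[kept, 3],
    i = voxel_ijk[kept, 1], j = voxel_ijk[kept, 2], k = voxel_ijk[kept, 3],
    voxel = kept, d = average_diff[kept],
    p = if (is.null(p_values)) NA_real_ else p_values[kept],
    source = narrative, stringsAsFactors = FALSE
  )
  class(out) <- c("peak_table", class(out))
  out
}

#' Score every subject at the peak voxels
#'
#' Reads each subject's within-group R, between-group R and their
#' difference at every peak voxel.
#'
#' @param maps A `"polarization_maps"` object.
#' @param peaks A `"peak_table"` from [extract_peaks()].
#' @param assignment Group assignment (`subject_id`, `group`).
#' @return Data frame of class `"peak_scores"`: one row per subject x peak
#'   with `subject_id`, `peak`, `group`, `within_R`, `between_R`, `diff`.
#' @export
score_peaks <- function(maps, peaks, assignment) {
  if (nrow(peaks) == 0) stop("empty peak table")
  if (any(peaks$voxel < 1 | peaks$voxel > ncol(maps$diff))) {
    stop("peak voxel outside the map grid")
  }
  grp <- stats::setNames(assignment$group, assignment$subject_id)
  ids <- rownames(maps$diff)
  rows <- lapply(seq_len(nrow(peaks)), function(pi) {
    v <- peaks$voxel[pi]
    data.frame(subject_id = ids,
               peak = pi, group = unname(grp[ids]),
               within_R = maps$within[, v],
               between_R = maps$between[, v],
               diff = maps$diff[, v],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("peak_scores", class(out))
  out
}

# Pooled-variance two-sample t with Cohen's d; x and y plain vectors.
.two_sample_report <- function(x, y) {
  tt <- stats::t.test(x, y, var.equal = TRUE)
  t <- unname(tt$statistic)
  list(t = t, df = unname(tt$parameter), p = tt$p.value,
       cohens_d = cohens_d_from_t(t, length(x), length(y)),
       mean_x = mean(x), mean_y = mean(y),
       ci_x = mean(x) + c(-1, 1) * stats::qt(0.975, length(x) - 1) *
         stats::sd(x) / sqrt(length(x)),
       ci_y = mean(y) + c(-1, 1) * stats::qt(0.975, length(y) - 1) *
         stats::sd(y) / sqrt(length(y)))
}

#' Peak-level group statistics
#'
#' Per peak: (a) a one-sample t test of the within-minus-between difference
#' inside each group separately (df = n - 1), and (b) a pooled-variance
#' two-sample t test between the groups (df = n1 + n2 - 2) with Cohen's d.
#'
#' @param scores A `"peak_scores"` data frame.
#' @return Data frame with one row per peak: group-wise one-sample `t_more`
#'   / `p_more` / `t_less` / `p_less`, and between-group `t_between`,
#'   `df_between`, `p_between`, `cohens_d`.
#' @export
peak_level_tests <- function(scores) {
  by_peak <- split(scores, scores$peak)
  rows <- lapply(by_peak, function(s) {
    more <- s$diff[s$group == "more_supportive"]
    less <- s$diff[s$group == "less_supportive"]
    if (length(more) < 2 || length(less) < 2) {
      stop("both groups need at least 2 subjects")
    }
    one <- function(v) {
      if (stats::sd(v) == 0) {
        list(statistic = 0, parameter = length(v) - 1, p.value = 1)
      } else {
        stats::t.test(v)
      }
    }
    om <- one(more)
    ol <- one(less)
    bt <- .two_sample_report(more, less)
    data.frame(peak = s$peak[1],
               t_more = unname(om$statistic[[1]]), df_more = length(more) - 1,
               p_more = om$p.value,
               t_less = unname(ol$statistic[[1]]), df_less = length(less) - 1,
               p_less = ol$p.value,
               t_between = bt$t, df_between = bt$df, p_between = bt$p,
               cohens_d = bt$cohens_d, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pooled peak contrast between groups
#'
#' Averages each subject's within-minus-between difference over a set of
#' peaks and compares the pooled scores between the two groups
#' (pooled-variance t, Cohen's d, group means with t-based 95% CIs).
#'
#' @param scores A `"peak_scores"` data frame.
#' @param peak_set Peak indices to pool (default: all peaks present).
#' @return List: `pooled` (per-subject pooled scores), `t`, `df`, `p`,
#'   `cohens_d`, `mean_more`, `ci_more`, `mean_less`, `ci_less`.
#' @export
pooled_peak_contrast <- function(scores, peak_set = NULL) {
  if (!is.null(peak_set)) {
    if (length(peak_set) == 0) stop("empty peak set")
    scores <- scores[scores$peak %in% peak_set, , drop = FALSE]
    if (nrow(scores) == 0) stop("empty peak set")
  }
  pooled <- tapply(scores$diff, scores$subject_id, mean)
  grp <- stats::setNames(scores$group, scores$subject_id)
  grp <- grp[names(pooled)]
  more <- pooled[grp == "more_supportive"]
  less <- pooled[grp == "less_supportive"]
  bt <- .two_sample_report(as.numeric(more), as.numeric(less))
  list(pooled = pooled, t = bt$t, df = bt$df, p = bt$p,
       cohens_d = bt$cohens_d,
       mean_more = bt$mean_x, ci_more = bt$ci_x,
       mean_less = bt$mean_y, ci_less = bt$ci_y)
}

#' Contrast peak scores across narrative types
#'
#' For each peak, a paired t test (df = n - 1) across subjects comparing
#' the within-minus-between difference computed from pro frames against the
#' one computed from anti frames, with two-stage adaptive FDR q-values over
#' the peak family.
#'
#' @param scores_pro,scores_anti `"peak_scores"` for the same peaks and
#'   subjects, scored from the pro- and anti-restricted maps.
#' @param q_level FDR level over the peak family.
#' @return Data frame: `peak`, `t`, `df`, `p`, `q`.
#' @export
cross_narrative_contrast <- function(scores_pro, scores_anti,
                                     q_level = 0.05) {
  key <- function(s) paste(s$subject_id, s$peak)
  if (!identical(sort(key(scores_pro)), sort(key(scores_anti)))) {
    stop("pro and anti scorings must cover the same subjects and peaks")
  }
  scores_anti <- scores_anti[match(key(scores_pro), key(scores_anti)), ]
  rows <- lapply(split(seq_len(nrow(scores_pro)), scores_pro$peak),
                 function(idx) {
    d <- scores_pro$diff[idx] - scores_anti$diff[idx]
    if (stats::sd(d) == 0) {
      data.frame(peak = scores_pro$peak[idx[1]], t = 0,
                 df = length(d) - 1, p = 1)
    } else {
      tt <- stats::t.test(d)
      data.frame(peak = scores_pro$peak[idx[1]], t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value)
    }
  })
  out <- do.call(rbind, rows)
  out$q <- bky_fdr(.safe_p(out$p), q_level = q_level)$q
  out
}

#' Mixed-design interaction ANOVA (group x narrative type)
#'
#' Two-by-two mixed ANOVA with group (between subjects) and narrative type
#' (within subjects), computed from the classical sums-of-squares
#' decomposition; reports the interaction F with df (1, n - 2). For the
#' balanced design this F equals the square of the two-sample t on the
#' per-subject pro-minus-anti differences.
#'
#' @param diffs Data frame `subject_id`, `pro`, `anti` (per-subject scores
#'   under each narrative type).
#' @param assignment Group assignment (`subject_id`, `group`).
#' @return List: `F`, `df1`, `df2`, `p`.
#' @export
interaction_anova <- function(diffs, assignment) {
  if (anyNA(diffs$pro) || anyNA(diffs$anti)) stop("missing cells")
  grp <- stats::setNames(assignment$group, assignment$subject_id)
  g <- grp[diffs$subject_id]
  if (anyNA(g)) stop("subjects missing from the assignment")
  n <- nrow(diffs)
  y <- c(diffs$pro, diffs$anti)
  cond <- rep(c("pro", "anti"), each = n)
  subj <- rep(diffs$subject_id, 2)
  gg <- rep(g, 2)

  grand <- mean(y)
  cell_means <- tapply(y, list(gg, cond), mean)
  g_means <- tapply(y, gg, mean)
  c_means <- tapply(y, cond, mean)
  n_per_cell <- tapply(y, list(gg, cond), length)
  ss_inter <- sum(n_per_cell * (cell_means -
    outer(g_means, rep(1, 2)) -
    matrix(c_means[colnames(cell_means)], nrow = 2, ncol = 2, byrow = TRUE) +
    grand)^2)
  subj_means <- tapply(y, subj, mean)
  # residual of the within stratum: total within-subject SS minus condition
  # and interaction effects
  ss_within_total <- sum((y - subj_means[subj])^2)
  ss_cond <- sum(tapply(y, cond, length) * (c_means - grand)^2)
  ss_resid <- ss_within_total - ss_cond - ss_inter
  df2 <- n - 2
  Fstat <- (ss_inter / 1) / (ss_resid / df2)
  list(F = Fstat, df1 = 1, df2 = df2,
       p = stats::pf(Fstat, 1, df2, lower.tail = FALSE))
}

#' Compare between-group ISC across peak sets
#'
#' Pools every subject's between-group R over peak set A and over peak set
#' B, and runs a pooled-variance two-sample t test on the two stacks of
#' per-subject values (df = n_A + n_B - 2). Used to ask whether the
#' (negative) between-group coupling at one narrative's peaks differs from
#' the (positive) coupling at another's.
#'
#' @param scores_a,scores_b `"peak_scores"` for the two peak sets.
#' @return List: `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
between_group_sign_comparison <- function(scores_a, scores_b) {
  a <- tapply(scores_a$between_R, scores_a$subject_id, mean)
  b <- tapply(scores_b$between_R, scores_b$subject_id, mean)
  if (stats::sd(a) + stats::sd(b) == 0) stop("zero variance")
  bt <- .two_sample_report(as.numeric(a), as.numeric(b))
  list(t = bt$t, df = bt$df, p = bt$p, mean_a = bt$mean_x, mean_b = bt$mean_y)
}

#' Correlate peak scores with behavioral measures
#'
#' Pearson and Spearman correlations of each peak-score column against each
#' behavioral measure, with uncorrected p-values and two-stage adaptive FDR
#' q-values computed separately over the Pearson and Spearman families.
#'
#' @param peak_scores Named list of per-subject neural scores (each a named
#'   numeric vector, e.g. per-peak differences or a pooled score).
#' @param measures Named list of per-subject behavioral vectors (IAS,
#'   scale scores, ...), names keyed by subject id.
#' @param q_level FDR level.
#' @return Data frame: `neural`, `measure`, `pearson_r`, `pearson_p`,
#'   `pearson_q`, `spearman_rho`, `spearman_p`, `spearman_q`.
#' @export
correlate_peaks_with_behavior <- function(peak_scores, measures,
                                          q_level = 0.05) {
  rows <- list()
  for (nn in names(peak_scores)) {
    for (mn in names(measures)) {
      x <- peak_scores[[nn]]
      y <- measures[[mn]]
      ids <- intersect(names(x), names(y))
      if (length(ids) < 3) stop("need at least 3 subjects")
      if (stats::var(x[ids]) == 0 || stats::var(y[ids]) == 0) {
        stop("zero variance in ", nn, " or ", mn)
      }
      pe <- suppressWarnings(stats::cor.test(x[ids], y[ids],
                                             method = "pearson"))
      sp <- suppressWarnings(stats::cor.test(x[ids], y[ids],
                                             method = "spearman"))
      rows[[length(rows) + 1]] <- data.frame(
        neural = nn, measure = mn,
        pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
        spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$pearson_q <- bky_fdr(.safe_p(out$pearson_p), q_level = q_level)$q
  out$spearman_q <- bky_fdr(.safe_p(out$spearman_p), q_level = q_level)$q
  out
}
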