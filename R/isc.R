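# Coerce a cohort-like input into a named list of voxel x frame matrices.
.as_matrix_list <- function(x) {
  if (inherits(x, "synthetic_cohort")) return(x$data)
  if (is.list(x) && all(vapply(x, function(m) {
    inherits(m, "subject_ts") || is.matrix(m)
  }, logical(1)))) {
    out <- lapply(x, function(m) if (inherits(m, "subject_ts")) m$data else m)
    if (is.null(names(out))) names(out) <- sprintf("s%02d", seq_along(out))
    return(out)
  }
  stop("expected a synthetic_cohort, a list of subject_ts, or of matrices")
}

.check_conformable <- function(mats) {
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all subjects must share the same voxel set and frame count")
  }
  invisible(dims[, 1])
}

#' One-to-average inter-subject correlation
#'
#' For every subject and voxel, the Pearson correlation between that
#' subject's time course and the average time course of the other subjects
#' at the same voxel (leave-one-out by default). The cohort map is the mean
#' over subjects of these per-subject R values.
#'
#' @param cohort A `"synthetic_cohort"`, or a list of [subject_ts()] /
#'   voxel x frame matrices (all conformable; at least 3 subjects).
#' @param leave_one_out Exclude the subject from the reference average?
#'   `TRUE` (default) matches the within-group definition; `FALSE` uses the
#'   grand average including the subject.
#' @return Object of class `"isc_map"`: list with `R` (subject x voxel
#'   matrix), `average` (per-voxel mean R over subjects), `group_definition
#'   = "whole_sample"`, `narrative = "all"`. Voxels with a zero-variance
#'   series in a pair are `NA` (masked), never zero-filled.
#' @export
one_to_average_isc <- function(cohort, leave_one_out = TRUE) {
  mats <- .as_matrix_list(cohort)
  if (length(mats) < 3) stop("one-to-average ISC needs at least 3 subjects")
  .check_conformable(mats)
  total <- Reduce(`+`, mats)
  n <- length(mats)
  R <- t(vapply(seq_len(n), function(i) {
    ref <- if (leave_one_out) (total - mats[[i]]) / (n - 1) else total / n
    .row_pearson(mats[[i]], ref)
  }, numeric(nrow(mats[[1]]))))
  rownames(R) <- names(mats)
  structure(list(R = R, average = colMeans(R),
                 group_definition = "whole_sample", narrative = "all"),
            class = "isc_map")
}

#' Within- and between-group ISC and their difference
#'
#' For each subject: `within_R` correlates their time course with the
#' average of all *other* subjects in their own group (leave-one-out), and
#' `between_R` with the average of *all* subjects in the other group. The
#' per-subject, per-voxel difference `within_R - between_R` is the neural
#' polarization measure; its mean over subjects is the map the permutation
#' test consumes.
#'
#' @inheritParams one_to_average_isc
#' @param assignment Group assignment from [median_split()] (columns
#'   `subject_id`, `group`); both groups need at least 2 subjects.
#' @param frames Optional integer/logical frame selector applied to every
#'   subject before correlating (used for narrative-restricted analyses).
#' @param narrative Label recorded in the result (`"all"`, `"pro"`,
#'   `"anti"`).
#' @return Object of class `"polarization_maps"`: `within`, `between`,
#'   `diff` (subject x voxel matrices), `average_diff` (per-voxel mean of
#'   the per-subject differences), `assignment`, `narrative`.
#' @export
grouped_isc <- function(cohort, assignment, frames = NULL, narrative = "all") {
  mats <- .as_matrix_list(cohort)
  .check_conformable(mats)
  if (!is.null(frames)) {
    mats <- lapply(mats, function(m) m[, frames, drop = FALSE])
  }
  ids <- assignment$subject_id
  if (!all(ids %in% names(mats))) {
    stop("assignment contains subjects absent from the cohort")
  }
  mats <- mats[ids]
  grp <- split(ids, assignment$group)
  if (length(grp) != 2 || any(lengths(grp) < 2)) {
    stop("both groups need at least 2 subjects")
  }
  totals <- lapply(grp, function(g) Reduce(`+`, mats[g]))
  nv <- nrow(mats[[1]])
  within <- between <- matrix(NA_real_, length(ids), nv,
                              dimnames = list(ids, NULL))
  for (gi in seq_along(grp)) {
    own <- grp[[gi]]
    other <- grp[[3 - gi]]
    ref_between <- totals[[3 - gi]] / length(other)
    for (id in own) {
      ref_within <- (totals[[gi]] - mats[[id]]) / (length(own) - 1)
      within[id, ] <- .row_pearson(mats[[id]], ref_within)
      between[id, ] <- .row_pearson(mats[[id]], ref_between)
    }
  }
  diff <- within - between
  structure(list(within = within, between = between, diff = diff,
                 average_diff = colMeans(diff), assignment = assignment,
                 narrative = narrative),
            class = "polarization_maps")
}

#' Narrative-restricted grouped ISC
#'
#' Identical to [grouped_isc()] but correlations use only the concatenated
#' frames belonging to statements of the requested narrative type.
#'
#' @inheritParams grouped_isc
#' @param frame_type Character vector labelling each concatenated frame
#'   (`"pro"`/`"anti"`), e.g. from [extract_and_concatenate()].
#' @param type `"pro"`, `"anti"`, or `"all"` (the latter is exactly
#'   [grouped_isc()]).
#' @return A `"polarization_maps"` object (see [grouped_isc()]).
#' @export
narrative_restricted_isc <- function(cohort, assignment, frame_type,
                                     type = c("all", "pro", "anti")) {
  type <- match.arg(type)
  if (type == "all") {
    return(grouped_isc(cohort, assignment, narrative = "all"))
  }
  frames <- which(frame_type == type)
  if (length(frames) < 10) {
    stop("fewer than 10 frames belong to narrative type '", type, "'")
  }
  grouped_isc(cohort, assignment, frames = frames, narrative = type)
}

#' Write a per-voxel map as NIfTI-1 and TSV
#'
#' @param values Per-voxel vector (masked order).
#' @param mask 3D logical array.
#' @param affine 4x4 voxel-to-mm affine.
#' @param path Output path without extension; writes `<path>.nii` and
#'   `<path>.tsv` (columns i, j, k, value).
#' @param voxel_ijk Voxel index matrix matching `values`.
#' @return Invisibly, the two file paths.
#' @export
write_map <- function(values, mask, affine, voxel_ijk, path) {
  vol <- .vec_to_volume(values, mask, fill = 0)
  img <- RNifti::asNifti(vol)
  nii <- paste0(path, ".nii")
  RNifti::writeNifti(img, nii)
  tsv <- paste0(path, ".tsv")
  utils::write.table(
    data.frame(i = voxel_ijk[, 1], j = voxel_ijk[, 2], k = voxel_ijk[, 3],
               value = values),
    tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(nii, tsv))
}
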