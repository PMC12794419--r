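#' Subject time-series container
#'
#' Bundles one subject's masked voxel-by-frame data with the voxel index,
#' affine and sampling interval.
#'
#' @param subject_id Subject identifier.
#' @param data Numeric voxel x frame matrix.
#' @param voxel_ijk Integer matrix (voxels x 3) of 1-based grid indices.
#' @param affine 4x4 voxel-to-mm affine.
#' @param tr_s Sampling interval in seconds.
#' @return Object of class `"subject_ts"`.
#' @export
subject_ts <- function(subject_id, data, voxel_ijk, affine, tr_s) {
  stopifnot(is.matrix(data), nrow(voxel_ijk) == nrow(data), tr_s > 0)
  structure(list(subject_id = subject_id, data = data, voxel_ijk = voxel_ijk,
                 affine = affine, tr_s = tr_s),
            class = "subject_ts")
}

#' Exclude subjects by head motion
#'
#' A subject is excluded when strictly more than `frac` of their framewise
#' displacement values exceed `threshold_mm` (defaults: more than 25% of
#' frames above 0.5 mm).
#'
#' @param fd_by_subject Frame x subject matrix, or named list of FD vectors.
#' @param frac Proportion threshold (strict inequality).
#' @param threshold_mm FD threshold in mm.
#' @return List with `kept`, `excluded` (subject names) and `proportion`
#'   (named vector of above-threshold proportions).
#' @export
exclude_by_motion <- function(fd_by_subject, frac = 0.25, threshold_mm = 0.5) {
  if (is.matrix(fd_by_subject)) {
    fd_by_subject <- as.list(as.data.frame(fd_by_subject))
  }
  if (any(lengths(fd_by_subject) == 0)) stop("empty FD series")
  prop <- vapply(fd_by_subject, function(v) mean(v > threshold_mm), numeric(1))
  out <- names(prop)[prop > frac]
  list(kept = setdiff(names(prop), out), excluded = out, proportion = prop)
}

#' Regress nuisance confounds out of a subject's time series
#'
#' Per voxel, replaces the series with the residuals of an OLS fit on the
#' confound columns plus an intercept. Residuals are orthogonal to every
#' confound column.
#'
#' @param ts A [subject_ts()].
#' @param confounds Frame x column numeric matrix (e.g. the generator's
#'   22-column set: 6 motion parameters, their derivatives, global signal,
#'   framewise displacement, 6 aCompCor components, polynomial trends of
#'   orders 1-2; the order-0 trend is the intercept added here).
#' @return The `subject_ts` with residual data.
#' @export
regress_nuisance <- function(ts, confounds) {
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != ncol(ts$data)) {
    stop("confound rows must match the frame count")
  }
  design <- cbind(intercept = 1, confounds)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dep <- colnames(design)[qrd$pivot[seq(qrd$rank + 1, ncol(design))]]
    stop("confound matrix is rank deficient; dependent columns: ",
         paste(dep, collapse = ", "))
  }
  res <- qr.resid(qrd, t(ts$data))
  ts$data <- t(res)
  ts
}

#' High-pass filter a subject's time series
#'
#' Removes fluctuations slower than `cutoff_hz` (and the mean) by projecting
#' out a discrete-cosine basis spanning all periods longer than
#' `1/cutoff_hz` — a regression-style filter that avoids edge ringing.
#'
#' @param ts A [subject_ts()].
#' @param cutoff_hz High-pass cutoff in Hz (must be below Nyquist).
#' @return The filtered `subject_ts`.
#' @export
highpass <- function(ts, cutoff_hz = 0.01) {
  n <- ncol(ts$data)
  nyquist <- 1 / (2 * ts$tr_s)
  if (cutoff_hz >= nyquist) {
    stop("cutoff (", cutoff_hz, " Hz) must be below the Nyquist frequency (",
         signif(nyquist, 4), " Hz)")
  }
  # DCT-II regressor k has frequency k / (2 * n * tr); keep k below cutoff
  k_max <- floor(2 * n * ts$tr_s * cutoff_hz)
  tt <- seq_len(n) - 0.5
  x <- t(ts$data)
  x <- sweep(x, 2, colMeans(x))           # remove DC
  if (k_max >= 1) {
    basis <- sapply(seq_len(k_max), function(k) cos(pi * k * tt / n))
    x <- qr.resid(qr(basis), x)
  }
  ts$data <- t(x)
  ts
}

#' Extract statement windows and z-score each statement
#'
#' Keeps the frames whose midpoints fall inside a statement interval
#' `[onset, onset + duration)`, z-scores every voxel within each statement
#' window separately (mean 0, SD 1; constant windows become zeros), and
#' concatenates the windows in schedule order. The narrative type of each
#' kept frame is recorded in the `frame_type` element of the result.
#'
#' @param ts A [subject_ts()].
#' @param schedule Data frame `onset_s`, `duration_s`, `type`.
#' @return The `subject_ts` restricted to statement frames, with elements
#'   `frame_type` (per-frame `"pro"`/`"anti"`) and `frame_statement`
#'   (statement index) added.
#' @export
extract_and_concatenate <- function(ts, schedule) {
  n <- ncol(ts$data)
  mid <- .frame_midpoints(n, ts$tr_s)
  if (max(schedule$onset_s + schedule$duration_s) > n * ts$tr_s + ts$tr_s / 2) {
    stop("schedule extends beyond the recording")
  }
  pieces <- vector("list", nrow(schedule))
  types <- character(0)
  stmt <- integer(0)
  for (s in seq_len(nrow(schedule))) {
    idx <- which(mid >= schedule$onset_s[s] &
                   mid < schedule$onset_s[s] + schedule$duration_s[s])
    if (length(idx) < 2) {
      stop("statement ", s, " covers fewer than 2 frames")
    }
    w <- ts$data[, idx, drop = FALSE]
    mu <- rowMeans(w)
    sd <- sqrt(rowSums((w - mu)^2) / (length(idx) - 1))
    w <- (w - mu) / ifelse(sd > 0, sd, Inf)   # constant voxels -> zeros
    pieces[[s]] <- w
    types <- c(types, rep(schedule$type[s], length(idx)))
    stmt <- c(stmt, rep(s, length(idx)))
  }
  ts$data <- do.call(cbind, pieces)
  ts$frame_type <- types
  ts$frame_statement <- stmt
  ts
}

#' Prepare one subject end to end
#'
#' Applies the preparation chain in its fixed order: nuisance regression,
#' high-pass filtering, then statement extraction with per-statement
#' z-scoring. (Motion exclusion happens at the cohort level before this.)
#'
#' @inheritParams regress_nuisance
#' @inheritParams highpass
#' @param schedule Statement schedule table.
#' @return Prepared `subject_ts` restricted to statement frames.
#' @export
prepare_subject <- function(ts, confounds, schedule, cutoff_hz = 0.01) {
  ts <- regress_nuisance(ts, confounds)
  ts <- highpass(ts, cutoff_hz = cutoff_hz)
  extract_and_concatenate(ts, schedule)
}
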