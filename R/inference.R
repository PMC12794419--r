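#' Sign-flip permutation test on per-subject maps
#'
#' Tests, per voxel, whether the mean across subjects is greater than zero
#' with a one-sample t statistic whose null distribution is built by
#' randomly flipping the sign of each subject's whole map. One flip vector
#' per permutation is applied to all voxels simultaneously, preserving the
#' spatial dependence of the null. The p-value uses the add-one estimator
#' `p = (1 + #\{null t >= observed t\}) / (1 + n_perm)`, so the smallest
#' attainable p is `1 / (1 + n_perm)`; ties count toward the numerator.
#' With 12 or fewer subjects all `2^n` flip vectors are enumerated instead
#' of sampled.
#'
#' @param values Subject x voxel matrix (e.g. `diff` from [grouped_isc()]).
#'   Voxels containing non-finite values or no across-subject variance are
#'   masked (`NA` p).
#' @param n_perm Number of permutations (default 10000, the conventional
#'   setting). Fewer than 100 triggers a warning.
#' @param seed Integer seed for the flip draws.
#' @param alternative `"greater"` (default: more positive than observed) or
#'   `"two.sided"`.
#' @return Object of class `"permutation_result"`: `t` (observed per-voxel
#'   t), `p`, `n_permutations`, `seed`, `exhaustive`, `flip_scheme`.
#' @export
signflip_permutation <- function(values, n_perm = 10000, seed = 1L,
                                 alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  values <- as.matrix(values)
  n <- nrow(values)
  if (n < 3) stop("need at least 3 subjects")
  if (n_perm < 100) warning("fewer than 100 permutations: p-values are coarse")

  keep <- apply(values, 2, function(v) all(is.finite(v))) &
    apply(values, 2, stats::var) > 0
  V <- ncol(values)
  t_obs <- rep(NA_real_, V)
  p <- rep(NA_real_, V)
  x <- values[, keep, drop = FALSE]
  tk <- .col_tstat(x)
  t_obs[keep] <- tk

  exhaustive <- n <= 12
  if (exhaustive) {
    flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    set.seed(seed)
    flips <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  }
  n_eff <- nrow(flips)

  ss <- colSums(x * x)                      # invariant under sign flips
  count <- numeric(ncol(x))
  thr <- if (alternative == "greater") tk else abs(tk)
  # ties count toward the numerator (conservative); tolerance so the
  # identity flip always ties its own observed statistic
  thr <- thr - 1e-8 * (1 + abs(thr))
  block <- 1000L
  for (start in seq(1, n_eff, by = block)) {
    idx <- start:min(start + block - 1, n_eff)
    m <- (flips[idx, , drop = FALSE] %*% x) / n
    v <- sweep(-n * m^2, 2, ss, `+`) / (n - 1)
    v[v < 0] <- 0
    tnull <- m / sqrt(v / n)
    if (alternative == "two.sided") tnull <- abs(tnull)
    count <- count + colSums(sweep(tnull, 2, thr, `>=`))
  }
  p[keep] <- (1 + count) / (1 + n_eff)
  if (exhaustive) {
    # the identity flip is part of the enumerated null and already ties the
    # observed statistic; drop the add-one to keep p <= 1 exact
    p[keep] <- count / n_eff
  }
  structure(list(t = t_obs, p = p, n_permutations = n_eff, seed = seed,
                 exhaustive = exhaustive,
                 flip_scheme = "i.i.d. +/-1 per subject, shared across voxels",
                 alternative = alternative),
            class = "permutation_result")
}

#' Two-stage adaptive FDR (Benjamini-Krieger-Yekutieli)
#'
#' Adaptive linear step-up control of the false discovery rate. Stage 1
#' runs Benjamini-Hochberg at level `q' = q / (1 + q)` and estimates the
#' number of true nulls as `m0 = m - r1` from the non-rejections; stage 2
#' re-runs the step-up at the adapted level `q' * m / m0`. The reported
#' q-values are the Benjamini-Hochberg adjusted p-values scaled by
#' `m0 / m * (1 + q_level)`, so `q <= q_level` reproduces the two-stage
#' rejection set exactly.
#'
#' @param p_values Numeric p-values in (0, 1]. `NA`s are carried through.
#' @param q_level Target FDR level.
#' @return Object of class `"fdr_result"`: `q` (adjusted values), `mask`
#'   (`q <= q_level`), `m0` (estimated true nulls), `q_level`.
#' @export
bky_fdr <- function(p_values, q_level = 0.05) {
  if (length(p_values) == 0) stop("empty p-value vector")
  ok <- !is.na(p_values)
  p <- p_values[ok]
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  m <- length(p)
  qp <- q_level / (1 + q_level)

  bh_reject <- function(pv, level) {
    o <- order(pv)
    thr <- level * seq_along(pv) / length(pv)
    passed <- which(pv[o] <= thr)
    k <- if (length(passed)) max(passed) else 0L
    rej <- logical(length(pv))
    if (k > 0) rej[o[seq_len(k)]] <- TRUE
    rej
  }

  r1 <- sum(bh_reject(p, qp))
  bh_q <- stats::p.adjust(p, method = "BH")
  if (r1 == 0) {
    m0 <- m
    mask <- rep(FALSE, m)
  } else if (r1 == m) {
    m0 <- 0
    mask <- rep(TRUE, m)
  } else {
    m0 <- m - r1
    mask <- bh_reject(p, qp * m / m0)
  }
  qv <- if (m0 == 0) rep(0, m) else pmin(1, bh_q * (m0 / m) * (1 + q_level))

  q_full <- mask_full <- rep(NA, length(p_values))
  q_full[ok] <- qv
  mask_full[ok] <- mask
  structure(list(q = as.numeric(q_full), mask = as.logical(mask_full),
                 m0 = m0, q_level = q_level),
            class = "fdr_result")
}

#' Permutation inference with FDR correction on polarization maps
#'
#' Composes [signflip_permutation()] on the per-subject difference maps (or
#' per-subject R maps of an [one_to_average_isc()] result) with [bky_fdr()]
#' on the resulting p-values.
#'
#' @param maps A `"polarization_maps"` or `"isc_map"` object, or a subject x
#'   voxel matrix.
#' @inheritParams signflip_permutation
#' @param q_level FDR level for the significance mask.
#' @return List with `permutation` (a `"permutation_result"`) and `fdr`
#'   (an `"fdr_result"`).
#' @export
run_inference <- function(maps, n_perm = 10000, seed = 1L, q_level = 0.05,
                          alternative = "greater") {
  values <- if (inherits(maps, "polarization_maps")) {
    maps$diff
  } else if (inherits(maps, "isc_map")) {
    maps$R
  } else {
    as.matrix(maps)
  }
  perm <- signflip_permutation(values, n_perm = n_perm, seed = seed,
                               alternative = alternative)
  fdr <- bky_fdr(perm$p, q_level = q_level)
  list(permutation = perm, fdr = fdr)
}
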