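# Shared fixtures and independent (naive) reference implementations used as
# oracles against the package's vectorized code paths.

# A small cohort configuration that keeps simulation-based tests fast.
small_config <- function(seed = 1, ...) {
  defaults <- list(
    n_per_group = 3, grid_shape = c(6, 6, 6), n_statements = 10,
    polarized_region_spec = list(list(center = c(2, 2, 2), radius = 1,
                                      type = "both")),
    common_region_spec = list(list(center = c(5, 5, 5), radius = 1)),
    seed = seed
  )
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# Group assignment straight from the generator's ground truth (tests only).
truth_assignment <- function(cohort) {
  data.frame(
    subject_id = cohort$subject_ids,
    group = ifelse(cohort$truth$group == "more", "more_supportive",
                   "less_supportive"),
    stringsAsFactors = FALSE
  )
}

# Naive triple-loop within/between-group ISC: builds every leave-one-out and
# other-group average series explicitly and calls cor().
naive_grouped_isc <- function(mats, assignment) {
  ids <- assignment$subject_id
  grp <- stats::setNames(assignment$group, ids)
  nv <- nrow(mats[[1]])
  within <- between <- matrix(NA_real_, length(ids), nv,
                              dimnames = list(ids, NULL))
  for (id in ids) {
    own <- setdiff(ids[grp == grp[id]], id)
    other <- ids[grp != grp[id]]
    for (v in seq_len(nv)) {
      ref_w <- rowMeans(sapply(own, function(j) mats[[j]][v, ]))
      ref_b <- rowMeans(sapply(other, function(j) mats[[j]][v, ]))
      within[id, v] <- stats::cor(mats[[id]][v, ], ref_w)
      between[id, v] <- stats::cor(mats[[id]][v, ], ref_b)
    }
  }
  list(within = within, between = between, diff = within - between)
}

# Naive one-to-average ISC with explicit leave-one-out averages.
naive_one_to_average <- function(mats) {
  ids <- names(mats)
  nv <- nrow(mats[[1]])
  R <- matrix(NA_real_, length(ids), nv, dimnames = list(ids, NULL))
  for (id in ids) {
    others <- setdiff(ids, id)
    for (v in seq_len(nv)) {
      ref <- rowMeans(sapply(others, function(j) mats[[j]][v, ]))
      R[id, v] <- stats::cor(mats[[id]][v, ], ref)
    }
  }
  R
}

# Step-by-step transliteration of the two-stage adaptive FDR procedure:
# stage 1 is linear step-up at q/(1+q), the true-null count is estimated from
# the non-rejections, stage 2 re-runs the step-up at the adapted level.
naive_bky_reject <- function(p, q = 0.05) {
  m <- length(p)
  step_up <- function(pv, level) {
    o <- order(pv)
    passed <- which(pv[o] <= level * seq_len(m) / m)
    rej <- rep(FALSE, m)
    if (length(passed)) rej[o[seq_len(max(passed))]] <- TRUE
    rej
  }
  qp <- q / (1 + q)
  r1 <- sum(step_up(p, qp))
  if (r1 == 0) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  step_up(p, qp * m / (m - r1))
}

# Exhaustive sign-flip null for a single voxel (vector of subject values).
naive_signflip_p <- function(values) {
  n <- length(values)
  tstat <- function(v) mean(v) / (stats::sd(v) / sqrt(n))
  t_obs <- tstat(values)
  flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  tnull <- apply(flips, 1, function(s) tstat(s * values))
  mean(tnull >= t_obs - 1e-12)
}

# Monte-Carlo power of a two-sided one-sample t test at effect size d.
mc_power_one_sample <- function(d, n, alpha = 0.05, n_rep = 20000) {
  x <- matrix(stats::rnorm(n_rep * n, mean = d), n_rep, n)
  m <- rowMeans(x)
  s <- sqrt(rowSums((x - m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  mean(abs(t) > stats::qt(1 - alpha / 2, n - 1))
}

# Monte-Carlo power of a two-sided two-sample pooled t test at effect size d.
mc_power_two_sample <- function(d, n1, n2, alpha = 0.05, n_rep = 20000) {
  x <- matrix(stats::rnorm(n_rep * n1, mean = d), n_rep, n1)
  y <- matrix(stats::rnorm(n_rep * n2), n_rep, n2)
  mx <- rowMeans(x); my <- rowMeans(y)
  sp <- sqrt((rowSums((x - mx)^2) + rowSums((y - my)^2)) / (n1 + n2 - 2))
  t <- (mx - my) / (sp * sqrt(1 / n1 + 1 / n2))
  mean(abs(t) > stats::qt(1 - alpha / 2, n1 + n2 - 2))
}

# Synthetic confound table of the generator's layout for a given length.
.make_confounds_for_test <- function(n_frames, tr = 1.26, seed = 99) {
  set.seed(seed)
  polarisc:::.make_confounds(n_frames, tr)
}

# Long-format ratings table for one or more subjects from a rating matrix
# (subjects x statements) and a type vector.
ratings_from_matrix <- function(mat, types) {
  do.call(rbind, lapply(seq_len(nrow(mat)), function(i) {
    data.frame(subject_id = sprintf("s%02d", i),
               statement_id = sprintf("st%02d", seq_along(types)),
               statement_type = types,
               rating = as.integer(mat[i, ]),
               stringsAsFactors = FALSE)
  }))
}

# Questionnaire response table from a subjects x items score matrix.
responses_from_matrix <- function(mat, item_ids) {
  do.call(rbind, lapply(seq_len(nrow(mat)), function(i) {
    data.frame(subject_id = sprintf("s%02d", i), item_id = item_ids,
               response = as.integer(mat[i, ]), stringsAsFactors = FALSE)
  }))
}
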