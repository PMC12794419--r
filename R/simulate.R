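#' Configuration for a synthetic listening-study cohort
#'
#' Builds and validates the parameter set for [generate_cohort()]. The
#' defaults emulate a two-group naturalistic-stimulus design: 40 subjects in
#' two latent attitude groups of 20, 44 spoken statements (22 pro- and 22
#' anti-immigration) of about 16.3 s each sampled at TR = 1.26 s, and a voxel
#' grid in which each voxel belongs to one of three classes:
#'
#' * `common` — signal shared by the whole cohort,
#' * `polarized` — signal shared only within a latent group (the planted
#'   "neural polarization"),
#' * `null` — subject-specific noise only.
#'
#' Per-voxel signals are variance-partitioned: a `common` voxel is
#' `sqrt(common_share) * c(t) + sqrt(noise_share) * e_i(t)` and a `polarized`
#' voxel `sqrt(group_share) * s_g(t) + sqrt(noise_share) * e_i(t)`, where
#' `c` and `s_g` are unit-variance smooth processes and `e_i` is AR(1)
#' subject noise. Shares must sum to 1 within each voxel class, which ties
#' `common_share` and `group_share` to the single `noise_share`.
#'
#' @param n_per_group Subjects per latent group (two groups).
#' @param grid_shape Integer length-3 voxel grid dimensions.
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @param tr_s Sampling interval (repetition time) in seconds.
#' @param n_statements Number of statements; half pro, half anti.
#' @param statement_mean_s,statement_sd_s Mean / SD of statement duration (s).
#' @param gap_range_s Length-2 range of the randomized inter-statement
#'   wash-out interval (s); the realized gap is uniform in this range.
#' @param pre_rating_s Fixed pause between statement offset and the rating
#'   prompt (s); added to every gap.
#' @param common_share,group_share,noise_share Variance fractions of the
#'   shared cohort component, the group-specific component, and subject
#'   noise. `common_share + noise_share` and `group_share + noise_share`
#'   must each equal 1 (to within 1e-12).
#' @param polarized_region_spec List of regions planted with group-specific
#'   signal; each element is `list(center = c(i, j, k), radius = r,
#'   type = "pro"|"anti"|"both")`. `type` restricts the group component to
#'   frames of that narrative type (noise elsewhere).
#' @param common_region_spec List of regions carrying the cohort-common
#'   component; each element `list(center, radius)`.
#' @param ar1_coef Lag-1 autocorrelation of the subject noise.
#' @param smooth_fwhm_s FWHM (s) of the Gaussian kernel that smooths the
#'   shared signals.
#' @param rating_group_means Named list `more` / `less`, each a named vector
#'   `c(pro = , anti = )` of mean agreement ratings per latent group.
#' @param rating_sd SD of the latent (pre-discretization) rating noise.
#' @param scale_loadings Default factor loading of questionnaire items on the
#'   latent attitude.
#' @param seed Integer RNG seed; a fixed seed reproduces the cohort exactly.
#'
#' @return A validated list of class `"simulation_config"`.
#' @seealso [generate_cohort()], [generate_fd_traces()]
#' @export
simulation_config <- function(n_per_group = 20,
                              grid_shape = c(12, 12, 12),
                              voxel_size_mm = 3,
                              tr_s = 1.26,
                              n_statements = 44,
                              statement_mean_s = 16.3,
                              statement_sd_s = 2.0,
                              gap_range_s = c(16, 17),
                              pre_rating_s = 1.5,
                              common_share = 0.3,
                              group_share = 0.3,
                              noise_share = 0.7,
                              polarized_region_spec = list(
                                list(center = c(4, 4, 4), radius = 2, type = "both")
                              ),
                              common_region_spec = list(
                                list(center = c(9, 9, 9), radius = 3)
                              ),
                              ar1_coef = 0.3,
                              smooth_fwhm_s = 6,
                              rating_group_means = list(
                                more = c(pro = 4.4, anti = 1.1),
                                less = c(pro = 3.8, anti = 2.2)
                              ),
                              rating_sd = 0.7,
                              scale_loadings = 0.7,
                              seed = 1L) {
  cfg <- list(
    n_per_group = as.integer(n_per_group), grid_shape = as.integer(grid_shape),
    voxel_size_mm = voxel_size_mm, tr_s = tr_s,
    n_statements = as.integer(n_statements),
    statement_mean_s = statement_mean_s, statement_sd_s = statement_sd_s,
    gap_range_s = gap_range_s, pre_rating_s = pre_rating_s,
    common_share = common_share, group_share = group_share,
    noise_share = noise_share,
    polarized_region_spec = polarized_region_spec,
    common_region_spec = common_region_spec,
    ar1_coef = ar1_coef, smooth_fwhm_s = smooth_fwhm_s,
    rating_group_means = rating_group_means, rating_sd = rating_sd,
    scale_loadings = scale_loadings, seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

#' @rdname simulation_config
#' @param config A `"simulation_config"` object.
#' @export
validate_simulation_config <- function(config) {
  with(config, {
    if (n_per_group < 2) stop("n_per_group must be at least 2")
    if (length(grid_shape) != 3 || any(grid_shape < 1)) {
      stop("grid_shape must be three positive integers")
    }
    if (tr_s <= 0 || voxel_size_mm <= 0) stop("tr_s and voxel_size_mm must be positive")
    if (n_statements < 2 || n_statements %% 2 != 0) {
      stop("n_statements must be a positive even count (half pro, half anti)")
    }
    if (statement_mean_s <= 0 || statement_sd_s < 0) {
      stop("statement durations must be positive")
    }
    shares <- c(common_share, group_share, noise_share)
    if (any(shares < 0) || any(shares > 1)) stop("variance shares must lie in [0, 1]")
    if (abs(common_share + noise_share - 1) > 1e-12) {
      stop("variance shares of the common voxel class do not sum to 1 ",
           "(common_share + noise_share = ", common_share + noise_share, ")")
    }
    if (abs(group_share + noise_share - 1) > 1e-12) {
      stop("variance shares of the polarized voxel class do not sum to 1 ",
           "(group_share + noise_share = ", group_share + noise_share, ")")
    }
    if (abs(ar1_coef) >= 1) stop("ar1_coef must lie in (-1, 1)")
    for (reg in polarized_region_spec) {
      if (!reg$type %in% c("pro", "anti", "both")) {
        stop("polarized region type must be 'pro', 'anti' or 'both'")
      }
      .check_region_in_grid(reg, grid_shape)
    }
    for (reg in common_region_spec) .check_region_in_grid(reg, grid_shape)
  })
  invisible(config)
}

.check_region_in_grid <- function(region, grid_shape) {
  ctr <- region$center
  if (length(ctr) != 3) stop("region center must have three coordinates")
  if (any(ctr - region$radius < 1) || any(ctr + region$radius > grid_shape)) {
    stop("region at center (", paste(ctr, collapse = ", "),
         ") with radius ", region$radius, " lies outside the voxel grid")
  }
  invisible(region)
}

# Type presentation order of the 44 statements (fixed across subjects in the
# emulated design, with at most two consecutive statements of the same type).
.canonical_type_order <- c(
  "pro", "anti", "anti", "pro", "pro", "anti", "anti", "pro", "pro", "anti",
  "pro", "anti", "anti", "pro", "anti", "pro", "anti", "pro", "anti", "pro",
  "pro", "anti", "pro", "anti", "anti", "pro", "pro", "anti", "pro", "anti",
  "pro", "anti", "pro", "anti", "anti", "pro", "anti", "pro", "anti", "pro",
  "anti", "pro", "pro", "anti"
)

# Draw a statement schedule: onsets, durations, types. Consumes RNG state.
.make_schedule <- function(config) {
  n <- config$n_statements
  if (n == length(.canonical_type_order)) {
    types <- .canonical_type_order
  } else {
    types <- sample(rep(c("pro", "anti"), n / 2))
  }
  dur <- stats::rnorm(n, config$statement_mean_s, config$statement_sd_s)
  dur <- pmax(dur, 4 * config$tr_s)  # keep every statement several frames long
  gap <- config$pre_rating_s +
    stats::runif(n, config$gap_range_s[1], config$gap_range_s[2])
  onset <- numeric(n)
  t0 <- 5  # lead-in before the first statement
  for (i in seq_len(n)) {
    onset[i] <- t0
    t0 <- t0 + dur[i] + gap[i]
  }
  data.frame(onset_s = onset, duration_s = dur, type = types,
             stringsAsFactors = FALSE)
}

# Unit-variance smooth process: white noise convolved with a Gaussian kernel.
.smooth_unit <- function(n_frames, tr_s, fwhm_s) {
  sigma <- fwhm_s / (2 * sqrt(2 * log(2))) / tr_s  # in frames
  half <- max(1L, ceiling(4 * sigma))
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  x <- stats::rnorm(n_frames + 2 * half)
  sm <- stats::convolve(x, rev(kern), type = "filter")  # length n_frames
  as.numeric(scale(sm))
}

# V x T matrix of unit-variance AR(1) noise.
.ar1_noise <- function(n_voxels, n_frames, phi) {
  e <- matrix(stats::rnorm(n_voxels * n_frames), n_voxels, n_frames)
  if (phi != 0) {
    sc <- sqrt(1 - phi^2)  # first column stays N(0,1): stationary start
    for (t in 2:n_frames) e[, t] <- phi * e[, t - 1] + sc * e[, t]
  }
  e
}

# Logical vector marking voxels inside a spherical region (voxel units).
.region_voxels <- function(ijk, center, radius) {
  d2 <- (ijk[, 1] - center[1])^2 + (ijk[, 2] - center[2])^2 +
    (ijk[, 3] - center[3])^2
  d2 <= radius^2
}

#' Generate a synthetic two-group cohort
#'
#' Draws a full synthetic data set with the statistical structure the
#' polarization analysis assumes: per-subject voxel-by-frame signal matrices,
#' a statement schedule, agreement ratings whose pro-minus-anti means
#' separate the two latent groups, multi-item Likert questionnaires loading
#' on a shared attitude factor, framewise-displacement traces, and nuisance
#' regressor tables. Ground-truth labels (latent group per subject, class
#' per voxel) are stored in `$truth` and are never consumed by the analysis
#' stages; they exist so recovery tests can be blinded.
#'
#' @param config A [simulation_config()].
#' @return An object of class `"synthetic_cohort"`: a list with elements
#'   `data` (per-subject voxel x frame matrices), `subject_ids`, `mask`
#'   (3D logical), `voxel_ijk`, `affine`, `tr_s`, `schedule`, `frame_type`
#'   (narrative label of each frame midpoint, `NA` between statements),
#'   `ratings`, `questionnaires` (`$responses`, `$definitions`), `fd`
#'   (frame x subject matrix), `confounds` (per-subject frame x 22 tables),
#'   and `truth`.
#' @export
generate_cohort <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  n_sub <- 2L * config$n_per_group
  grid <- config$grid_shape
  mask <- array(TRUE, dim = grid)
  ijk <- as.matrix(expand.grid(i = seq_len(grid[1]), j = seq_len(grid[2]),
                               k = seq_len(grid[3])))
  n_vox <- nrow(ijk)

  schedule <- .make_schedule(config)
  last_end <- max(schedule$onset_s + schedule$duration_s)
  n_frames <- as.integer(ceiling((last_end + 5) / config$tr_s))
  mid <- .frame_midpoints(n_frames, config$tr_s)
  frame_type <- rep(NA_character_, n_frames)
  for (s in seq_len(nrow(schedule))) {
    inside <- mid >= schedule$onset_s[s] &
      mid < schedule$onset_s[s] + schedule$duration_s[s]
    frame_type[inside] <- schedule$type[s]
  }

  # voxel classes
  voxel_class <- rep("null", n_vox)
  region_id <- rep(NA_integer_, n_vox)
  region_type <- rep(NA_character_, n_vox)
  for (r in seq_along(config$common_region_spec)) {
    reg <- config$common_region_spec[[r]]
    voxel_class[.region_voxels(ijk, reg$center, reg$radius)] <- "common"
  }
  for (r in seq_along(config$polarized_region_spec)) {
    reg <- config$polarized_region_spec[[r]]
    sel <- .region_voxels(ijk, reg$center, reg$radius)
    voxel_class[sel] <- "polarized"
    region_id[sel] <- r
    region_type[sel] <- reg$type
  }

  # shared processes
  c_t <- .smooth_unit(n_frames, config$tr_s, config$smooth_fwhm_s)
  s_g <- replicate(2, .smooth_unit(n_frames, config$tr_s, config$smooth_fwhm_s),
                   simplify = FALSE)
  type_frames <- list(
    pro = !is.na(frame_type) & frame_type == "pro",
    anti = !is.na(frame_type) & frame_type == "anti",
    both = rep(TRUE, n_frames)
  )

  group <- rep(c("more", "less"), each = config$n_per_group)
  subject_ids <- sprintf("s%02d", seq_len(n_sub))
  names(group) <- subject_ids

  common_vox <- voxel_class == "common"
  data <- vector("list", n_sub)
  names(data) <- subject_ids
  signal_vox <- voxel_class != "null"
  for (i in seq_len(n_sub)) {
    # null voxels carry pure unit-variance noise; signal classes downweight
    # their noise so the variance shares sum to one
    x <- .ar1_noise(n_vox, n_frames, config$ar1_coef)
    x[signal_vox, ] <- sqrt(config$noise_share) * x[signal_vox, ]
    if (any(common_vox) && config$common_share > 0) {
      x[common_vox, ] <- x[common_vox, ] +
        sqrt(config$common_share) * rep(c_t, each = sum(common_vox))
    }
    if (config$group_share > 0) {
      g <- if (group[i] == "more") 1L else 2L
      for (r in seq_along(config$polarized_region_spec)) {
        reg <- config$polarized_region_spec[[r]]
        sel <- which(region_id == r)
        if (!length(sel)) next
        comp <- s_g[[g]] * as.numeric(type_frames[[reg$type]])
        x[sel, ] <- x[sel, ] + sqrt(config$group_share) * rep(comp, each = length(sel))
      }
    }
    data[[i]] <- x
  }

  ratings <- .generate_ratings(config, subject_ids, group, schedule)
  questionnaires <- .generate_questionnaires(config, subject_ids, group)
  fd <- generate_fd_traces(config, frac_high = 0, threshold_mm = 0.5,
                           n_frames = n_frames)
  confounds <- lapply(seq_len(n_sub), function(i) {
    .make_confounds(n_frames, config$tr_s, global = colMeans(data[[i]]))
  })
  names(confounds) <- subject_ids

  structure(list(
    data = data, subject_ids = subject_ids, mask = mask, voxel_ijk = ijk,
    affine = .default_affine(grid, config$voxel_size_mm), tr_s = config$tr_s,
    schedule = schedule, frame_type = frame_type, ratings = ratings,
    questionnaires = questionnaires, fd = fd, confounds = confounds,
    truth = list(group = group, voxel_class = voxel_class,
                 region_id = region_id, region_type = region_type),
    config = config
  ), class = "synthetic_cohort")
}

# Ratings: discretized Gaussians around group/type means, clipped to 1..5.
.generate_ratings <- function(config, subject_ids, group, schedule) {
  n_st <- nrow(schedule)
  out <- vector("list", length(subject_ids))
  for (i in seq_along(subject_ids)) {
    mu <- config$rating_group_means[[group[i]]]
    raw <- stats::rnorm(n_st, mu[schedule$type], config$rating_sd)
    out[[i]] <- data.frame(
      subject_id = subject_ids[i],
      statement_id = sprintf("st%02d", seq_len(n_st)),
      statement_type = schedule$type,
      rating = as.integer(pmin(pmax(round(raw), 1), 5)),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Default questionnaire scale definitions
#'
#' The battery of explicit attitude scales the generator emulates: political
#' inclination, empathic and negative emotions, dehumanisation, feeling
#' thermometer, perceived warmth/competence, perceived threat, right-wing
#' authoritarianism (RWA), multiculturalism, resistance to change, group
#' superiority, and discriminatory workplace attitudes. Each definition
#' carries the item ids, the reverse-keyed subset, the Likert bounds, the
#' sign and size (in pooled-SD units) of the planted between-group shift,
#' and the item loading on the latent attitude factor.
#'
#' @param loading Default item loading on the latent attitude factor.
#' @return Named list of scale definitions (class `"scale_definition"` each).
#' @export
default_scale_definitions <- function(loading = 0.7) {
  spec <- list(
    political        = list(k = 1,  min = 1, max = 7,  shift = 0.4,  rev = integer(0)),
    empathic_emotions = list(k = 3, min = 1, max = 7,  shift = 0.6,  rev = integer(0)),
    negative_emotions = list(k = 5, min = 1, max = 7,  shift = -0.3, rev = integer(0)),
    dehumanisation   = list(k = 1,  min = 0, max = 10, shift = 0.2,  rev = integer(0)),
    feeling_thermometer = list(k = 1, min = 0, max = 10, shift = 0.5, rev = integer(0)),
    warmth           = list(k = 1,  min = 1, max = 5,  shift = 0.3,  rev = integer(0)),
    competence       = list(k = 1,  min = 1, max = 5,  shift = 1.1,  rev = integer(0)),
    perceived_threat = list(k = 4,  min = 1, max = 7,  shift = -0.5, rev = c(2L)),
    rwa              = list(k = 7,  min = 1, max = 7,  shift = -1.15, rev = c(3L, 6L)),
    multiculturalism = list(k = 10, min = 1, max = 7,  shift = 0.99, rev = c(2L, 7L)),
    resistance_to_change = list(k = 7, min = 1, max = 7, shift = -0.3, rev = c(4L)),
    group_superiority = list(k = 8, min = 1, max = 7,  shift = -0.5, rev = c(5L)),
    workplace        = list(k = 10, min = 1, max = 7,  shift = -0.99, rev = c(3L, 8L))
  )
  out <- lapply(names(spec), function(nm) {
    s <- spec[[nm]]
    items <- sprintf("%s_%02d", nm, seq_len(s$k))
    structure(list(
      scale_name = nm, item_ids = items,
      reverse_items = items[s$rev],
      range_min = s$min, range_max = s$max,
      group_shift_d = s$shift, loading = loading
    ), class = "scale_definition")
  })
  names(out) <- names(spec)
  out
}

#' Define a questionnaire scale
#'
#' @param scale_name Scale label.
#' @param item_ids Character vector of item identifiers.
#' @param reverse_items Subset of `item_ids` that are reverse-keyed.
#' @param range_min,range_max Integer Likert bounds (`min < max`).
#' @return A `"scale_definition"` object.
#' @export
scale_definition <- function(scale_name, item_ids, reverse_items = character(0),
                             range_min = 1, range_max = 7) {
  if (!all(reverse_items %in% item_ids)) {
    stop("reverse_items must be a subset of item_ids")
  }
  if (range_min >= range_max || range_min != round(range_min) ||
      range_max != round(range_max)) {
    stop("Likert bounds must be integers with range_min < range_max")
  }
  structure(list(scale_name = scale_name, item_ids = item_ids,
                 reverse_items = reverse_items, range_min = range_min,
                 range_max = range_max),
            class = "scale_definition")
}

# Questionnaire responses: items load on a latent attitude factor whose mean
# differs between the two latent groups by the scale's planted shift.
.generate_questionnaires <- function(config, subject_ids, group) {
  defs <- default_scale_definitions(config$scale_loadings)
  latent <- stats::rnorm(length(subject_ids))  # shared attitude factor noise
  rows <- list()
  for (d in defs) {
    mid <- (d$range_min + d$range_max) / 2
    span <- (d$range_max - d$range_min) / 6
    k <- length(d$item_ids)
    # calibrate the latent group shift so the *scale score* (item mean)
    # carries approximately the planted Cohen's d: averaging k items shrinks
    # the unique-noise variance but not the shared-factor variance
    sd_score <- sqrt(d$loading^2 * 0.25 + (1 - d$loading^2) / k)
    mu_half <- d$group_shift_d * sd_score / (2 * d$loading)
    mu <- ifelse(group == "more", mu_half, -mu_half)
    for (it in d$item_ids) {
      z <- d$loading * (mu + latent * 0.5) +
        sqrt(max(0, 1 - d$loading^2)) * stats::rnorm(length(subject_ids))
      v <- round(mid + span * 1.8 * z)
      v <- pmin(pmax(v, d$range_min), d$range_max)
      if (it %in% d$reverse_items) v <- d$range_min + d$range_max - v
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = subject_ids, item_id = it, response = as.integer(v),
        stringsAsFactors = FALSE
      )
    }
  }
  list(responses = do.call(rbind, rows), definitions = defs)
}

#' Generate framewise-displacement traces
#'
#' Produces a frame-by-subject matrix of framewise displacement (FD, mm).
#' Subjects listed in `high_subjects` get exactly `round(frac_high *
#' n_frames)` frames above `threshold_mm` (so their above-threshold
#' proportion equals `frac_high`); all other subjects stay strictly below
#' the threshold. Used to exercise the strictly-greater-than motion
#' exclusion rule.
#'
#' @param config A [simulation_config()].
#' @param frac_high Proportion of high-motion frames for flagged subjects.
#' @param threshold_mm FD threshold in mm (non-negative).
#' @param high_subjects Indices of subjects to flag.
#' @param n_frames Optional frame count; derived from the configured
#'   schedule when omitted.
#' @return Numeric matrix, `n_frames` rows by `2 * n_per_group` columns.
#' @export
generate_fd_traces <- function(config, frac_high = 0, threshold_mm = 0.5,
                               high_subjects = integer(0), n_frames = NULL) {
  if (frac_high < 0 || frac_high > 1) stop("frac_high must lie in [0, 1]")
  if (threshold_mm < 0) stop("threshold_mm must be non-negative")
  if (is.null(n_frames)) {
    set.seed(config$seed)
    schedule <- .make_schedule(config)
    n_frames <- as.integer(ceiling((max(schedule$onset_s + schedule$duration_s) + 5) /
                                     config$tr_s))
  }
  n_sub <- 2L * config$n_per_group
  fd <- matrix(stats::runif(n_frames * n_sub, 0.02, 0.8 * max(threshold_mm, 1e-3)),
               n_frames, n_sub)
  n_high <- round(frac_high * n_frames)
  for (s in high_subjects) {
    idx <- sample.int(n_frames, n_high)
    fd[idx, s] <- stats::runif(n_high, threshold_mm * 1.2 + 1e-6,
                               threshold_mm * 2 + 1e-3)
  }
  colnames(fd) <- sprintf("s%02d", seq_len(n_sub))
  fd
}

# fMRIPrep-style nuisance table: 6 motion parameters, their backward-difference
# derivatives, global signal, FD, 6 aCompCor components, and polynomial trend
# columns of orders 1-2 (the order-0 term is the regression intercept).
.make_confounds <- function(n_frames, tr_s, global = NULL) {
  motion <- sapply(1:6, function(j) cumsum(stats::rnorm(n_frames, 0, 0.02)))
  deriv <- rbind(0, diff(motion))
  fd <- c(0, rowSums(abs(diff(motion))))
  compcor <- sapply(1:6, function(j) .smooth_unit(n_frames, tr_s, 4))
  if (is.null(global)) global <- stats::rnorm(n_frames, 0, 0.1)
  tt <- seq_len(n_frames) / n_frames
  trend <- cbind(tt - mean(tt), (tt - mean(tt))^2 - mean((tt - mean(tt))^2))
  cf <- cbind(motion, deriv, global, fd, compcor, trend)
  colnames(cf) <- c(
    paste0("motion_", 1:6), paste0("motion_deriv_", 1:6),
    "global_signal", "framewise_displacement",
    paste0("a_comp_cor_", 1:6), "trend_1", "trend_2"
  )
  cf
}

#' Write a synthetic cohort to disk
#'
#' Writes per-subject NIfTI-1 volumes plus a mask volume, the schedule as a
#' tab-separated table (`onset_s`, `duration_s`, `type`), ratings and
#' questionnaire responses as CSV, FD traces as a one-column-per-subject
#' CSV, and per-subject confound TSVs.
#'
#' @param cohort A `"synthetic_cohort"`.
#' @param dir Output directory (created if needed).
#' @param volumes Write the (large) 4D volumes? Tables and the mask are
#'   always written.
#' @return Invisibly, the vector of written file paths.
#' @export
write_cohort <- function(cohort, dir, volumes = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  add <- function(p) paths <<- c(paths, p)

  mask_img <- RNifti::asNifti(array(as.integer(cohort$mask), dim(cohort$mask)))
  mask_path <- file.path(dir, "mask.nii")
  RNifti::writeNifti(mask_img, mask_path)
  add(mask_path)

  if (volumes) {
    for (id in cohort$subject_ids) {
      vol <- array(0, c(dim(cohort$mask), ncol(cohort$data[[id]])))
      mvec <- which(cohort$mask)
      for (t in seq_len(ncol(cohort$data[[id]]))) {
        slab <- array(0, dim(cohort$mask))
        slab[mvec] <- cohort$data[[id]][, t]
        vol[, , , t] <- slab
      }
      p <- file.path(dir, paste0(id, "_bold.nii"))
      img <- RNifti::asNifti(vol)
      RNifti::pixdim(img) <- c(rep(cohort$config$voxel_size_mm, 3), cohort$tr_s)
      RNifti::writeNifti(img, p)
      add(p)
    }
  }

  p <- file.path(dir, "schedule.tsv")
  utils::write.table(cohort$schedule, p, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  add(p)
  p <- file.path(dir, "ratings.csv")
  utils::write.csv(cohort$ratings, p, row.names = FALSE)
  add(p)
  p <- file.path(dir, "questionnaires.csv")
  utils::write.csv(cohort$questionnaires$responses, p, row.names = FALSE)
  add(p)
  p <- file.path(dir, "fd.csv")
  utils::write.csv(as.data.frame(cohort$fd), p, row.names = FALSE)
  add(p)
  for (id in cohort$subject_ids) {
    p <- file.path(dir, paste0(id, "_confounds.tsv"))
    utils::write.table(as.data.frame(cohort$confounds[[id]]), p, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    add(p)
  }
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
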