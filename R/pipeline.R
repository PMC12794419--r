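#' Build a full-run configuration
#'
#' Collects every knob of an end-to-end run — simulation parameters,
#' preparation settings, inference settings, peak extraction parameters —
#' into one serializable list. Reruns with an identical configuration (and
#' therefore identical seed) produce identical outputs.
#'
#' @param seed Master seed; every random stage derives its seed from it.
#' @param n_perm Permutations for the sign-flip test.
#' @param q_level FDR level.
#' @param min_distance_mm Minimum peak separation.
#' @param cutoff_hz High-pass cutoff.
#' @param motion_frac,motion_threshold_mm Motion exclusion rule.
#' @param simulation Named list of [simulation_config()] arguments.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, n_perm = 10000, q_level = 0.05,
                       min_distance_mm = 10, cutoff_hz = 0.01,
                       motion_frac = 0.25, motion_threshold_mm = 0.5,
                       simulation = list()) {
  structure(list(seed = as.integer(seed), n_perm = n_perm, q_level = q_level,
                 min_distance_mm = min_distance_mm, cutoff_hz = cutoff_hz,
                 motion_frac = motion_frac,
                 motion_threshold_mm = motion_threshold_mm,
                 simulation = simulation),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_run_config()] returns a `"run_config"`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(run_config, raw[setdiff(names(raw), "simulation")])
  cfg$simulation <- raw$simulation %||% list()
  cfg
}

#' @rdname read_run_config
#' @param config A `"run_config"`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Derive a stage seed from the master seed (kept well below 2^31).
.stage_seed <- function(seed, offset) (as.integer(seed) * 1009L + offset) %% 2000000011L

#' Run the full polarization pipeline
#'
#' Orchestrates simulate -> motion exclusion -> nuisance regression ->
#' high-pass -> statement extraction -> behavioral scoring and group split
#' -> within/between-group ISC for all three narrative selections (all,
#' pro, anti) -> sign-flip permutation inference with two-stage FDR ->
#' peak extraction and peak-level statistics -> neural-behavioral
#' correlations. Every artifact is written under `out_dir` and listed, with
#' its md5 checksum, in `manifest.json`. Ground-truth labels from the
#' generator are never consulted.
#'
#' @param config A `"run_config"` (or path to its YAML).
#' @param out_dir Output directory.
#' @return Invisibly, the manifest (also written as JSON): configuration
#'   hash, artifact table, and summary statistics.
#' @export
run_full <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  emit <- function(p) {
    artifacts <<- c(artifacts, p)
    p
  }
  fail <- function(stage, e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  cfg_path <- emit(file.path(out_dir, "config.yaml"))
  write_run_config(config, cfg_path)

  # -- simulate ---------------------------------------------------------
  cohort <- tryCatch({
    sim_args <- config$simulation
    sim_args$seed <- sim_args$seed %||% .stage_seed(config$seed, 1L)
    if (!is.null(sim_args$grid_shape)) {
      sim_args$grid_shape <- as.integer(unlist(sim_args$grid_shape))
    }
    generate_cohort(do.call(simulation_config, sim_args))
  }, error = function(e) fail("simulate", e))

  # -- motion exclusion -------------------------------------------------
  excl <- tryCatch(
    exclude_by_motion(cohort$fd, frac = config$motion_frac,
                      threshold_mm = config$motion_threshold_mm),
    error = function(e) fail("exclude", e))
  kept <- intersect(cohort$subject_ids, excl$kept)
  utils::write.csv(
    data.frame(subject_id = names(excl$proportion),
               prop_high_fd = excl$proportion,
               excluded = names(excl$proportion) %in% excl$excluded),
    emit(file.path(out_dir, "motion_exclusion.csv")), row.names = FALSE)

  # -- prep -------------------------------------------------------------
  prepped <- tryCatch({
    out <- lapply(kept, function(id) {
      ts <- subject_ts(id, cohort$data[[id]], cohort$voxel_ijk,
                       cohort$affine, cohort$tr_s)
      prepare_subject(ts, cohort$confounds[[id]], cohort$schedule,
                      cutoff_hz = config$cutoff_hz)
    })
    names(out) <- kept
    out
  }, error = function(e) fail("prep", e))
  frame_type <- prepped[[1]]$frame_type

  # -- behavioral -------------------------------------------------------
  behav <- tryCatch({
    ratings <- cohort$ratings[cohort$ratings$subject_id %in% kept, ]
    ias <- compute_ias(ratings)
    assignment <- median_split(ias)
    defs <- cohort$questionnaires$definitions
    resp <- cohort$questionnaires$responses
    resp <- resp[resp$subject_id %in% kept, ]
    scores <- lapply(defs, function(d) score_scale(resp, d))
    names(scores) <- names(defs)
    alphas <- vapply(defs[vapply(defs, function(d) length(d$item_ids) > 1,
                                 logical(1))],
                     function(d) cronbach_alpha(resp, d), numeric(1))
    comparisons <- compare_groups_on_scales(scores, assignment)
    correlations <- correlate_with_ias(
      scores[setdiff(names(scores), "political")], ias)
    political <- correlate_with_ias(scores["political"], ias, fdr = FALSE)
    mat <- do.call(cbind, lapply(scores, function(s) s[ias$subject_id]))
    rownames(mat) <- ias$subject_id
    # the joint regression needs more subjects than predictors + 1
    regression <- if (nrow(mat) > ncol(mat) + 1) {
      regress_ias_on_scales(mat, ias)
    } else {
      NULL
    }
    list(ias = ias, assignment = assignment, scores = scores,
         alphas = alphas, comparisons = comparisons,
         correlations = correlations, political = political,
         regression = regression)
  }, error = function(e) fail("behavioral", e))

  utils::write.csv(behav$ias, emit(file.path(out_dir, "ias.csv")),
                   row.names = FALSE)
  utils::write.csv(behav$assignment, emit(file.path(out_dir, "groups.csv")),
                   row.names = FALSE)
  utils::write.csv(behav$comparisons,
                   emit(file.path(out_dir, "scale_comparisons.csv")),
                   row.names = FALSE)
  utils::write.csv(behav$correlations,
                   emit(file.path(out_dir, "scale_ias_correlations.csv")),
                   row.names = FALSE)

  # -- ISC + inference + peaks per narrative ----------------------------
  narratives <- c("all", "pro", "anti")
  maps <- list()
  inference <- list()
  peak_tables <- list()
  peak_scores <- list()
  for (nt in narratives) {
    maps[[nt]] <- tryCatch(
      narrative_restricted_isc(prepped, behav$assignment, frame_type, nt),
      error = function(e) fail(paste0("isc_", nt), e))
    inference[[nt]] <- tryCatch(
      run_inference(maps[[nt]], n_perm = config$n_perm,
                    seed = .stage_seed(config$seed, 2L + match(nt, narratives)),
                    q_level = config$q_level),
      error = function(e) fail(paste0("inference_", nt), e))
    write_map(maps[[nt]]$average_diff, cohort$mask, cohort$affine,
              cohort$voxel_ijk,
              file.path(out_dir, paste0("avg_diff_", nt)))
    emit(file.path(out_dir, paste0("avg_diff_", nt, ".nii")))
    emit(file.path(out_dir, paste0("avg_diff_", nt, ".tsv")))
    write_map(inference[[nt]]$permutation$p, cohort$mask, cohort$affine,
              cohort$voxel_ijk, file.path(out_dir, paste0("p_", nt)))
    emit(file.path(out_dir, paste0("p_", nt, ".nii")))
    emit(file.path(out_dir, paste0("p_", nt, ".tsv")))
    write_map(as.numeric(inference[[nt]]$fdr$q), cohort$mask, cohort$affine,
              cohort$voxel_ijk, file.path(out_dir, paste0("q_", nt)))
    emit(file.path(out_dir, paste0("q_", nt, ".nii")))
    emit(file.path(out_dir, paste0("q_", nt, ".tsv")))

    sig <- inference[[nt]]$fdr$mask
    sig[is.na(sig)] <- FALSE
    pk <- tryCatch(
      extract_peaks(maps[[nt]]$average_diff, sig, cohort$voxel_ijk,
                    cohort$affine, min_distance_mm = config$min_distance_mm,
                    p_values = inference[[nt]]$permutation$p, narrative = nt),
      error = function(e) fail(paste0("peaks_", nt), e))
    peak_tables[[nt]] <- pk
    utils::write.table(
      as.data.frame(pk),
      emit(file.path(out_dir, paste0("peaks_", nt, ".tsv"))),
      sep = "\t", row.names = FALSE, quote = FALSE)
    if (nrow(pk) > 0) {
      ps <- score_peaks(maps[[nt]], pk, behav$assignment)
      peak_scores[[nt]] <- ps
      utils::write.csv(
        as.data.frame(ps),
        emit(file.path(out_dir, paste0("peak_scores_", nt, ".csv"))),
        row.names = FALSE)
    }
  }

  # -- peak-level statistics -------------------------------------------
  reports <- list()
  for (nt in narratives) {
    if (!is.null(peak_scores[[nt]])) {
      reports[[paste0("peak_tests_", nt)]] <-
        peak_level_tests(peak_scores[[nt]])
    }
  }
  if (!is.null(peak_scores[["pro"]]) && !is.null(peak_scores[["anti"]])) {
    both <- rbind(
      transform(peak_scores[["pro"]],
                peak = paste0("pro_", peak)),
      transform(peak_scores[["anti"]],
                peak = paste0("anti_", peak)))
    class(both) <- class(peak_scores[["pro"]])
    reports$pooled_pro_anti <- pooled_peak_contrast(both)[
      c("t", "df", "p", "cohens_d", "mean_more", "ci_more",
        "mean_less", "ci_less")]
    reports$between_group_sign <- between_group_sign_comparison(
      peak_scores[["anti"]], peak_scores[["pro"]])
    pooled <- tapply(both$diff, both$subject_id, mean)
    ias_vec <- stats::setNames(behav$ias$ias, behav$ias$subject_id)
    reports$neural_behavioral <- correlate_peaks_with_behavior(
      list(pooled_peaks = pooled),
      c(list(ias = ias_vec), behav$scores))
  }
  if (!is.null(behav$regression)) {
    reports$behavioral_regression <- behav$regression[
      c("F", "df1", "df2", "p", "adj_r_squared")]
  }
  reports$cronbach_alpha <- as.list(behav$alphas)

  json_path <- emit(file.path(out_dir, "reports.json"))
  jsonlite::write_json(
    lapply(reports, function(r) if (is.data.frame(r)) r else r),
    json_path, auto_unbox = TRUE, digits = 10, pretty = TRUE, force = TRUE)

  # -- manifest ---------------------------------------------------------
  sums <- tools::md5sum(artifacts)
  manifest <- list(
    package_version = as.character(utils::packageVersion("polarisc")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_subjects_kept = length(kept),
    n_frames_concatenated = ncol(prepped[[1]]$data),
    artifacts = data.frame(path = basename(artifacts),
                           md5 = unname(sums),
                           stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(manifest)
}

#' Demo run configuration
#'
#' A scaled-down configuration (two groups of 6, an 8x8x8 grid, 500
#' permutations) that exercises every pipeline stage in well under a
#' minute.
#'
#' @param seed Master seed.
#' @return A `"run_config"`.
#' @export
demo_run_config <- function(seed = 1L) {
  run_config(
    seed = seed, n_perm = 500,
    simulation = list(
      n_per_group = 6, grid_shape = c(8, 8, 8), n_statements = 20,
      polarized_region_spec = list(
        list(center = c(3, 3, 3), radius = 1.5, type = "both")),
      common_region_spec = list(list(center = c(6, 6, 6), radius = 1.5))
    )
  )
}
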