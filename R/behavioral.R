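#' Compute the Immigration Attitude Score (IAS)
#'
#' For each subject, the IAS is the mean agreement rating over the
#' pro-immigration statements minus the mean over the anti-immigration
#' statements, giving a scale from -4 (strongly oppose) to +4 (strongly
#' support).
#'
#' @param ratings Data frame with columns `subject_id`, `statement_id`,
#'   `statement_type` (`"pro"`/`"anti"`) and integer `rating` in 1..5. Every
#'   subject must rate every statement exactly once.
#' @return Data frame with one row per subject: `subject_id`, `mean_pro`,
#'   `mean_anti`, `ias`.
#' @export
compute_ias <- function(ratings) {
  req <- c("subject_id", "statement_id", "statement_type", "rating")
  if (!all(req %in% names(ratings))) {
    stop("ratings must have columns ", paste(req, collapse = ", "))
  }
  if (anyNA(ratings$rating) || !all(ratings$rating %in% 1:5)) {
    stop("ratings must be integers in 1..5 with no missing values")
  }
  if (!all(ratings$statement_type %in% c("pro", "anti"))) {
    stop("statement_type must be 'pro' or 'anti'")
  }
  tab <- table(ratings$subject_id, ratings$statement_id)
  if (any(tab != 1)) {
    stop("each subject must rate every statement exactly once")
  }
  mp <- tapply(ratings$rating[ratings$statement_type == "pro"],
               ratings$subject_id[ratings$statement_type == "pro"], mean)
  ma <- tapply(ratings$rating[ratings$statement_type == "anti"],
               ratings$subject_id[ratings$statement_type == "anti"], mean)
  ids <- sort(unique(ratings$subject_id))
  data.frame(subject_id = ids,
             mean_pro = as.numeric(mp[ids]),
             mean_anti = as.numeric(ma[ids]),
             ias = as.numeric(mp[ids] - ma[ids]),
             stringsAsFactors = FALSE)
}

#' Median split of subjects on the IAS
#'
#' Partitions subjects at the sample median of their attitude scores:
#' subjects above the median become `more_supportive`, subjects below it
#' `less_supportive`. Subjects exactly at the median are assigned in
#' ascending subject-id order so the group sizes come out
#' floor(n/2) / ceiling(n/2); with all ties at the median this reduces to
#' filling the less-supportive group first.
#'
#' @param scores Data frame with `subject_id` and `ias` (e.g. from
#'   [compute_ias()]).
#' @return Data frame `subject_id`, `ias`, `group`
#'   (`"more_supportive"`/`"less_supportive"`), plus attribute
#'   `split_value` (the median IAS).
#' @export
median_split <- function(scores) {
  if (nrow(scores) < 2) stop("median split needs at least 2 subjects")
  if (length(unique(scores$ias)) == 1) {
    stop("all scores identical: the median split is undefined")
  }
  ord <- order(scores$ias, scores$subject_id)
  n <- nrow(scores)
  n_less <- ceiling(n / 2)
  group <- rep("more_supportive", n)
  group[ord[seq_len(n_less)]] <- "less_supportive"
  out <- data.frame(subject_id = scores$subject_id, ias = scores$ias,
                    group = group, stringsAsFactors = FALSE)
  attr(out, "split_value") <- stats::median(scores$ias)
  out
}

#' Score a multi-item Likert scale
#'
#' Reverse-keyed items are reflected (`v -> range_min + range_max - v`) and
#' the scale score is the mean over items.
#'
#' @param responses Data frame `subject_id`, `item_id`, `response`.
#' @param definition A [scale_definition()].
#' @return Named numeric vector of per-subject scores.
#' @export
score_scale <- function(responses, definition) {
  d <- definition
  resp <- responses[responses$item_id %in% d$item_ids, , drop = FALSE]
  if (any(resp$response < d$range_min | resp$response > d$range_max)) {
    stop("responses outside the declared Likert bounds [", d$range_min, ", ",
         d$range_max, "] for scale ", d$scale_name)
  }
  tab <- table(resp$subject_id, factor(resp$item_id, levels = d$item_ids))
  if (any(tab != 1)) stop("every subject must answer every item exactly once")
  rev <- resp$item_id %in% d$reverse_items
  resp$response[rev] <- d$range_min + d$range_max - resp$response[rev]
  out <- tapply(resp$response, resp$subject_id, mean)
  out[sort(names(out))]
}

#' Cronbach's alpha for a multi-item scale
#'
#' `alpha = k/(k-1) * (1 - sum of item variances / variance of the item
#' sum)`, with sample (n-1) variances and reverse-keyed items reflected
#' first.
#'
#' @inheritParams score_scale
#' @return Scalar alpha.
#' @export
cronbach_alpha <- function(responses, definition) {
  d <- definition
  k <- length(d$item_ids)
  if (k < 2) stop("Cronbach's alpha needs at least 2 items")
  resp <- responses[responses$item_id %in% d$item_ids, , drop = FALSE]
  rev <- resp$item_id %in% d$reverse_items
  resp$response[rev] <- d$range_min + d$range_max - resp$response[rev]
  wide <- stats::reshape(resp[, c("subject_id", "item_id", "response")],
                         idvar = "subject_id", timevar = "item_id",
                         direction = "wide")
  m <- as.matrix(wide[, -1, drop = FALSE])
  if (nrow(m) < 2) stop("Cronbach's alpha needs at least 2 subjects")
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) stop("zero variance of the item sum")
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

#' Cohen's d from a two-sample t statistic
#'
#' `d = t * sqrt(1/n1 + 1/n2)`, the convention under which printed (t, d)
#' pairs for equal groups of 20 round-trip exactly.
#'
#' @param t t statistic. @param n1,n2 Group sizes (each >= 2).
#' @return Cohen's d.
#' @export
cohens_d_from_t <- function(t, n1, n2) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be at least 2")
  t * sqrt(1 / n1 + 1 / n2)
}

#' Minimal detectable effect size at a target power
#'
#' Smallest Cohen's d at which a two-sided t test attains the requested
#' power, solved from the exact noncentral t power function.
#'
#' @param n1 Sample size (per group for `design = "two_sample"`).
#' @param n2 Second group size; defaults to `n1` for two-sample designs.
#' @param alpha Two-sided significance level.
#' @param power Target power in (0, 1); must exceed `alpha`.
#' @param design `"one_sample"` or `"two_sample"`.
#' @return Minimal detectable Cohen's d.
#' @export
minimal_detectable_effect <- function(n1, n2 = NULL, alpha = 0.05,
                                      power = 0.80,
                                      design = c("one_sample", "two_sample")) {
  design <- match.arg(design)
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("alpha and power must lie in (0, 1)")
  }
  if (power <= alpha) stop("infeasible: power must exceed alpha")
  if (design == "one_sample") {
    res <- stats::power.t.test(n = n1, power = power, sig.level = alpha,
                               type = "one.sample", alternative = "two.sided")
    return(res$delta)
  }
  n2 <- n2 %||% n1
  if (n1 == n2) {
    res <- stats::power.t.test(n = n1, power = power, sig.level = alpha,
                               type = "two.sample", alternative = "two.sided")
    return(res$delta)
  }
  # unequal groups: solve the noncentral-t power equation directly
  df <- n1 + n2 - 2
  ncp_of_d <- function(d) d / sqrt(1 / n1 + 1 / n2)
  pow <- function(d) {
    q <- stats::qt(1 - alpha / 2, df)
    ncp <- ncp_of_d(d)
    stats::pt(q, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-q, df, ncp = ncp)
  }
  stats::uniroot(function(d) pow(d) - power, c(1e-6, 10), tol = 1e-9)$root
}

#' Compare the two groups on each explicit scale
#'
#' Independent two-sample Student t tests (pooled variance, df = n1+n2-2)
#' per scale, Cohen's d from the t statistic, and q-values from the
#' two-stage adaptive FDR procedure over the family of scales.
#'
#' @param scores_by_scale Named list (or data frame) of per-subject scale
#'   scores; each element a named numeric vector keyed by `subject_id`.
#' @param assignment Group assignment from [median_split()].
#' @param q_level FDR level for the scale family.
#' @return Data frame with one row per scale: `scale`, `t`, `df`, `p`, `q`,
#'   `cohens_d`, `ci_lo`, `ci_hi` (95% CI of the mean difference).
#' @export
compare_groups_on_scales <- function(scores_by_scale, assignment,
                                     q_level = 0.05) {
  groups <- split(assignment$subject_id, assignment$group)
  if (length(groups) != 2 || any(lengths(groups) < 2)) {
    stop("need two groups with at least 2 subjects each")
  }
  g1 <- groups[["more_supportive"]]
  g2 <- groups[["less_supportive"]]
  rows <- lapply(names(scores_by_scale), function(nm) {
    x <- scores_by_scale[[nm]]
    a <- x[as.character(g1)]
    b <- x[as.character(g2)]
    if (stats::var(a) + stats::var(b) == 0) {
      stop("zero pooled variance for scale ", nm)
    }
    tt <- stats::t.test(a, b, var.equal = TRUE)
    data.frame(scale = nm, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               cohens_d = cohens_d_from_t(unname(tt$statistic),
                                          length(a), length(b)),
               ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bky_fdr(.safe_p(out$p), q_level = q_level)$q
  out[, c("scale", "t", "df", "p", "q", "cohens_d", "ci_lo", "ci_hi")]
}

#' Correlate explicit scale scores with the IAS
#'
#' Pearson or Spearman correlation per scale with two-sided p-values, plus
#' two-stage adaptive FDR q-values over the family of scales.
#'
#' @param scale_scores Named list of per-subject score vectors (named by
#'   subject id).
#' @param ias Data frame `subject_id`, `ias` (e.g. [compute_ias()] output).
#' @param method `"pearson"` or `"spearman"`.
#' @param q_level FDR level.
#' @param fdr Apply the FDR correction? Set `FALSE` for measures reported
#'   uncorrected.
#' @return Data frame `scale`, `r`, `p`, and `q` when `fdr` is `TRUE`.
#' @export
correlate_with_ias <- function(scale_scores, ias,
                               method = c("pearson", "spearman"),
                               q_level = 0.05, fdr = TRUE) {
  method <- match.arg(method)
  y <- ias$ias
  names(y) <- ias$subject_id
  rows <- lapply(names(scale_scores), function(nm) {
    x <- scale_scores[[nm]]
    ids <- intersect(names(x), names(y))
    if (length(ids) < 3) stop("need at least 3 paired observations")
    if (stats::var(x[ids]) == 0 || stats::var(y[ids]) == 0) {
      stop("zero variance in ", nm, " or in the IAS")
    }
    ct <- suppressWarnings(stats::cor.test(x[ids], y[ids], method = method))
    data.frame(scale = nm, r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (fdr) out$q <- bky_fdr(.safe_p(out$p), q_level = q_level)$q
  out
}

#' Regress the IAS on the explicit scale scores
#'
#' Ordinary least squares of the IAS on all scale scores jointly, with the
#' overall F test and adjusted R-squared.
#'
#' @param scale_matrix Numeric matrix or data frame, subjects x scales, row
#'   names = subject ids.
#' @param ias Data frame `subject_id`, `ias`.
#' @return List with `fit` (the `lm`), `F`, `df1`, `df2`, `p`,
#'   `adj_r_squared`, `coefficients`.
#' @export
regress_ias_on_scales <- function(scale_matrix, ias) {
  x <- as.matrix(scale_matrix)
  if (is.null(rownames(x))) stop("scale_matrix needs subject ids as row names")
  y <- ias$ias[match(rownames(x), ias$subject_id)]
  if (anyNA(y)) stop("scale_matrix rows do not match the IAS subjects")
  if (nrow(x) <= ncol(x) + 1) {
    stop("need more subjects than predictors + 1")
  }
  qrx <- qr(cbind(1, x))
  if (qrx$rank < ncol(x) + 1) {
    dep <- colnames(x)[qrx$pivot[seq(qrx$rank + 1, ncol(x) + 1)] - 1]
    stop("rank-deficient design; collinear columns: ",
         paste(dep, collapse = ", "))
  }
  df <- data.frame(ias = y, x, check.names = TRUE)
  fit <- stats::lm(ias ~ ., data = df)
  sm <- summary(fit)
  list(fit = fit,
       F = unname(sm$fstatistic["value"]),
       df1 = unname(sm$fstatistic["numdf"]),
       df2 = unname(sm$fstatistic["dendf"]),
       p = stats::pf(sm$fstatistic["value"], sm$fstatistic["numdf"],
                     sm$fstatistic["dendf"], lower.tail = FALSE)[[1]],
       adj_r_squared = sm$adj.r.squared,
       coefficients = stats::coef(fit))
}
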