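#' Per-larva averages of trial metrics
#'
#' Collapses a per-trial table to one row per larva and metric, honoring an
#' optional exclusion flag (excluded trials leave the denominator). Larvae
#' with no valid trials are dropped with a warning.
#'
#' @param trials A data.frame with a `larva_id` column, one or more numeric
#'   metric columns, and optionally a logical `excluded` column.
#' @param metrics Character vector of metric column names; defaults to all
#'   numeric columns other than `larva_id` / `trial`.
#' @return A data.frame, one row per larva, with per-larva means of each
#'   metric (`NA` values are dropped per metric).
#' @export
per_larva_average <- function(trials, metrics = NULL) {
  stopifnot(is.data.frame(trials), "larva_id" %in% names(trials))
  if ("excluded" %in% names(trials)) {
    trials <- trials[!isTRUE_vec(trials$excluded), , drop = FALSE]
  }
  if (is.null(metrics)) {
    metrics <- setdiff(
      names(trials)[vapply(trials, is.numeric, logical(1))],
      c("larva_id", "trial")
    )
  }
  ids <- unique(trials$larva_id)
  rows <- lapply(ids, function(id) {
    sub <- trials[trials$larva_id == id, , drop = FALSE]
    if (nrow(sub) == 0) {
      return(NULL)
    }
    vals <- vapply(metrics, function(m) {
      x <- sub[[m]]
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    }, numeric(1))
    cbind(data.frame(larva_id = id, n_trials = nrow(sub)), t(vals))
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!all(keep)) warning("larvae with no valid trials were dropped")
  out <- do.call(rbind, rows[keep])
  rownames(out) <- NULL
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Group summary: mean and SEM
#'
#' @param values Numeric vector of per-larva values.
#' @param group Group label.
#' @return A one-row data.frame (`GroupSummary`): `group`, `n`, `mean`,
#'   `sem` (`sd / sqrt(n)`), and the values as a list column.
#' @export
group_summary <- function(values, group = "group") {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1) stop("a group needs at least one value", call. = FALSE)
  out <- data.frame(
    group = group, n = n, mean = mean(values),
    sem = if (n > 1) stats::sd(values) / sqrt(n) else NA_real_
  )
  out$values <- list(values)
  class(out) <- c("GroupSummary", "data.frame")
  out
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided rank-sum comparison of two independent groups, exact when the
#' combined sample size is at most 20 and there are no ties, with the
#' normal approximation (tie and continuity corrected) otherwise — the
#' package's standard between-group test for rates and ratios.
#'
#' @param group_a,group_b Numeric vectors (each non-empty).
#' @param label_a,label_b Comparison labels.
#' @return A one-row data.frame (`TestResult`): `test`, `statistic` (the
#'   rank-sum U of the first group), `p_value`, `comparison`, `method`
#'   (`"exact"` or `"normal_approx"`).
#' @export
rank_sum_test <- function(group_a, group_b, label_a = "a", label_b = "b") {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  use_exact <- !ties && (length(group_a) + length(group_b)) <= 20
  wt <- suppressWarnings(stats::wilcox.test(
    group_a, group_b,
    alternative = "two.sided", exact = use_exact, correct = TRUE
  ))
  data.frame(
    test = "wilcoxon_rank_sum",
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    comparison = paste(label_a, "vs", label_b),
    method = if (use_exact) "exact" else "normal_approx",
    stringsAsFactors = FALSE
  ) -> out
  class(out) <- c("TestResult", "data.frame")
  out
}

#' One-way ANOVA with Tukey's HSD post hoc comparisons
#'
#' @param groups Named list of numeric vectors, one per group; at least two
#'   groups of at least two observations each.
#' @return A data.frame (`TestResult` rows): the omnibus F test first, then
#'   one row per pairwise comparison with the Tukey-adjusted p-value
#'   (studentized range distribution).
#' @export
anova_tukey <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2)) {
    stop("every group needs at least two observations", call. = FALSE)
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), sizes), levels = names(groups))
  )
  fit <- stats::aov(value ~ group, data = df)
  ftab <- summary(fit)[[1]]
  omni <- data.frame(
    test = "one_way_anova", statistic = ftab[1, "F value"],
    p_value = ftab[1, "Pr(>F)"], comparison = "omnibus",
    method = "F", stringsAsFactors = FALSE
  )
  tk <- stats::TukeyHSD(fit)$group
  pairs <- data.frame(
    test = "tukey_hsd", statistic = tk[, "diff"],
    p_value = tk[, "p adj"], comparison = rownames(tk),
    method = "studentized_range", stringsAsFactors = FALSE
  )
  out <- rbind(omni, pairs)
  rownames(out) <- NULL
  class(out) <- c("TestResult", "data.frame")
  out
}

#' Trial 1 versus trial 6 habituation check
#'
#' Paired per-larva comparison of a metric between the first and last trial
#' of the standard six-trial protocol, with a two-sided Wilcoxon signed-rank
#' test on the paired differences.
#'
#' @param trials A data.frame with columns `larva_id`, `trial`, and the
#'   metric column.
#' @param metric Name of the metric column.
#' @param trial_first,trial_last Trial indices to pair (defaults 1 and 6).
#' @return A list with `pairs` (per-larva values and differences) and `test`
#'   (a `TestResult` row; `NA` p-value when all differences are zero).
#' @export
trial_effect_table <- function(trials, metric, trial_first = 1,
                               trial_last = 6) {
  stopifnot(all(c("larva_id", "trial", metric) %in% names(trials)))
  a <- trials[trials$trial == trial_first, c("larva_id", metric)]
  b <- trials[trials$trial == trial_last, c("larva_id", metric)]
  m <- merge(a, b, by = "larva_id", suffixes = c("_first", "_last"))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) == 0) stop("no complete trial pairs", call. = FALSE)
  v1 <- m[[paste0(metric, "_first")]]
  v2 <- m[[paste0(metric, "_last")]]
  m$difference <- v2 - v1
  if (all(m$difference == 0)) {
    test <- data.frame(
      test = "wilcoxon_signed_rank", statistic = NA_real_,
      p_value = NA_real_,
      comparison = sprintf("trial %d vs trial %d", trial_first, trial_last),
      method = "degenerate_all_zero", stringsAsFactors = FALSE
    )
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(v2, v1, paired = TRUE, alternative = "two.sided")
    )
    test <- data.frame(
      test = "wilcoxon_signed_rank", statistic = unname(wt$statistic),
      p_value = wt$p.value,
      comparison = sprintf("trial %d vs trial %d", trial_first, trial_last),
      method = "signed_rank", stringsAsFactors = FALSE
    )
  }
  class(test) <- c("TestResult", "data.frame")
  list(pairs = m, test = test)
}
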