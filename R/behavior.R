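#' Speed-accuracy efficiency score
#'
#' Composite performance measure `(accuracy / response time) * 10`:
#' higher is better, penalizing both errors and slow responding. Units
#' follow the inputs (accuracy as a proportion, response time in the
#' unit supplied).
#'
#' @param accuracy Proportion correct in `[0, 1]` (vectorized).
#' @param rt Response time, `> 0` (vectorized).
#' @return Numeric efficiency score(s).
#' @export
efficiency_score <- function(accuracy, rt) {
  if (any(rt <= 0)) abort("Response times must be > 0.", class = "lexrsa_error_parameter")
  if (any(accuracy < 0 | accuracy > 1)) {
    abort("Accuracy must lie in [0, 1].", class = "lexrsa_error_parameter")
  }
  (accuracy / rt) * 10
}

#' Trim reaction-time outliers per subject
#'
#' Removes, for each subject, reaction times outside
#' `mean ± k * SD` where mean and SD are computed per subject in a
#' single pass (no re-iteration after removal). Subjects with zero RT
#' variance keep all their trials.
#'
#' @param trials Data frame with columns `subject` and `rt_ms` (other
#'   columns pass through); every subject needs at least 3 RTs.
#' @param k SD multiplier, default 2.5.
#' @return The trimmed tibble, with an attribute `n_removed` and a
#'   `removed` logical marking nothing (removed rows are dropped).
#' @export
trim_rt_outliers <- function(trials, k = 2.5) {
  trials <- tibble::as_tibble(trials)
  missing_cols <- setdiff(c("subject", "rt_ms"), names(trials))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "lexrsa_error_schema"
    )
  }
  if (any(trials$rt_ms <= 0)) abort("RTs must be > 0.", class = "lexrsa_error_schema")
  counts <- table(trials$subject)
  if (any(counts < 3)) abort("Every subject needs at least 3 RTs.", class = "lexrsa_error_parameter")
  out <- trials |>
    dplyr::group_by(.data$subject) |>
    dplyr::mutate(
      .m = mean(.data$rt_ms), .s = sd(.data$rt_ms),
      .keep_row = .data$.s == 0 |
        (.data$rt_ms >= .data$.m - k * .data$.s & .data$rt_ms <= .data$.m + k * .data$.s)
    ) |>
    dplyr::ungroup()
  n_removed <- sum(!out$.keep_row)
  out <- out |>
    dplyr::filter(.data$.keep_row) |>
    dplyr::select(-".m", -".s", -".keep_row")
  attr(out, "n_removed") <- n_removed
  out
}

#' Group summary statistics
#'
#' Constructor for the summary form (n, mean, SD) in which published
#' group comparisons are reported and from which effect sizes and
#' pooled-variance t-tests can be recomputed exactly.
#'
#' @param group Group label.
#' @param n Sample size, `>= 2`.
#' @param mean Group mean.
#' @param sd Group standard deviation, `>= 0`.
#' @return One-row tibble of class `group_summary`.
#' @export
group_summary <- function(group, n, mean, sd) {
  if (n < 2) abort("`n` must be >= 2.", class = "lexrsa_error_parameter")
  if (sd < 0) abort("`sd` must be >= 0.", class = "lexrsa_error_parameter")
  structure(
    tibble::tibble(group = group, n = as.integer(n), mean = mean, sd = sd),
    class = c("group_summary", class(tibble::tibble()))
  )
}

as_group_summary <- function(x) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(c("n", "mean", "sd"), names(x))
  if (length(missing_cols) || nrow(x) != 1) {
    abort("Expected a one-row summary with columns n, mean, sd.", class = "lexrsa_error_schema")
  }
  x
}

pooled_sd <- function(a, b) {
  sqrt(((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2))
}

#' Cohen's d from group summaries
#'
#' Standardized mean difference `(mean_a - mean_b) / s_pooled` with the
#' pooled standard deviation
#' `sqrt(((n_a - 1) sd_a^2 + (n_b - 1) sd_b^2) / (n_a + n_b - 2))`.
#' By the package's convention the first group is the clinical group
#' (dyslexic readers), so deficits come out negative.
#'
#' @param a,b One-row summaries (see [group_summary()]).
#' @return Cohen's d.
#' @export
cohens_d <- function(a, b) {
  a <- as_group_summary(a)
  b <- as_group_summary(b)
  sp <- pooled_sd(a, b)
  if (sp == 0) abort("Zero pooled SD: effect size undefined.", class = "lexrsa_error_degenerate")
  (a$mean - b$mean) / sp
}

#' Pooled-variance two-sample t-test from group summaries
#'
#' `t = (mean_a - mean_b) / (s_pooled * sqrt(1/n_a + 1/n_b))` with
#' `dof = n_a + n_b - 2`; identical to a raw-data pooled t-test when
#' the summaries are computed from the raw samples.
#'
#' @param a,b One-row summaries (see [group_summary()]).
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
two_sample_t <- function(a, b) {
  a <- as_group_summary(a)
  b <- as_group_summary(b)
  sp <- pooled_sd(a, b)
  if (sp == 0) abort("Zero pooled SD: t undefined.", class = "lexrsa_error_degenerate")
  df <- a$n + b$n - 2
  t_stat <- (a$mean - b$mean) / (sp * sqrt(1 / a$n + 1 / b$n))
  tibble::tibble(statistic = t_stat, df = df, p_value = 2 * pt(-abs(t_stat), df))
}

#' Published assessment summaries for the two reader groups
#'
#' Group means, standard deviations, and sample sizes on the cognitive
#' and language assessment battery of a word-reading study comparing
#' university students with dyslexia (n = 20) to typical readers
#' (n = 22): standardized reading fluency, adult reading-history
#' questionnaire, vocabulary and nonverbal IQ, and efficiency scores
#' (see [efficiency_score()]) for pseudoword reading, phonemic
#' awareness, and phonological short-term memory. These summaries are
#' the inputs from which group effect sizes ([cohens_d()]) and pooled
#' t-tests ([two_sample_t()]) are recomputed.
#'
#' @return Tibble: `measure`, `group`, `n`, `mean`, `sd`.
#' @export
assessment_summaries <- function() {
  tibble::tribble(
    ~measure, ~group, ~n, ~mean, ~sd,
    "age", "dyslexic", 20L, 22.7, 4.2,
    "age", "typical", 22L, 23.1, 3.7,
    "educational_level", "dyslexic", 20L, 2.9, 1.3,
    "educational_level", "typical", 22L, 3.3, 1.2,
    "reading_fluency", "dyslexic", 20L, 368.7, 72.9,
    "reading_fluency", "typical", 22L, 491.4, 59.8,
    "arhq_r", "dyslexic", 20L, 0.58, 0.08,
    "arhq_r", "typical", 22L, 0.32, 0.08,
    "vocabulary", "dyslexic", 20L, 38.2, 5.1,
    "vocabulary", "typical", 22L, 39.1, 4.6,
    "nonverbal_iq", "dyslexic", 20L, 41.6, 8.3,
    "nonverbal_iq", "typical", 22L, 42.2, 7.1,
    "pseudoword_reading", "dyslexic", 20L, 0.7, 0.2,
    "pseudoword_reading", "typical", 22L, 1.3, 0.3,
    "phonemic_awareness", "dyslexic", 20L, 29.4, 9.0,
    "phonemic_awareness", "typical", 22L, 53.9, 17.1,
    "phonological_stm", "dyslexic", 20L, 0.7, 0.2,
    "phonological_stm", "typical", 22L, 1.1, 0.2
  )
}

#' Group comparison table from assessment summaries
#'
#' Recomputes Cohen's d and the pooled two-sample t-test for every
#' measure in a summary table with exactly two groups per measure, in
#' the order (dyslexic - typical), i.e. (first group - second group)
#' by the `group` factor order supplied.
#'
#' @param summaries Tibble as returned by [assessment_summaries()].
#' @param order Character vector of the two group labels; the first is
#'   the minuend. Default `c("dyslexic", "typical")`.
#' @return Tibble: `measure`, `cohens_d`, `statistic`, `df`, `p_value`.
#' @export
compare_groups <- function(summaries = assessment_summaries(),
                           order = c("dyslexic", "typical")) {
  summaries <- tibble::as_tibble(summaries)
  summaries |>
    dplyr::group_by(.data$measure) |>
    dplyr::reframe({
      a <- dplyr::filter(dplyr::pick(dplyr::everything()), .data$group == order[1])
      b <- dplyr::filter(dplyr::pick(dplyr::everything()), .data$group == order[2])
      tt <- two_sample_t(a, b)
      tibble::tibble(
        cohens_d = cohens_d(a, b),
        statistic = tt$statistic, df = tt$df, p_value = tt$p_value
      )
    })
}

#' Mixed-design repetition ANOVA on reaction times
#'
#' Classical univariate mixed ANOVA for a reading-aloud design with
#' Group as a between-subject factor and stimulus Repetition as a
#' within-subject factor: Group is tested against subjects-within-group
#' variance, Repetition and the Group x Repetition interaction against
#' the repetition-by-subject residual. Cell means per subject x
#' repetition are computed first; every subject must contribute every
#' repetition level. No sphericity correction is applied.
#'
#' @param trials Data frame with columns `subject`, `group`,
#'   `repetition`, `rt_ms`.
#' @return Tibble: `term`, `df`, `df_residual`, `statistic`, `p_value`.
#' @export
repetition_anova <- function(trials) {
  trials <- tibble::as_tibble(trials)
  need <- c("subject", "group", "repetition", "rt_ms")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "lexrsa_error_schema"
    )
  }
  cells <- trials |>
    dplyr::group_by(.data$subject, .data$group, .data$repetition) |>
    dplyr::summarise(rt = mean(.data$rt_ms), .groups = "drop")
  reps <- sort(unique(cells$repetition))
  full <- cells |>
    dplyr::count(.data$subject) |>
    dplyr::filter(.data$n != length(reps))
  if (nrow(full)) {
    abort("Every subject must contribute every repetition level.", class = "lexrsa_error_schema")
  }
  if (var(cells$rt) == 0) {
    abort("Degenerate model: constant response.", class = "lexrsa_error_degenerate")
  }
  cells <- cells |>
    dplyr::mutate(
      subject = factor(.data$subject),
      group = factor(.data$group),
      repetition = factor(.data$repetition)
    )
  fit <- aov(rt ~ group * repetition + Error(subject), data = cells)
  s <- summary(fit)
  between <- as.data.frame(s[["Error: subject"]][[1]])
  within <- as.data.frame(s[["Error: Within"]][[1]])
  parse_stratum <- function(tab) {
    tab$term <- trimws(rownames(tab))
    resid_df <- tab[tab$term == "Residuals", "Df"]
    tab <- tab[tab$term != "Residuals", ]
    tibble::tibble(
      term = tab$term, df = tab$Df, df_residual = resid_df,
      statistic = tab[["F value"]], p_value = tab[["Pr(>F)"]]
    )
  }
  dplyr::bind_rows(parse_stratum(between), parse_stratum(within))
}
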