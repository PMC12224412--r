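#' Confound-partialled Spearman correlation
#'
#' Second-order rank correlation between a neural and a theoretical
#' dissimilarity vector with nuisance dissimilarities partialled out.
#' All vectors are rank-transformed (average ranks for ties); the neural
#' and model ranks are residualized on the confound ranks by ordinary
#' least squares (with intercept); the partial correlation is the
#' Pearson correlation of the two residual vectors. With no confounds
#' this is exactly the Spearman correlation.
#'
#' @param x,y Numeric vectors of equal length `>= 4` (typically
#'   [rdm_vec()] of a neural and a model RDM).
#' @param confounds List of numeric vectors of the same length (possibly
#'   empty), e.g. vectorized lexical-frequency and word-length RDMs.
#' @return Partial Spearman correlation in `[-1, 1]`.
#' @export
partial_spearman <- function(x, y, confounds = list()) {
  if (is_rdm(x)) x <- rdm_vec(x)
  if (is_rdm(y)) y <- rdm_vec(y)
  confounds <- purrr::map(confounds, function(z) if (is_rdm(z)) rdm_vec(z) else z)
  n <- length(x)
  if (n < 4) abort("Need vectors of length >= 4.", class = "lexrsa_error_parameter")
  lens <- vapply(c(list(y), confounds), length, integer(1))
  if (any(lens != n)) abort("All vectors must have equal length.", class = "lexrsa_error_parameter")
  rx <- rank(x)
  ry <- rank(y)
  if (length(confounds)) {
    z <- cbind(1, vapply(confounds, rank, numeric(n)))
    qz <- qr(z)
    rx <- qr.resid(qz, rx)
    ry <- qr.resid(qz, ry)
  } else {
    rx <- rx - mean(rx)
    ry <- ry - mean(ry)
  }
  if (sd(rx) < 1e-12 || sd(ry) < 1e-12) {
    abort("Partial correlation undefined: zero-variance residuals.",
      class = "lexrsa_error_degenerate"
    )
  }
  sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
}

#' Wilcoxon signed-rank test against zero median
#'
#' Group-level RSA inference: per-subject second-order correlations are
#' compared to a distribution with median zero by a two-sided Wilcoxon
#' signed-rank test. Exact zeros are dropped (Wilcoxon's original rule);
#' the exact null distribution is used for `n <= 25` remaining values
#' (when there are no ties among the absolute values), a normal
#' approximation with continuity correction otherwise.
#'
#' @param x Numeric vector; at least 5 nonzero values required.
#' @return One-row tibble: `statistic` (V), `p_value`, `n` (after
#'   dropping zeros), `n_zero`, `method` (`"exact"` or `"approximate"`).
#' @export
signed_rank_test <- function(x) {
  stopifnot(is.numeric(x))
  n_zero <- sum(x == 0)
  x <- x[x != 0]
  n <- length(x)
  if (n < 5) abort("Need at least 5 nonzero values.", class = "lexrsa_error_parameter")
  want_exact <- n <= 25 && !any(duplicated(abs(x)))
  ht <- suppressWarnings(wilcox.test(x, mu = 0, exact = want_exact, correct = TRUE))
  tibble::tibble(
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    n = n,
    n_zero = n_zero,
    method = if (want_exact) "exact" else "approximate"
  )
}

#' Two-sample test between groups
#'
#' Pooled-variance two-sample t-test (default, `dof = n_a + n_b - 2`) or
#' Wilcoxon rank-sum test, two-sided.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param method `"ttest"` or `"ranksum"`.
#' @return One-row tibble: `statistic`, `df` (`NA` for ranksum),
#'   `p_value`, `method`.
#' @export
between_group_test <- function(a, b, method = c("ttest", "ranksum")) {
  method <- match.arg(method)
  if (length(a) < 2 || length(b) < 2) abort("Each group needs n >= 2.", class = "lexrsa_error_parameter")
  if (method == "ttest") {
    if (var(c(a - mean(a), b - mean(b))) == 0) {
      abort("Zero pooled variance: t-test undefined.", class = "lexrsa_error_degenerate")
    }
    ht <- t.test(a, b, var.equal = TRUE)
    tibble::tibble(
      statistic = unname(ht$statistic), df = unname(ht$parameter),
      p_value = ht$p.value, method = method
    )
  } else {
    ht <- suppressWarnings(wilcox.test(a, b))
    tibble::tibble(
      statistic = unname(ht$statistic), df = NA_real_,
      p_value = ht$p.value, method = method
    )
  }
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values with enforced monotonicity; `q >= p`
#' elementwise and the ordering of p-values is preserved.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values.
#' @export
fdr_bh <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("p-values must all lie in [0, 1].", class = "lexrsa_error_parameter")
  }
  p.adjust(p, method = "BH")
}

#' Per-subject second-order correlations
#'
#' Computes the confound-partialled Spearman correlation between each
#' subject's neural RDM and each theoretical model RDM.
#'
#' @param neural A tibble with columns `subject`, `group`, `roi`, and a
#'   list-column `rdm` of neural [rdm] objects.
#' @param models Named list of model [rdm]s (e.g.
#'   `list(SemModel = ..., OrthModel = ...)`).
#' @param confounds List of confound [rdm]s partialled out of every
#'   correlation (possibly empty).
#' @return A tibble: `subject`, `group`, `roi`, `model`, `rho`.
#' @export
rsa_correlations <- function(neural, models, confounds = list()) {
  neural <- tibble::as_tibble(neural)
  need <- c("subject", "group", "roi", "rdm")
  missing_cols <- setdiff(need, names(neural))
  if (length(missing_cols)) {
    abort(paste0("`neural` is missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "lexrsa_error_schema"
    )
  }
  if (is.null(names(models)) || any(names(models) == "")) {
    abort("`models` must be a named list of RDMs.", class = "lexrsa_error_parameter")
  }
  purrr::walk(models, function(m) check_same_labels(models[[1]], m))
  purrr::walk(confounds, function(m) check_same_labels(models[[1]], m))
  conf_vecs <- purrr::map(confounds, rdm_vec)
  model_vecs <- purrr::map(models, rdm_vec)
  purrr::map_dfr(seq_len(nrow(neural)), function(i) {
    nr <- neural$rdm[[i]]
    check_same_labels(models[[1]], nr)
    nv <- rdm_vec(nr)
    tibble::tibble(
      subject = neural$subject[i],
      group = neural$group[i],
      roi = neural$roi[i],
      model = names(models),
      rho = unname(purrr::map_dbl(model_vecs, function(mv) partial_spearman(nv, mv, conf_vecs)))
    )
  })
}

#' Group-level RSA inference with FDR control
#'
#' Within each group and region, tests whether the per-subject
#' second-order correlations for each model have nonzero median
#' (two-sided signed-rank test), then adjusts p-values across the model
#' dimension by Benjamini-Hochberg FDR within each (group, region)
#' family — the default, matching correction "on the model dimension";
#' `fdr_family = "pooled"` instead pools all tests of the same kind into
#' one family. When exactly two groups are present, between-group
#' contrasts per region and model are appended.
#'
#' @param correlations Output of [rsa_correlations()].
#' @param alpha Significance threshold recorded in the output.
#' @param fdr_family `"per_roi_group"` (default) or `"pooled"`.
#' @param between_method Two-group contrast: `"ttest"` (default) or
#'   `"ranksum"`.
#' @return A tibble: `roi`, `model`, `group` (a group label or
#'   `"<a> vs <b>"`), `n`, `median_rho`, `statistic`, `p_value`,
#'   `q_value`, `test`, `significant`.
#' @export
rsa_group_tests <- function(correlations, alpha = 0.05,
                            fdr_family = c("per_roi_group", "pooled"),
                            between_method = c("ttest", "ranksum")) {
  fdr_family <- match.arg(fdr_family)
  between_method <- match.arg(between_method)
  correlations <- tibble::as_tibble(correlations)

  within <- correlations |>
    dplyr::group_by(.data$group, .data$roi, .data$model) |>
    dplyr::reframe(
      n = length(.data$rho),
      median_rho = median(.data$rho),
      signed_rank_test(.data$rho)[, c("statistic", "p_value")]
    ) |>
    dplyr::mutate(test = "signed_rank")

  groups <- unique(correlations$group)
  between <- NULL
  if (length(groups) == 2) {
    between <- correlations |>
      dplyr::group_by(.data$roi, .data$model) |>
      dplyr::reframe({
        a <- .data$rho[.data$group == groups[1]]
        b <- .data$rho[.data$group == groups[2]]
        bt <- between_group_test(a, b, method = between_method)
        tibble::tibble(
          group = paste(groups[1], "vs", groups[2]),
          n = length(a) + length(b),
          median_rho = median(a) - median(b),
          statistic = bt$statistic, p_value = bt$p_value, test = bt$method
        )
      })
  }
  out <- dplyr::bind_rows(within, between)
  out <- if (fdr_family == "per_roi_group") {
    out |>
      dplyr::group_by(.data$group, .data$roi) |>
      dplyr::mutate(q_value = fdr_bh(.data$p_value)) |>
      dplyr::ungroup()
  } else {
    out |>
      dplyr::group_by(.data$test) |>
      dplyr::mutate(q_value = fdr_bh(.data$p_value)) |>
      dplyr::ungroup()
  }
  out |>
    dplyr::mutate(significant = .data$q_value < alpha) |>
    dplyr::select(
      "roi", "model", "group", "n", "median_rho",
      "statistic", "p_value", "q_value", "test", "significant"
    ) |>
    dplyr::arrange(.data$roi, .data$group, .data$model)
}

#' Neural RDMs for every subject of a simulated dataset
#'
#' @param dataset A `lexrsa_dataset` from [simulate_dataset()].
#' @param scheme Cross-validation scheme, see [make_partitions()].
#' @param roi Region label attached to the output (simulated datasets
#'   contain a single region).
#' @return Tibble with `subject`, `group`, `roi`, `rdm` (list-column),
#'   ready for [rsa_correlations()].
#' @export
neural_rdms <- function(dataset, scheme = c("ordered_pairs", "all_pairs"), roi = "sim") {
  stopifnot(inherits(dataset, "lexrsa_dataset"))
  scheme <- match.arg(scheme)
  dataset$subjects |>
    dplyr::transmute(
      .data$subject, .data$group, roi = roi,
      rdm = purrr::map(.data$patterns, function(p) {
        cleaned <- remove_dead_voxels(p)$patterns
        crossval_euclidean_rdm(cleaned, scheme = scheme)
      })
    )
}

#' Run the full RSA pipeline on a dataset
#'
#' Orchestrates the second-order analysis: per-subject cross-validated
#' neural RDMs, confound-partialled Spearman correlations against the
#' semantic and orthographic model RDMs, and group-level signed-rank /
#' between-group inference with FDR control.
#'
#' @param dataset A `lexrsa_dataset` from [simulate_dataset()].
#' @param models Named list of model [rdm]s; defaults to
#'   `list(SemModel = dataset$sem, OrthModel = dataset$orth)`.
#' @param confounds List of confound [rdm]s; defaults to the combined
#'   log-frequency and length matrices of the dataset's words, passed
#'   individually (`NULL` to use defaults, `list()` for none).
#' @inheritParams rsa_group_tests
#' @inheritParams neural_rdms
#' @return A list of class `lexrsa_rsa`: `correlations`, `group_tests`,
#'   `models`, `alpha`.
#' @export
run_rsa <- function(dataset, models = NULL, confounds = NULL,
                    scheme = c("ordered_pairs", "all_pairs"), alpha = 0.05,
                    fdr_family = c("per_roi_group", "pooled"),
                    between_method = c("ttest", "ranksum")) {
  stopifnot(inherits(dataset, "lexrsa_dataset"))
  if (is.null(models)) {
    models <- list(SemModel = dataset$sem, OrthModel = dataset$orth)
  }
  if (is.null(confounds)) {
    confounds <- list(
      frequency = confound_rdm(dataset$words, "freq_pm"),
      length = confound_rdm(dataset$words, "length")
    )
  }
  neural <- neural_rdms(dataset, scheme = match.arg(scheme))
  correlations <- rsa_correlations(neural, models, confounds)
  group_tests <- rsa_group_tests(correlations,
    alpha = alpha,
    fdr_family = match.arg(fdr_family), between_method = match.arg(between_method)
  )
  structure(list(
    correlations = correlations, group_tests = group_tests,
    models = names(models), alpha = alpha
  ), class = "lexrsa_rsa")
}

#' @export
print.lexrsa_rsa <- function(x, ...) {
  cat(sprintf(
    "<lexrsa_rsa: %d subject-level correlations, %d group tests (alpha = %g)>\n",
    nrow(x$correlations), nrow(x$group_tests), x$alpha
  ))
  print(x$group_tests, n = 10)
  invisible(x)
}

#' @describeIn run_rsa Subject-level correlations as a tibble.
#' @param x,object A `lexrsa_rsa` object.
#' @param ... Unused.
#' @export
tidy.lexrsa_rsa <- function(x, ...) x$correlations

#' @describeIn run_rsa Group-level test table.
#' @export
glance.lexrsa_rsa <- function(x, ...) x$group_tests

#' Boxplot of subject-level second-order correlations
#'
#' @param object A `lexrsa_rsa` object.
#' @param ... Unused.
#' @return A ggplot: per-subject rho by model and group, one facet per
#'   region.
#' @export
autoplot.lexrsa_rsa <- function(object, ...) {
  ggplot2::ggplot(
    object$correlations,
    ggplot2::aes(x = .data$model, y = .data$rho, fill = .data$group)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.7) +
    ggplot2::geom_point(
      position = ggplot2::position_jitterdodge(jitter.width = 0.12),
      size = 0.8, alpha = 0.6
    ) +
    ggplot2::facet_wrap(~roi) +
    ggplot2::labs(y = "partial Spearman rho", x = NULL) +
    ggplot2::theme_minimal()
}
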