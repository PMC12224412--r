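as_run_list <- function(patterns) {
  if (is.matrix(patterns)) patterns <- list(patterns)
  if (!is.list(patterns) || !all(vapply(patterns, is.matrix, logical(1)))) {
    abort("`patterns` must be a matrix or list of condition x voxel matrices.",
      class = "lexrsa_error_schema"
    )
  }
  labs <- rownames(patterns[[1]])
  if (is.null(labs)) abort("Pattern matrices need condition rownames.", class = "lexrsa_error_schema")
  for (r in seq_along(patterns)) {
    if (!identical(rownames(patterns[[r]]), labs)) {
      missing_cond <- setdiff(labs, rownames(patterns[[r]]))
      abort(paste0(
        "Run ", r, " does not match run 1's conditions",
        if (length(missing_cond)) paste0(" (missing: ", paste(missing_cond, collapse = ", "), ")"),
        "."
      ), class = "lexrsa_error_schema")
    }
    if (ncol(patterns[[r]]) != ncol(patterns[[1]])) {
      abort("All runs must have the same voxel count.", class = "lexrsa_error_schema")
    }
  }
  patterns
}

#' Remove dead voxels from multi-run patterns
#'
#' Drops voxels whose values are constant (zero variance, which includes
#' all-zero) across every sample of every run — voxels carrying no
#' activation information. The order of the remaining voxels is
#' preserved.
#'
#' @param patterns Condition-by-voxel matrix or list of per-run matrices.
#' @return A list: `patterns` (same shape as input), `removed` (count).
#' @export
remove_dead_voxels <- function(patterns) {
  single <- is.matrix(patterns)
  patterns <- as_run_list(patterns)
  stacked <- do.call(rbind, patterns)
  if (ncol(stacked) < 1) abort("Need at least one voxel.", class = "lexrsa_error_schema")
  v <- apply(stacked, 2, var)
  dead <- v == 0
  if (all(dead)) abort("All voxels are dead (constant).", class = "lexrsa_error_degenerate")
  out <- lapply(patterns, function(p) p[, !dead, drop = FALSE])
  list(
    patterns = if (single) out[[1]] else out,
    removed = sum(dead)
  )
}

#' Cross-validation partitions over runs
#'
#' Enumerates (train run, test run) pairs. The default `"ordered_pairs"`
#' scheme uses all ordered pairs of *distinct* runs (`r * (r - 1)`
#' partitions; 12 for 4 runs) — true cross-validation, which keeps the
#' distance estimator unbiased. `"all_pairs"` additionally includes
#' train == test pairs (`r^2` partitions; 16 for 4 runs), reproducing
#' the partition count reported for 4x4 run designs at the price of
#' reintroducing the positive bias of within-run distances.
#'
#' @param runs Vector of run labels (length >= 2) or a single integer
#'   count of runs.
#' @param scheme `"ordered_pairs"` (default) or `"all_pairs"`.
#' @return A tibble with columns `train`, `test`.
#' @export
make_partitions <- function(runs, scheme = c("ordered_pairs", "all_pairs")) {
  scheme <- match.arg(scheme)
  if (length(runs) == 1L && is.numeric(runs)) runs <- seq_len(runs)
  if (length(runs) < 2L) abort("Need at least 2 runs.", class = "lexrsa_error_parameter")
  grid <- tidyr::expand_grid(train = runs, test = runs)
  if (scheme == "ordered_pairs") grid <- dplyr::filter(grid, .data$train != .data$test)
  grid
}

#' Cross-validated Euclidean distance RDM
#'
#' For conditions `a, b` and a partition with train run `T` and test run
#' `S`, the cross-validated squared Euclidean distance is the inner
#' product of the condition difference vectors from the two runs,
#' normalized by voxel count:
#' `d(a, b) = (x_a^T - x_b^T) . (x_a^S - x_b^S) / n_voxels`.
#' Because train and test noise are independent, the estimator is
#' unbiased: its expectation is the true pattern distance, and it can go
#' negative when the true distance is near zero. Entries are averaged
#' over all partitions; the ordered-pair schemes make the result
#' symmetric by construction, and the diagonal is set to 0 by
#' convention (self-distances never enter second-order correlations).
#'
#' @param patterns List of per-run condition-by-voxel matrices (all runs
#'   share conditions and voxel count), e.g. one element of
#'   `simulate_dataset()$subjects$patterns` or stacked [glm_patterns()]
#'   outputs.
#' @param scheme Partition scheme, see [make_partitions()].
#' @param partitions Optional explicit partition tibble overriding
#'   `scheme`.
#' @return An [rdm] (negative entries allowed) with attributes
#'   `n_partitions` and `n_voxels`.
#' @export
crossval_euclidean_rdm <- function(patterns, scheme = c("ordered_pairs", "all_pairs"),
                                   partitions = NULL) {
  patterns <- as_run_list(patterns)
  if (nrow(patterns[[1]]) < 2) abort("Need at least 2 conditions.", class = "lexrsa_error_schema")
  if (is.null(partitions)) {
    partitions <- make_partitions(length(patterns), match.arg(scheme))
  }
  labs <- rownames(patterns[[1]])
  nv <- ncol(patterns[[1]])
  n <- length(labs)
  acc <- matrix(0, n, n)
  for (p in seq_len(nrow(partitions))) {
    xt <- patterns[[partitions$train[p]]]
    xs <- patterns[[partitions$test[p]]]
    g <- xt %*% t(xs) / nv
    dg_t <- diag(g)
    # d(a,b) = g[a,a] + g[b,b] - g[a,b] - g[b,a]
    acc <- acc + outer(dg_t, rep(1, n)) + outer(rep(1, n), dg_t) - g - t(g)
  }
  d <- acc / nrow(partitions)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  out <- rdm(d, labs, allow_negative = TRUE)
  attr(out, "n_partitions") <- nrow(partitions)
  attr(out, "n_voxels") <- nv
  out
}

#' Naive Euclidean distance RDM of run-averaged patterns
#'
#' Squared Euclidean distance between run-mean condition patterns,
#' normalized by voxel count. Unlike the cross-validated estimator this
#' is positively biased under noise (noise inflates every distance), but
#' in the noiseless limit the two coincide — which makes it the natural
#' oracle for [crossval_euclidean_rdm()].
#'
#' @inheritParams crossval_euclidean_rdm
#' @return An [rdm].
#' @export
naive_euclidean_rdm <- function(patterns) {
  patterns <- as_run_list(patterns)
  avg <- Reduce(`+`, patterns) / length(patterns)
  d <- as.matrix(dist(avg))^2 / ncol(avg)
  rdm(d, rownames(patterns[[1]]))
}
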