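#' Representational dissimilarity matrices (RDMs)
#'
#' An `rdm` is a labeled square numeric matrix of pairwise dissimilarities
#' between conditions (here, words), with a zero diagonal. Both theoretical
#' model matrices (orthographic, semantic, category, confound) and neural
#' matrices estimated from voxel patterns are `rdm` objects; second-order
#' analysis correlates their vectorized lower triangles.
#'
#' Theoretical RDMs are non-negative and symmetric by construction.
#' Cross-validated neural RDMs are symmetric with a conventional zero
#' diagonal but may contain negative entries, because the cross-validated
#' distance estimator is unbiased and can undershoot zero; construct those
#' with `allow_negative = TRUE`.
#'
#' @param values Square numeric matrix of dissimilarities.
#' @param labels Character vector of condition labels, one per row/column.
#'   Defaults to existing `rownames(values)`.
#' @param allow_negative Permit negative entries (cross-validated neural
#'   RDMs); default `FALSE`.
#' @return An object of class `rdm`: the numeric matrix with `dimnames`
#'   set to `labels`.
#' @examples
#' m <- rdm(matrix(c(0, 1, 1, 0), 2), labels = c("arc", "sea"))
#' rdm_vec(m)
#' @export
rdm <- function(values, labels = rownames(values), allow_negative = FALSE) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (n != ncol(values)) abort("RDM must be square.", class = "lexrsa_error_rdm")
  if (is.null(labels)) abort("RDM needs condition labels.", class = "lexrsa_error_rdm")
  labels <- as.character(labels)
  if (length(labels) != n) abort("One label per condition is required.", class = "lexrsa_error_rdm")
  if (anyDuplicated(labels)) abort("RDM labels must be unique.", class = "lexrsa_error_rdm")
  if (!all(is.finite(values))) abort("RDM entries must all be finite.", class = "lexrsa_error_rdm")
  if (max(abs(values - t(values))) > 1e-8) {
    abort("RDM must be symmetric.", class = "lexrsa_error_rdm")
  }
  values <- (values + t(values)) / 2
  if (max(abs(diag(values))) > 1e-8) {
    abort("RDM diagonal must be zero.", class = "lexrsa_error_rdm")
  }
  diag(values) <- 0
  if (!allow_negative && min(values) < 0) {
    abort("Negative dissimilarities require `allow_negative = TRUE`.", class = "lexrsa_error_rdm")
  }
  dimnames(values) <- list(labels, labels)
  structure(values, class = c("rdm", "matrix", "array"))
}

#' @rdname rdm
#' @param x Object to test or vectorize.
#' @export
is_rdm <- function(x) inherits(x, "rdm")

rdm_labels <- function(x) rownames(x)

check_same_labels <- function(a, b) {
  if (!identical(rdm_labels(a), rdm_labels(b))) {
    abort("RDMs must share identical condition labels in the same order.",
      class = "lexrsa_error_labels"
    )
  }
  invisible(TRUE)
}

#' Vectorize an RDM
#'
#' Extracts the strictly lower triangle in row-major order — entry (2,1),
#' then (3,1), (3,2), (4,1), ... — the fixed vectorization convention used
#' for every second-order correlation in the package, so results are
#' reproducible bit-for-bit.
#'
#' @return For `rdm_vec()`, a numeric vector of length `n(n-1)/2`; for
#'   `rdm_unvec()`, the reconstructed symmetric `rdm`.
#' @rdname rdm
#' @export
rdm_vec <- function(x) {
  m <- unclass(as.matrix(x))
  tm <- t(m)
  tm[upper.tri(tm)]
}

#' @rdname rdm
#' @param v Numeric vector as produced by `rdm_vec()`.
#' @param labels Condition labels of the reconstructed matrix.
#' @export
rdm_unvec <- function(v, labels) {
  n <- length(labels)
  if (length(v) != n * (n - 1) / 2) {
    abort("Vector length does not match n(n-1)/2 for these labels.",
      class = "lexrsa_error_rdm"
    )
  }
  m <- matrix(0, n, n)
  tm <- t(m)
  tm[upper.tri(tm)] <- v
  m <- t(tm)
  m <- m + t(m)
  rdm(m, labels, allow_negative = TRUE)
}

#' Correlate two RDMs
#'
#' Second-order correlation: Pearson or Spearman correlation between the
#' vectorized strictly-lower triangles of two RDMs defined over the same
#' conditions. Spearman (rank) correlation is the conventional choice
#' because it does not assume a linear relation between the two
#' dissimilarity scales; ties receive average ranks.
#'
#' @param a,b `rdm` objects with identical labels and at least 3 conditions.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
rdm_correlate <- function(a, b, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  check_same_labels(a, b)
  if (nrow(a) < 3) abort("Need at least 3 conditions.", class = "lexrsa_error_rdm")
  va <- rdm_vec(a)
  vb <- rdm_vec(b)
  if (sd(va) == 0 || sd(vb) == 0) {
    abort("Correlation undefined: an RDM has zero off-diagonal variance.",
      class = "lexrsa_error_degenerate"
    )
  }
  cor(va, vb, method = method)
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm: %d x %d conditions>\n", nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE], ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more conditions\n", nrow(x) - 6L))
  invisible(x)
}

#' Tidy an RDM into a long tibble
#'
#' @param x An `rdm`.
#' @param upper Include the full matrix (`TRUE`) or only the strictly
#'   lower triangle (default), one row per unordered pair.
#' @param ... Unused.
#' @return A tibble with columns `label_i`, `label_j`, `value`.
#' @export
tidy.rdm <- function(x, upper = FALSE, ...) {
  labs <- rdm_labels(x)
  df <- tibble::as_tibble(as.data.frame.table(unclass(as.matrix(x)),
    responseName = "value", stringsAsFactors = FALSE
  ))
  names(df) <- c("label_i", "label_j", "value")
  df$label_i <- factor(df$label_i, levels = labs)
  df$label_j <- factor(df$label_j, levels = labs)
  if (!upper) {
    df <- df[as.integer(df$label_i) > as.integer(df$label_j), ]
    df <- df[order(df$label_i, df$label_j), ]
  }
  df$label_i <- as.character(df$label_i)
  df$label_j <- as.character(df$label_j)
  tibble::as_tibble(df)
}

#' Heatmap of an RDM
#'
#' @param object An `rdm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rdm <- function(object, ...) {
  df <- tidy(object, upper = TRUE)
  labs <- rdm_labels(object)
  df$label_i <- factor(df$label_i, levels = labs)
  df$label_j <- factor(df$label_j, levels = rev(labs))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label_i, y = .data$label_j, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "dissimilarity") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1))
}
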