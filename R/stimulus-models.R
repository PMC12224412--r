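#' Validate a word stimulus table
#'
#' Word stimuli are carried as a tibble with one row per word: `token`
#' (the letter string), `category` (semantic category label, e.g. "art"
#' vs "water"), and `freq_pm` (lexical frequency, occurrences per
#' million, strictly positive). A `length` column (letter count) is added
#' if absent and checked against the token if present. Tokens must be
#' unique; their order is the condition order shared by every RDM built
#' from the table.
#'
#' @param words A data frame with columns `token`, `category`, `freq_pm`.
#' @return A validated tibble with columns `token`, `category`,
#'   `freq_pm`, `length`.
#' @export
validate_words <- function(words) {
  words <- tibble::as_tibble(words)
  need <- c("token", "category", "freq_pm")
  missing_cols <- setdiff(need, names(words))
  if (length(missing_cols)) {
    abort(paste0("Word table is missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "lexrsa_error_schema"
    )
  }
  if (anyDuplicated(words$token)) {
    abort("Word tokens must be unique.", class = "lexrsa_error_schema")
  }
  if (!all(is.finite(words$freq_pm)) || any(words$freq_pm <= 0)) {
    abort("`freq_pm` must be finite and > 0 for every word.", class = "lexrsa_error_schema")
  }
  len <- nchar(words$token)
  if ("length" %in% names(words)) {
    if (!all(words$length == len)) {
      abort("`length` must equal the letter count of `token`.", class = "lexrsa_error_schema")
    }
  }
  words$length <- as.integer(len)
  if (any(words$length < 1L)) abort("Tokens must have at least one letter.", class = "lexrsa_error_schema")
  core <- c("token", "category", "freq_pm", "length")
  words[, c(core, setdiff(names(words), core))]
}

#' Orthographic model RDM
#'
#' Pairwise position-weighted Levenshtein distances between word tokens
#' (see [weighted_levenshtein()]): the theoretical dissimilarity matrix
#' for orthographic word form ("OrthModel").
#'
#' @param words Word table (see [validate_words()]).
#' @param w_edge Edge-position cost multiplier, `>= 1`; default `2`.
#' @return An [rdm] labeled by token.
#' @export
orth_rdm <- function(words, w_edge = 2) {
  words <- validate_words(words)
  if (nrow(words) < 2) abort("Need at least 2 words.", class = "lexrsa_error_rdm")
  tok <- words$token
  n <- length(tok)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- weighted_levenshtein(tok[i], tok[j], w_edge)
    }
  }
  rdm(m, tok)
}

#' Validate an embedding table
#'
#' One fixed-dimension real vector per word token; tibble with a `token`
#' column followed by numeric coordinate columns.
#'
#' @param embeddings Data frame: `token` plus `k >= 2` numeric columns.
#' @param tokens Optional token vector that must all be present.
#' @return Validated tibble.
#' @export
validate_embeddings <- function(embeddings, tokens = NULL) {
  embeddings <- tibble::as_tibble(embeddings)
  if (!"token" %in% names(embeddings)) {
    abort("Embedding table needs a `token` column.", class = "lexrsa_error_schema")
  }
  coord <- setdiff(names(embeddings), "token")
  if (length(coord) < 2) {
    abort("Embeddings must have dimension k >= 2.", class = "lexrsa_error_schema")
  }
  vals <- as.matrix(embeddings[, coord])
  if (!is.numeric(vals) || !all(is.finite(vals))) {
    abort("Embedding coordinates must be finite numerics.", class = "lexrsa_error_schema")
  }
  if (anyDuplicated(embeddings$token)) {
    abort("Embedding tokens must be unique.", class = "lexrsa_error_schema")
  }
  if (!is.null(tokens)) {
    missing_tok <- setdiff(tokens, embeddings$token)
    if (length(missing_tok)) {
      abort(paste0("No embedding vector for token(s): ", paste(missing_tok, collapse = ", ")),
        class = "lexrsa_error_schema"
      )
    }
  }
  embeddings
}

#' Semantic model RDM
#'
#' Pairwise distances between word embedding vectors (e.g. coordinates
#' from a low-dimensional distributional embedding of a text corpus):
#' the theoretical dissimilarity matrix for word meaning ("SemModel").
#' Euclidean distance is the default reading of such embedding spaces;
#' cosine distance (`1 - cosine similarity`) is available.
#'
#' @param words Word table; RDM rows follow its token order.
#' @param embeddings Embedding table with a vector for every token.
#' @param metric `"euclidean"` (default) or `"cosine"`.
#' @return An [rdm] labeled by token.
#' @export
sem_rdm <- function(words, embeddings, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  words <- validate_words(words)
  embeddings <- validate_embeddings(embeddings, tokens = words$token)
  coord <- setdiff(names(embeddings), "token")
  x <- as.matrix(embeddings[match(words$token, embeddings$token), coord])
  m <- if (metric == "euclidean") {
    as.matrix(dist(x, method = "euclidean"))
  } else {
    nrm <- sqrt(rowSums(x^2))
    if (any(nrm == 0)) abort("Cosine distance undefined for a zero vector.", class = "lexrsa_error_degenerate")
    s <- (x %*% t(x)) / outer(nrm, nrm)
    1 - pmin(pmax(s, -1), 1)
  }
  diag(m) <- 0
  rdm(m, words$token)
}

#' Semantic-category model RDM
#'
#' Binary dissimilarity: 0 for word pairs in the same semantic category,
#' 1 otherwise.
#'
#' @param words Word table with a `category` column.
#' @return An [rdm] labeled by token.
#' @export
category_rdm <- function(words) {
  words <- validate_words(words)
  m <- 1 - outer(words$category, words$category, "==")
  storage.mode(m) <- "double"
  rdm(m, words$token)
}

#' Confound RDM from a per-word covariate
#'
#' Pairwise absolute differences of a nuisance variable, optionally on a
#' log10 scale. Lexical frequency is conventionally log-transformed
#' (frequency effects in reading are approximately logarithmic); word
#' length is used on its raw scale.
#'
#' @param words Word table.
#' @param var Column to use: `"freq_pm"` or `"length"` (or any numeric
#'   column present in `words`).
#' @param transform `"identity"` or `"log10"`. Defaults to `"log10"` for
#'   `freq_pm`, `"identity"` otherwise.
#' @return An [rdm] labeled by token.
#' @export
confound_rdm <- function(words, var = c("freq_pm", "length"), transform = NULL) {
  words <- validate_words(words)
  var <- if (is.character(var)) var[1] else var
  if (!var %in% names(words)) {
    abort(paste0("No column `", var, "` in word table."), class = "lexrsa_error_schema")
  }
  v <- as.numeric(words[[var]])
  if (is.null(transform)) transform <- if (var == "freq_pm") "log10" else "identity"
  transform <- match.arg(transform, c("identity", "log10"))
  if (!all(is.finite(v))) abort("Covariate values must be finite.", class = "lexrsa_error_schema")
  if (transform == "log10") {
    if (any(v <= 0)) abort("log10 transform requires strictly positive values.", class = "lexrsa_error_parameter")
    v <- log10(v)
  }
  rdm(abs(outer(v, v, "-")), words$token)
}

scale_rdm_unit <- function(x) {
  v <- rdm_vec(x)
  rng <- range(v)
  if (diff(rng) == 0) {
    abort("Cannot min-max scale a constant (zero-range) RDM.", class = "lexrsa_error_degenerate")
  }
  m <- (unclass(as.matrix(x)) - rng[1]) / diff(rng)
  diag(m) <- 0
  rdm(m, rdm_labels(x))
}

#' Average confound RDMs on a common scale
#'
#' Nuisance matrices (lexical frequency, word length) live on
#' incommensurate scales, so each input RDM is first min-max scaled to
#' `[0, 1]` over its off-diagonal entries and the scaled matrices are
#' then averaged entrywise.
#'
#' @param rdms List of [rdm] objects with identical labels.
#' @return The combined confound [rdm].
#' @export
combine_confounds <- function(rdms) {
  if (!length(rdms)) abort("Need at least one RDM.", class = "lexrsa_error_parameter")
  purrr::walk(rdms, function(r) check_same_labels(rdms[[1]], r))
  scaled <- purrr::map(rdms, scale_rdm_unit)
  m <- Reduce(`+`, purrr::map(scaled, function(r) unclass(as.matrix(r)))) / length(scaled)
  rdm(m, rdm_labels(rdms[[1]]))
}

#' Classical (Torgerson) multidimensional scaling of an RDM
#'
#' Double-centers the squared dissimilarities and returns the top-`k`
#' eigencoordinates. When the RDM is Euclidean-embeddable in `k`
#' dimensions the recovered coordinates reproduce it exactly (up to
#' rotation/reflection); negative eigenvalues are clipped to zero with a
#' warning, and missing dimensions are padded with zero columns.
#'
#' @param x An [rdm].
#' @param k Target dimension, `1 <= k < n`.
#' @return A tibble with columns `label`, `dim1` ... `dimk`.
#' @export
classical_mds <- function(x, k) {
  stopifnot(is_rdm(x))
  n <- nrow(x)
  if (k < 1 || k >= n) abort("Require 1 <= k < number of conditions.", class = "lexrsa_error_parameter")
  fit <- suppressWarnings(cmdscale(stats::as.dist(unclass(as.matrix(x))), k = k, eig = TRUE))
  if (any(fit$eig < -1e-8 * max(abs(fit$eig), 1))) {
    warn("RDM is not Euclidean-embeddable: negative eigenvalues clipped to zero.")
  }
  pts <- fit$points
  if (is.null(pts) || ncol(pts) < k) {
    pad <- matrix(0, n, k - if (is.null(pts)) 0L else ncol(pts))
    pts <- cbind(pts, pad)
  }
  out <- tibble::as_tibble(as.data.frame(pts), .name_repair = "minimal")
  names(out) <- paste0("dim", seq_len(k))
  dplyr::bind_cols(tibble::tibble(label = rdm_labels(x)), out)
}

#' Check that two model RDMs are decorrelated
#'
#' Stimulus-design check: word sets are chosen under the constraint that
#' the orthographic and semantic model matrices are not correlated, so
#' that second-order effects can be attributed to one dimension or the
#' other. Reports the Spearman correlation of the two RDMs together with
#' a permutation p-value obtained by permuting condition labels of one
#' matrix; the design passes when the correlation is *not* significant
#' (`p > alpha`).
#'
#' @param orth,sem [rdm] objects with identical labels, `n >= 4`.
#' @param alpha Significance threshold, default `0.05`.
#' @param n_perm Number of label permutations, default `1000`.
#' @return A one-row tibble: `rho`, `p_perm`, `alpha`, `pass`.
#' @export
design_check <- function(orth, sem, alpha = 0.05, n_perm = 1000) {
  check_same_labels(orth, sem)
  n <- nrow(orth)
  if (n < 4) abort("Permutation null degenerate below 4 conditions.", class = "lexrsa_error_parameter")
  rho <- rdm_correlate(orth, sem, method = "spearman")
  vo <- rank(rdm_vec(orth))
  ms <- unclass(as.matrix(sem))
  stat <- abs(rho)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    vp <- rdm_vec(rdm(ms[idx, idx], rdm_labels(sem), allow_negative = TRUE))
    r <- cor(vo, rank(vp))
    if (abs(r) >= stat - 1e-12) exceed <- exceed + 1L
  }
  p_perm <- (exceed + 1L) / (n_perm + 1L)
  tibble::tibble(rho = rho, p_perm = p_perm, alpha = alpha, pass = p_perm > alpha)
}
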