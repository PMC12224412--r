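# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the package implementation.

# Position-weighted edit distance by exhaustive enumeration of monotone
# alignment paths (no DP table): the cost of consuming position i of
# string a (or j of b) is w if it is the first or last position.
oracle_weighted_edit <- function(a, b, w) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  na <- length(av)
  nb <- length(bv)
  cost_a <- function(i) if (i == 1 || i == na) w else 1
  cost_b <- function(j) if (j == 1 || j == nb) w else 1
  rec <- function(i, j) {
    if (i > na && j > nb) return(0)
    best <- Inf
    if (i <= na) best <- min(best, cost_a(i) + rec(i + 1, j))
    if (j <= nb) best <- min(best, cost_b(j) + rec(i, j + 1))
    if (i <= na && j <= nb) {
      sub <- if (av[i] == bv[j]) 0 else max(cost_a(i), cost_b(j))
      best <- min(best, sub + rec(i + 1, j + 1))
    }
    best
  }
  rec(1, 1)
}

# Exact two-sided signed-rank p-value by full 2^n sign enumeration.
oracle_signed_rank_p <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  v_obs <- sum(r[x > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  v_all <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Partial correlation of ranks from the precision matrix of the
# rank-correlation matrix (matrix-inversion route, no residualization).
oracle_partial_spearman <- function(x, y, confounds) {
  vars <- cbind(rank(x), rank(y), vapply(confounds, rank, numeric(length(x))))
  prec <- solve(cor(vars))
  -prec[1, 2] / sqrt(prec[1, 1] * prec[2, 2])
}

# Benjamini-Hochberg by the textbook step-up formula.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Cross-validated distance by an explicit per-pair loop.
oracle_crossval <- function(patterns, partitions) {
  labs <- rownames(patterns[[1]])
  n <- length(labs)
  nv <- ncol(patterns[[1]])
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      vals <- numeric(nrow(partitions))
      for (p in seq_len(nrow(partitions))) {
        xt <- patterns[[partitions$train[p]]]
        xs <- patterns[[partitions$test[p]]]
        vals[p] <- sum((xt[a, ] - xt[b, ]) * (xs[a, ] - xs[b, ])) / nv
      }
      d[a, b] <- mean(vals)
    }
  }
  d
}

random_word <- function(min_len = 0, max_len = 8) {
  len <- sample(min_len:max_len, 1)
  paste(sample(letters[1:6], len, replace = TRUE), collapse = "")
}

# tiny word table for model tests
toy_words <- function() {
  tibble::tibble(
    token = c("arc", "art", "sea", "lake", "tart"),
    category = c("art", "art", "water", "water", "art"),
    freq_pm = c(5, 50, 12, 3, 20)
  )
}

toy_embeddings <- function(dim = 3, seed = 7) {
  set.seed(seed)
  words <- toy_words()
  emb <- tibble::as_tibble(
    as.data.frame(matrix(rnorm(nrow(words) * dim), nrow(words), dim)),
    .name_repair = "minimal"
  )
  names(emb) <- paste0("v", seq_len(dim))
  dplyr::bind_cols(tibble::tibble(token = words$token), emb)
}
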