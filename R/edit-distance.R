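#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions, and
#' substitutions needed to turn one string into another. This is the
#' classic orthographic distance used to quantify visual word similarity:
#' words one substitution apart ("shirt"/"short") are orthographic
#' neighbours, unrelated words are far.
#'
#' @param a,b Character scalars. Empty strings are allowed.
#' @return Integer edit distance; `0` if and only if `a == b`.
#' @examples
#' levenshtein("shirt", "ship")   # 2
#' levenshtein("", "abc")         # 3
#' @seealso [weighted_levenshtein()] for the position-weighted variant
#'   used to build orthographic model RDMs.
#' @export
levenshtein <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  as.integer(weighted_levenshtein(a, b, w_edge = 1))
}

#' Position-weighted Levenshtein distance
#'
#' Edit distance in which any operation that consumes the first or the
#' last character position of either string costs `w_edge` instead of 1.
#' Exact matches always cost 0, so two words sharing their initial and
#' final letters are *relatively* closer under `w_edge > 1` than under the
#' plain distance: the weighting penalises edits at word edges, where
#' letter identity is known to matter most for visual word recognition.
#'
#' With `w_edge = 1` this reduces exactly to [levenshtein()], and for any
#' `w_edge >= 1` the weighted distance is `>=` the unweighted one.
#'
#' @param a,b Character scalars.
#' @param w_edge Cost multiplier for edits at the first/last position of
#'   either string; must be `>= 1`. Default `2`.
#' @return Non-negative numeric distance, symmetric in `a` and `b`.
#' @examples
#' weighted_levenshtein("art", "tart", w_edge = 2)
#' weighted_levenshtein("shirt", "ship", w_edge = 1)  # == levenshtein
#' @export
weighted_levenshtein <- function(a, b, w_edge = 2) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  if (!is.numeric(w_edge) || length(w_edge) != 1L || is.na(w_edge) || w_edge < 1) {
    abort("`w_edge` must be a single number >= 1.", class = "lexrsa_error_parameter")
  }
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  na <- length(av)
  nb <- length(bv)
  # per-position operation costs: edge positions (first or last) cost w_edge
  ca <- if (na > 0) ifelse(seq_len(na) == 1L | seq_len(na) == na, w_edge, 1) else numeric(0)
  cb <- if (nb > 0) ifelse(seq_len(nb) == 1L | seq_len(nb) == nb, w_edge, 1) else numeric(0)
  d <- matrix(0, na + 1L, nb + 1L)
  d[, 1L] <- c(0, cumsum(ca))
  d[1L, ] <- c(0, cumsum(cb))
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      sub_cost <- if (av[i] == bv[j]) 0 else max(ca[i], cb[j])
      d[i + 1L, j + 1L] <- min(
        d[i, j + 1L] + ca[i],     # delete a[i]
        d[i + 1L, j] + cb[j],     # insert b[j]
        d[i, j] + sub_cost        # substitute / match
      )
    }
  }
  d[na + 1L, nb + 1L]
}
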