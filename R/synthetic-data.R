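#' Configuration for the synthetic dataset generator
#'
#' Collects every knob of the generator in one validated list. The
#' defaults mirror the design of the word-reading experiment the package
#' targets: 33 words from 2 semantic categories, 4 scanning runs with 3
#' repetitions of each word per run plus as many hash-mark baseline
#' trials, a repetition time of 1.23 s, and per-region pattern matrices
#' of 150 voxels.
#'
#' The planted representational geometry of the patterns is a weighted
#' mixture of the semantic and orthographic model RDMs
#' (`w_sem`, `w_orth`), embedded in `latent_dim` dimensions; run-level
#' Gaussian noise with standard deviation `noise_sd` (on the scale of
#' the per-voxel signal, which has approximately unit variance across
#' conditions) is added independently per run. Two subject groups with
#' different mixture weights can be requested via `groups`.
#'
#' @param n_words Number of word conditions (default 33).
#' @param n_categories Number of semantic categories (default 2).
#' @param n_runs Number of runs (default 4).
#' @param n_repetitions Repetitions of each word per run (default 3).
#' @param n_voxels Voxels per simulated region (default 150).
#' @param latent_dim Dimension of the latent geometry embedding (default 8).
#' @param embedding_dim Dimension of the word embedding vectors (default 2,
#'   the conventional dimensionality of visualisation embeddings).
#' @param w_sem,w_orth Non-negative mixture weights of the semantic and
#'   orthographic geometry (defaults 0.5 / 0.5).
#' @param noise_sd Run-level Gaussian noise SD, `> 0` (default 8; on the
#'   scale of the per-voxel signal this is a realistically low per-voxel
#'   SNR, yielding subject-level second-order correlations of roughly
#'   0.1-0.4 against the planted model, the magnitude seen in practice).
#' @param n_subjects Subjects per group (default 20).
#' @param groups Optional named list of per-group overrides, each a list
#'   with elements `w_sem` and/or `w_orth`, e.g.
#'   `list(control = list(w_sem = 0.8), dyslexic = list(w_sem = 0.4))`.
#'   `NULL` (default) simulates a single group `"all"`.
#' @param tr Repetition time in seconds (default 1.23).
#' @param w_edge Edge weighting of the orthographic distance (default 2).
#' @param metric Distance metric for the semantic RDM.
#' @param rho_max Decorrelation constraint: maximum absolute
#'   confound-partialled Spearman correlation tolerated between the
#'   generated orthographic and semantic model RDMs (default 0.01);
#'   embeddings are redrawn until the constraint holds, mirroring the
#'   stimulus-selection rule that the two model matrices be
#'   uncorrelated. The default keeps residual model overlap an order of
#'   magnitude below subject-level sampling variability, so null models
#'   stay null at the group level.
#' @param max_tries Redraw budget for the decorrelation constraint.
#' @param seed Integer seed fixing the full output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_words = 33, n_categories = 2, n_runs = 4,
                       n_repetitions = 3, n_voxels = 150, latent_dim = 8,
                       embedding_dim = 2, w_sem = 0.5, w_orth = 0.5,
                       noise_sd = 8, n_subjects = 20, groups = NULL,
                       tr = 1.23, w_edge = 2,
                       metric = c("euclidean", "cosine"),
                       rho_max = 0.01, max_tries = 100, seed = 1L) {
  metric <- match.arg(metric)
  cfg <- list(
    n_words = as.integer(n_words), n_categories = as.integer(n_categories),
    n_runs = as.integer(n_runs), n_repetitions = as.integer(n_repetitions),
    n_voxels = as.integer(n_voxels), latent_dim = as.integer(latent_dim),
    embedding_dim = as.integer(embedding_dim),
    w_sem = w_sem, w_orth = w_orth, noise_sd = noise_sd,
    n_subjects = as.integer(n_subjects), groups = groups, tr = tr,
    w_edge = w_edge, metric = metric, rho_max = rho_max,
    max_tries = as.integer(max_tries), seed = as.integer(seed)
  )
  counts <- c("n_words", "n_categories", "n_runs", "n_repetitions",
              "n_voxels", "latent_dim", "embedding_dim", "n_subjects")
  if (any(vapply(cfg[counts], function(x) x < 1L, logical(1)))) {
    abort("All counts in the simulation config must be >= 1.", class = "lexrsa_error_parameter")
  }
  if (cfg$w_sem < 0 || cfg$w_orth < 0) abort("Mixture weights must be >= 0.", class = "lexrsa_error_parameter")
  if (cfg$noise_sd <= 0) abort("`noise_sd` must be > 0.", class = "lexrsa_error_parameter")
  if (cfg$tr <= 0) abort("`tr` must be > 0.", class = "lexrsa_error_parameter")
  if (cfg$n_words < 4) abort("Need at least 4 words.", class = "lexrsa_error_parameter")
  if (!is.null(groups)) {
    if (is.null(names(groups)) || any(names(groups) == "")) {
      abort("`groups` must be a named list.", class = "lexrsa_error_parameter")
    }
    bad <- purrr::map_lgl(groups, function(g) length(setdiff(names(g), c("w_sem", "w_orth"))) > 0)
    if (any(bad)) abort("Group overrides may only set `w_sem`/`w_orth`.", class = "lexrsa_error_parameter")
  }
  structure(cfg, class = "sim_config")
}

# deterministic derived seeds, kept inside 32-bit integer range
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) + 104729 * as.double(index)) %% 2147483647)
}

random_token <- function(len) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

#' Generate a synthetic word set with embeddings
#'
#' Draws random letter strings (lengths 2-10, centered on realistic word
#' lengths), assigns them evenly to semantic categories, plants
#' orthographic neighbour pairs (single middle-letter substitutions)
#' across category boundaries so that orthographic and semantic
#' similarity cut across each other, samples log-normal lexical
#' frequencies, and draws embedding vectors as category-centered
#' Gaussian clusters so the semantic RDM carries category structure.
#'
#' Embeddings are redrawn (against the fixed token set) until the
#' orthographic and semantic model RDMs satisfy the decorrelation
#' constraint `|partial spearman| <= rho_max`, with the frequency and
#' length confounds partialled out — the same quantity the downstream
#' analysis computes — emulating the stimulus-selection rule that the
#' two theoretical matrices be uncorrelated. The achieved correlation
#' and the number of draws are reported.
#'
#' @param cfg A [sim_config()].
#' @return A list: `words` (tibble), `embeddings` (tibble), `orth` and
#'   `sem` ([rdm]s), `rho_orth_sem`, `tries`.
#' @export
make_wordset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_words
  cats <- paste0("cat", seq_len(cfg$n_categories))
  category <- rep_len(cats, n)
  for (try in seq_len(cfg$max_tries)) {
    lens <- pmin(pmax(round(rnorm(n, mean = 6.85, sd = 1.7)), 2L), 10L)
    tokens <- character(n)
    ok <- TRUE
    for (i in seq_len(n)) {
      for (attempt in 1:50) {
        tok <- random_token(lens[i])
        if (!tok %in% tokens[seq_len(i - 1L)]) break
      }
      if (tok %in% tokens[seq_len(i - 1L)]) {
        ok <- FALSE
        break
      }
      tokens[i] <- tok
    }
    if (!ok) next
    # plant cross-category orthographic neighbours: single-letter substitution
    n_pairs <- max(1L, n %/% 8L)
    donors <- which(category == cats[1] & lens >= 3L)
    receivers <- which(category != cats[1])
    n_pairs <- min(n_pairs, length(donors), length(receivers))
    planted <- integer(0)
    for (p in seq_len(n_pairs)) {
      d <- donors[p]
      r <- receivers[p]
      base <- strsplit(tokens[d], "")[[1]]
      for (attempt in 1:50) {
        inner <- 2:(length(base) - 1L)
        pos <- if (length(inner) == 1L) inner else sample(inner, 1L)
        cand <- base
        cand[pos] <- sample(setdiff(letters, base[pos]), 1L)
        cand <- paste(cand, collapse = "")
        if (!cand %in% tokens) break
      }
      if (cand %in% tokens) next
      tokens[r] <- cand
      planted <- c(planted, d, r)
    }
    if (anyDuplicated(tokens)) next
    freq <- pmin(pmax(rlnorm(n, meanlog = 2.7, sdlog = 1.1), 1), 150)
    words <- validate_words(tibble::tibble(
      token = tokens, category = category, freq_pm = freq
    ))
    orth <- orth_rdm(words, w_edge = cfg$w_edge)
    # the selection constraint targets the same quantity the analysis
    # uses: orth~sem rank correlation with the confounds partialled out;
    # embeddings (the cheap component) are redrawn against the fixed
    # token set until the constraint holds
    conf <- purrr::map(
      list(confound_rdm(words, "freq_pm"), confound_rdm(words, "length")),
      rdm_vec
    )
    ov <- rdm_vec(orth)
    for (etry in seq_len(cfg$max_tries)) {
      centers <- matrix(rnorm(cfg$n_categories * cfg$embedding_dim, sd = 2),
        cfg$n_categories, cfg$embedding_dim
      )
      emb <- centers[match(category, cats), , drop = FALSE] +
        matrix(rnorm(n * cfg$embedding_dim), n, cfg$embedding_dim)
      embeddings <- tibble::as_tibble(as.data.frame(emb), .name_repair = "minimal")
      names(embeddings) <- paste0("v", seq_len(cfg$embedding_dim))
      embeddings <- dplyr::bind_cols(tibble::tibble(token = tokens), embeddings)
      sem <- sem_rdm(words, embeddings, metric = cfg$metric)
      rho <- partial_spearman(ov, rdm_vec(sem), conf)
      if (abs(rho) <= cfg$rho_max) {
        return(list(
          words = words, embeddings = embeddings, orth = orth, sem = sem,
          rho_orth_sem = rho, tries = (try - 1L) * cfg$max_tries + etry
        ))
      }
    }
  }
  abort(sprintf(
    "Could not satisfy the model decorrelation constraint |rho| <= %.3f in %d tries.",
    cfg$rho_max, cfg$max_tries
  ), class = "lexrsa_error_design")
}

#' Generate per-run trial schedules
#'
#' Builds a fast event-related schedule per run: every word appears
#' `n_repetitions` times plus `n_words` hash-mark baseline trials, in
#' pseudo-random order. Each trial is a 350 ms fixation, a 700 ms blank,
#' a 700 ms stimulus, and a blank inter-trial jitter drawn uniformly
#' from 550-1550 ms, so consecutive stimulus onsets are at least 2.3 s
#' apart. Onsets are stimulus onsets, in seconds from run start.
#'
#' @param cfg A [sim_config()].
#' @param tokens Word tokens to schedule; defaults to placeholder labels
#'   `w01...` when no word set is supplied.
#' @return An event tibble: `onset`, `duration`, `condition`, `run`,
#'   with `condition == "baseline"` for hash-mark trials.
#' @export
schedule_runs <- function(cfg = sim_config(), tokens = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(tokens)) tokens <- sprintf("w%02d", seq_len(cfg$n_words))
  if (length(tokens) != cfg$n_words) {
    abort("`tokens` must have length `n_words`.", class = "lexrsa_error_parameter")
  }
  purrr::map_dfr(seq_len(cfg$n_runs), function(r) {
    trial_conditions <- sample(c(
      rep(tokens, times = cfg$n_repetitions),
      rep("baseline", cfg$n_words)
    ))
    n_trials <- length(trial_conditions)
    jitter <- runif(n_trials, 0.55, 1.55)
    # trial = fixation .35 + blank .70 + stimulus .70 + jitter
    trial_dur <- 0.35 + 0.70 + 0.70 + jitter
    trial_start <- c(0, cumsum(trial_dur[-n_trials]))
    tibble::tibble(
      onset = trial_start + 0.35 + 0.70,
      duration = 0.70,
      condition = trial_conditions,
      run = r
    )
  })
}

#' Embed a semantic/orthographic mixture geometry
#'
#' Forms the target dissimilarity structure
#' `D* = w_sem * scale(sem) + w_orth * scale(orth)` (each component
#' scaled by its largest dissimilarity so the weights are comparable)
#' and embeds
#' it in `latent_dim` dimensions by classical MDS. The returned latent
#' coordinates are rescaled to unit mean squared norm; their pairwise
#' distances track `D*` closely (rank correlation near 1 for
#' `latent_dim >= 8` at 33 conditions), so patterns generated from them
#' carry the requested representational geometry by construction.
#'
#' @param sem,orth Model [rdm]s sharing labels.
#' @param w_sem,w_orth Non-negative mixture weights, not both zero.
#' @param latent_dim Embedding dimension.
#' @return Numeric matrix `n x latent_dim` with condition rownames; the
#'   mixture RDM is attached as attribute `"target"`.
#' @export
plant_geometry <- function(sem, orth, w_sem, w_orth, latent_dim = 8) {
  check_same_labels(sem, orth)
  if (w_sem < 0 || w_orth < 0) abort("Weights must be >= 0.", class = "lexrsa_error_parameter")
  if (w_sem + w_orth <= 0) abort("At least one mixture weight must be positive.", class = "lexrsa_error_parameter")
  # components are scaled by their largest dissimilarity (not min-max):
  # pure scaling keeps a Euclidean-embeddable component exactly
  # embeddable, so a single-component mixture is reproduced distortion-free
  scale_max <- function(x) {
    v <- rdm_vec(x)
    if (max(v) == 0) abort("Cannot scale an all-zero RDM.", class = "lexrsa_error_degenerate")
    unclass(as.matrix(x)) / max(v)
  }
  target <- w_sem * scale_max(sem) + w_orth * scale_max(orth)
  target <- rdm(target, rdm_labels(sem))
  # mixture RDMs are generically non-Euclidean: clipping the negative
  # eigenvalue mass is part of the embedding, so the MDS warning is muted
  coords <- suppressWarnings(classical_mds(target, k = latent_dim))
  x <- as.matrix(coords[, -1])
  rownames(x) <- coords$label
  msn <- mean(rowSums(x^2))
  if (msn > 0) x <- x / sqrt(msn)
  attr(x, "target") <- target
  x
}

#' Simulate multi-run voxel patterns from a latent geometry
#'
#' Maps the latent condition coordinates into voxel space through one
#' fixed random linear map per subject (shared across runs, so
#' cross-validated distances estimate the latent geometry without bias)
#' and adds independent Gaussian run-level noise.
#'
#' @param latent Latent coordinate matrix from [plant_geometry()].
#' @param cfg A [sim_config()] supplying `n_voxels`, `n_runs`, `noise_sd`.
#' @param seed Subject-level seed; fixes map and noise.
#' @return List of `n_runs` pattern matrices (conditions x voxels, with
#'   condition rownames).
#' @export
simulate_patterns <- function(latent, cfg = sim_config(), seed = 1L) {
  stopifnot(is.matrix(latent), all(is.finite(latent)))
  if (cfg$n_voxels < ncol(latent)) {
    abort("`n_voxels` must be >= the latent dimension.", class = "lexrsa_error_parameter")
  }
  set.seed(seed)
  map <- matrix(rnorm(ncol(latent) * cfg$n_voxels), ncol(latent), cfg$n_voxels)
  signal <- latent %*% map
  lapply(seq_len(cfg$n_runs), function(r) {
    p <- signal + matrix(rnorm(length(signal), sd = cfg$noise_sd),
      nrow(signal), ncol(signal)
    )
    rownames(p) <- rownames(latent)
    p
  })
}

#' Simulate a full multi-subject dataset
#'
#' End-to-end generator: word set and embeddings, model RDMs, planted
#' mixture geometry per group, and per-subject multi-run pattern
#' matrices. Ground-truth mixture weights are stored per subject so
#' recovery can be tested. All randomness derives from `cfg$seed`;
#' subject seeds are derived deterministically.
#'
#' @param cfg A [sim_config()]. When `cfg$groups` is `NULL` a single
#'   group `"all"` with the global weights is simulated.
#' @return A list of class `lexrsa_dataset`: `words`, `embeddings`,
#'   `orth`, `sem`, `rho_orth_sem`, `config`, and `subjects` — a tibble
#'   with columns `subject`, `group`, `w_sem`, `w_orth`, `patterns`
#'   (list-column of per-run pattern matrices).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ws <- make_wordset(cfg)
  groups <- cfg$groups %||% list(all = list())
  latents <- purrr::map(groups, function(g) {
    plant_geometry(ws$sem, ws$orth,
      w_sem = g$w_sem %||% cfg$w_sem,
      w_orth = g$w_orth %||% cfg$w_orth,
      latent_dim = cfg$latent_dim
    )
  })
  idx <- 0L
  subjects <- purrr::map_dfr(seq_along(groups), function(gi) {
    gname <- names(groups)[gi]
    g <- groups[[gi]]
    purrr::map_dfr(seq_len(cfg$n_subjects), function(si) {
      idx <<- idx + 1L
      sseed <- derive_seed(cfg$seed, idx)
      pats <- simulate_patterns(latents[[gi]], cfg, seed = sseed)
      tibble::tibble(
        subject = sprintf("sub-%s%02d", gname, si),
        group = gname,
        w_sem = g$w_sem %||% cfg$w_sem,
        w_orth = g$w_orth %||% cfg$w_orth,
        seed = sseed,
        patterns = list(pats)
      )
    })
  })
  structure(list(
    words = ws$words, embeddings = ws$embeddings, orth = ws$orth,
    sem = ws$sem, rho_orth_sem = ws$rho_orth_sem, config = cfg,
    subjects = subjects
  ), class = "lexrsa_dataset")
}

#' @export
print.lexrsa_dataset <- function(x, ...) {
  cat(sprintf(
    "<lexrsa_dataset: %d words, %d runs, %d subjects (%s)>\n",
    x$config$n_words, x$config$n_runs, nrow(x$subjects),
    paste(unique(x$subjects$group), collapse = ", ")
  ))
  cat(sprintf("  orth~sem model correlation: %.3f\n", x$rho_orth_sem))
  invisible(x)
}

#' Simulate an event-related BOLD series for one run
#'
#' Generates voxel time series as the linear superposition of
#' HRF-convolved condition regressors weighted by each condition's voxel
#' amplitude pattern, plus white noise: the forward model that the GLM
#' estimation stage inverts. Conditions without a row in `amplitudes`
#' (e.g. `"baseline"`) contribute no signal.
#'
#' @param events Event tibble for a single run (`onset`, `duration`,
#'   `condition`).
#' @param amplitudes Condition-by-voxel amplitude matrix with condition
#'   rownames.
#' @param tr Repetition time, seconds.
#' @param noise_sd White-noise SD added to every scan/voxel (default 0).
#' @param hrf HRF parameters, see [hrf_params()].
#' @return A list: `series` (scans x voxels matrix), `tr`, `n_scans`.
#' @export
simulate_bold <- function(events, amplitudes, tr = 1.23, noise_sd = 0,
                          hrf = hrf_params()) {
  events <- validate_events(events, single_run = TRUE)
  stopifnot(is.matrix(amplitudes), !is.null(rownames(amplitudes)))
  n_scans <- ceiling((max(events$onset + events$duration) + 20) / tr)
  conds <- rownames(amplitudes)
  task <- task_regressors(events, n_scans = n_scans, tr = tr, hrf = hrf,
    conditions = intersect(unique(events$condition), conds)
  )
  series <- matrix(0, n_scans, ncol(amplitudes))
  if (ncol(task)) {
    series <- task %*% amplitudes[colnames(task), , drop = FALSE]
  }
  if (noise_sd > 0) {
    series <- series + matrix(rnorm(length(series), sd = noise_sd),
      nrow(series), ncol(series)
    )
  }
  list(series = series, tr = tr, n_scans = n_scans)
}
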