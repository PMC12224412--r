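#' Replicate experiments on synthetic data
#'
#' Three canned simulation experiments that characterise the pipeline's
#' statistical behaviour, each running the full chain (word set,
#' planted geometry, patterns, cross-validated neural RDMs,
#' confound-partialled correlations, signed-rank group test) once per
#' replicate with a fresh word set and subjects:
#'
#' * `null_calibration()` — type-I error of the orthographic model test
#'   when the planted geometry contains *no* orthographic component
#'   (`w_orth = 0`): the signed-rank rejection rate at `alpha` should
#'   match `alpha`.
#' * `recovery_grid()` — recovery of the semantic mixture weight: group
#'   mean correlation against the semantic model across a grid of
#'   `w_sem` values, paired within each replicate (one word set shared
#'   by all grid points, so the comparison is made at fixed stimulus
#'   conditions) and expected to increase strictly with `w_sem`.
#' * `separation_power()` — power to separate two groups differing only
#'   in `w_sem` with a between-group t-test on the semantic-model
#'   correlations.
#'
#' @param n_reps Number of replicate experiments.
#' @param cfg Base [sim_config()]; per-replicate seeds are derived from
#'   `cfg$seed`.
#' @param alpha Rejection threshold.
#' @return A tibble with one row per replicate (and grid point, for
#'   `recovery_grid()`).
#' @name lexrsa_experiments
NULL

replicate_cfg <- function(cfg, rep, ...) {
  over <- list(...)
  args <- unclass(cfg)
  args$groups <- NULL
  args[names(over)] <- over
  args$seed <- derive_seed(cfg$seed, 7 * rep + 3)
  do.call(sim_config, args)
}

subject_rhos <- function(ds, model_vec, conf_vecs) {
  vapply(ds$subjects$patterns, function(p) {
    nr <- crossval_euclidean_rdm(remove_dead_voxels(p)$patterns)
    partial_spearman(rdm_vec(nr), model_vec, conf_vecs)
  }, numeric(1))
}

dataset_confounds <- function(ds) {
  purrr::map(
    list(confound_rdm(ds$words, "freq_pm"), confound_rdm(ds$words, "length")),
    rdm_vec
  )
}

#' @rdname lexrsa_experiments
#' @export
null_calibration <- function(n_reps = 100, cfg = sim_config(w_sem = 1, w_orth = 0),
                             alpha = 0.05) {
  if (cfg$w_orth != 0) abort("Null calibration requires `w_orth = 0`.", class = "lexrsa_error_parameter")
  purrr::map_dfr(seq_len(n_reps), function(r) {
    ds <- simulate_dataset(replicate_cfg(cfg, r))
    rhos <- subject_rhos(ds, rdm_vec(ds$orth), dataset_confounds(ds))
    st <- signed_rank_test(rhos)
    tibble::tibble(
      rep = r, mean_rho = mean(rhos), p_value = st$p_value,
      reject = st$p_value < alpha
    )
  })
}

#' @rdname lexrsa_experiments
#' @param w_sem_values Grid of semantic mixture weights (the
#'   orthographic weight stays at `cfg$w_orth`).
#' @export
recovery_grid <- function(n_reps = 50, w_sem_values = c(0.2, 0.5, 0.8),
                          cfg = sim_config()) {
  purrr::map_dfr(seq_len(n_reps), function(r) {
    rcfg <- replicate_cfg(cfg, r)
    set.seed(rcfg$seed)
    ws <- make_wordset(rcfg)
    conf <- purrr::map(
      list(confound_rdm(ws$words, "freq_pm"), confound_rdm(ws$words, "length")),
      rdm_vec
    )
    sv <- rdm_vec(ws$sem)
    purrr::map_dfr(seq_along(w_sem_values), function(k) {
      lat <- plant_geometry(ws$sem, ws$orth,
        w_sem = w_sem_values[k], w_orth = rcfg$w_orth, latent_dim = rcfg$latent_dim
      )
      rhos <- vapply(seq_len(rcfg$n_subjects), function(i) {
        p <- simulate_patterns(lat, rcfg, seed = derive_seed(rcfg$seed, 1000 * k + i))
        partial_spearman(rdm_vec(crossval_euclidean_rdm(p)), sv, conf)
      }, numeric(1))
      tibble::tibble(rep = r, w_sem = w_sem_values[k], mean_rho = mean(rhos))
    })
  })
}

#' @rdname lexrsa_experiments
#' @param w_sem_a,w_sem_b Semantic weights of the two groups.
#' @export
separation_power <- function(n_reps = 50, w_sem_a = 0.8, w_sem_b = 0.4,
                             cfg = sim_config(), alpha = 0.05) {
  purrr::map_dfr(seq_len(n_reps), function(r) {
    rcfg <- replicate_cfg(cfg, r,
      groups = list(a = list(w_sem = w_sem_a), b = list(w_sem = w_sem_b))
    )
    ds <- simulate_dataset(rcfg)
    conf <- dataset_confounds(ds)
    sv <- rdm_vec(ds$sem)
    rhos <- subject_rhos(ds, sv, conf)
    grp <- ds$subjects$group
    bt <- between_group_test(rhos[grp == "a"], rhos[grp == "b"], method = "ttest")
    tibble::tibble(rep = r, statistic = bt$statistic, p_value = bt$p_value,
      reject = bt$p_value < alpha
    )
  })
}
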