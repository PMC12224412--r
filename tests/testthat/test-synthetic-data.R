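fast_cfg <- function(...) {
  sim_config(n_words = 8, n_voxels = 30, latent_dim = 4, n_subjects = 5, ...)
}

test_that("simulation config validates its fields", {
  expect_error(sim_config(n_words = 0), class = "lexrsa_error_parameter")
  expect_error(sim_config(noise_sd = 0), class = "lexrsa_error_parameter")
  expect_error(sim_config(w_sem = -1), class = "lexrsa_error_parameter")
  expect_error(sim_config(groups = list(list(w_sem = 1))), class = "lexrsa_error_parameter")
  expect_error(sim_config(groups = list(a = list(noise = 1))), class = "lexrsa_error_parameter")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("generated word sets have the requested structure and satisfy decorrelation", {
  cfg <- sim_config(n_words = 16, n_categories = 2, seed = 5)
  set.seed(5)
  ws <- make_wordset(cfg)
  expect_equal(nrow(ws$words), 16)
  expect_equal(as.integer(table(ws$words$category)), c(8L, 8L))
  expect_false(anyDuplicated(ws$words$token) > 0)
  expect_true(all(ws$words$length >= 2 & ws$words$length <= 10))
  expect_true(all(ws$words$freq_pm >= 1))
  expect_lte(abs(ws$rho_orth_sem), cfg$rho_max)
  # planted neighbours: some cross-category pair is much closer than typical
  ov <- unclass(ws$orth)
  cross <- outer(ws$words$category, ws$words$category, "!=")
  expect_lte(min(ov[cross]), cfg$w_edge)
  expect_gt(median(ov[cross & upper.tri(ov)]), min(ov[cross]))
})

test_that("word set generation is reproducible under a fixed seed", {
  cfg <- fast_cfg(seed = 9)
  set.seed(9)
  a <- make_wordset(cfg)
  set.seed(9)
  b <- make_wordset(cfg)
  expect_identical(a$words, b$words)
  expect_identical(a$embeddings, b$embeddings)
})

test_that("run schedules reproduce the design trial counts and timing floors", {
  set.seed(2)
  ev34 <- schedule_runs(sim_config(n_words = 34))
  expect_equal(sum(ev34$run == 1), 136) # 34 words x 3 + 34 baseline
  ev33 <- schedule_runs(sim_config())
  expect_equal(sum(ev33$run == 1), 132) # 33 words x 3 + 33 baseline
  for (r in unique(ev33$run)) {
    on <- ev33$onset[ev33$run == r]
    expect_true(all(diff(on) > 0))
    expect_gte(min(diff(on)), 2.3 - 1e-9)
    expect_lte(max(diff(on)), 3.3 + 1e-9)
  }
  counts <- table(ev33$condition[ev33$run == 2])
  expect_equal(unname(counts[names(counts) != "baseline"]), rep(3L, 33),
    ignore_attr = TRUE
  )
  expect_equal(unname(counts["baseline"]), 33L, ignore_attr = TRUE)
})

test_that("planted geometry tracks the mixture and reproduces embeddable structures exactly", {
  cfg <- sim_config(seed = 3)
  set.seed(3)
  ws <- make_wordset(cfg)
  # pure semantic mixture: latent distances rank-match the semantic RDM
  lat <- plant_geometry(ws$sem, ws$orth, w_sem = 1, w_orth = 0, latent_dim = 8)
  dl <- as.numeric(dist(lat))
  ds <- as.numeric(stats::as.dist(unclass(ws$sem)))
  expect_gte(cor(dl, ds, method = "spearman"), 0.95)
  # mixture RDM with enough latent dimensions: exact round trip
  set.seed(33)
  pts <- matrix(rnorm(10 * 9), 10, 9)
  labs <- sprintf("c%02d", 1:10)
  target <- rdm(as.matrix(dist(pts)), labs)
  lat2 <- plant_geometry(target, target, w_sem = 1, w_orth = 0, latent_dim = 9)
  expect_equal(
    as.matrix(dist(lat2)) / max(dist(lat2)),
    unclass(as.matrix(target)) / max(unclass(target)),
    ignore_attr = TRUE, tolerance = 1e-8
  )
  # symmetric role of the two models under weight swap
  l_ab <- plant_geometry(ws$sem, ws$orth, 0.7, 0.3, 6)
  l_ba <- plant_geometry(ws$orth, ws$sem, 0.3, 0.7, 6)
  expect_equal(as.matrix(dist(l_ab)), as.matrix(dist(l_ba)), tolerance = 1e-8)
  expect_error(plant_geometry(ws$sem, ws$orth, 0, 0), class = "lexrsa_error_parameter")
})

test_that("pattern simulation is deterministic, run-noise controlled, and dimension-checked", {
  cfg <- fast_cfg(seed = 4, noise_sd = 0.5)
  set.seed(4)
  ws <- make_wordset(cfg)
  lat <- plant_geometry(ws$sem, ws$orth, 0.5, 0.5, cfg$latent_dim)
  p1 <- simulate_patterns(lat, cfg, seed = 99)
  p2 <- simulate_patterns(lat, cfg, seed = 99)
  expect_identical(p1, p2)
  expect_length(p1, cfg$n_runs)
  expect_equal(rownames(p1[[1]]), rownames(lat))
  # near-noiseless limit: runs are nearly identical
  cfg0 <- fast_cfg(seed = 4, noise_sd = 1e-9)
  p0 <- simulate_patterns(lat, cfg0, seed = 99)
  expect_lt(max(abs(p0[[1]] - p0[[2]])), 1e-6)
  # empirical run-level noise SD close to the requested value
  cfg_many <- sim_config(
    n_words = 8, n_voxels = 30, latent_dim = 4, n_subjects = 1,
    n_runs = 100, noise_sd = 0.5, seed = 4
  )
  pm <- simulate_patterns(lat, cfg_many, seed = 7)
  arr <- simplify2array(pm)
  resid <- sweep(arr, c(1, 2), apply(arr, c(1, 2), mean))
  expect_equal(sd(resid), 0.5, tolerance = 0.05)
  expect_error(
    simulate_patterns(lat, sim_config(n_words = 8, n_voxels = 2), seed = 1),
    class = "lexrsa_error_parameter"
  )
})

test_that("full dataset simulation stores ground truth and is seed-reproducible", {
  cfg <- fast_cfg(
    seed = 10,
    groups = list(control = list(w_sem = 0.8), dyslexic = list(w_sem = 0.4))
  )
  ds1 <- simulate_dataset(cfg)
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds1$subjects$patterns, ds2$subjects$patterns)
  expect_equal(nrow(ds1$subjects), 10)
  expect_equal(unique(ds1$subjects$group), c("control", "dyslexic"))
  expect_equal(ds1$subjects$w_sem[ds1$subjects$group == "control"], rep(0.8, 5))
  expect_equal(ds1$subjects$w_sem[ds1$subjects$group == "dyslexic"], rep(0.4, 5))
  expect_equal(ds1$subjects$w_orth, rep(0.5, 10))
})

test_that("simulated BOLD is the HRF superposition the GLM expects", {
  amp <- matrix(c(2, -1, 0.5, 3), 2, 2)
  rownames(amp) <- c("w1", "w2")
  ev <- tibble::tibble(
    onset = c(10, 30), duration = 0.7, condition = c("w1", "w2"), run = 1L
  )
  bold <- simulate_bold(ev, amp, tr = 1.0)
  expect_equal(bold$n_scans, ceiling(30.7 + 20))
  # single-event series is proportional to the shifted sampled kernel
  ev1 <- ev[1, ]
  b1 <- simulate_bold(ev1, amp["w1", , drop = FALSE], tr = 1.0)
  v <- b1$series[, 1]
  expect_equal(v[1:10], rep(0, 10)) # nothing before onset
  peak_t <- which.max(v)
  expect_gt(peak_t, 10)
  expect_lt(peak_t, 22)
  expect_equal(cor(b1$series[, 1], b1$series[, 2] * sign(amp["w1", 2] * amp["w1", 1])), 1)
  # zero amplitudes -> pure noise at the stated SD
  set.seed(8)
  zero <- matrix(0, 2, 50, dimnames = list(c("w1", "w2"), NULL))
  bn <- simulate_bold(ev, zero, tr = 1.0, noise_sd = 2)
  expect_equal(sd(bn$series), 2, tolerance = 0.1)
})
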