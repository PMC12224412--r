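test_that("partial Spearman equals plain Spearman with no confounds", {
  set.seed(101)
  for (i in 1:100) {
    x <- rnorm(20)
    y <- rnorm(20)
    expect_equal(
      partial_spearman(x, y),
      cor(x, y, method = "spearman"),
      tolerance = 1e-12
    )
  }
  expect_equal(partial_spearman(1:10, 1:10), 1)
})

test_that("partial Spearman matches the precision-matrix oracle with confounds", {
  set.seed(102)
  for (i in 1:50) {
    n <- 12
    z1 <- rnorm(n)
    z2 <- rnorm(n)
    x <- z1 + rnorm(n)
    y <- z1 - 0.5 * z2 + rnorm(n)
    expect_equal(
      partial_spearman(x, y, list(z1, z2)),
      oracle_partial_spearman(x, y, list(z1, z2)),
      tolerance = 1e-10
    )
  }
  # hand-set 8-element vectors with one confound
  x <- c(3, 1, 4, 1.5, 5, 9, 2, 6)
  y <- c(2, 7, 1, 8, 2.5, 8.5, 3, 4)
  z <- c(1, 2, 3, 4, 5, 6, 7, 8)
  expect_equal(
    partial_spearman(x, y, list(z)),
    oracle_partial_spearman(x, y, list(z)),
    tolerance = 1e-10
  )
  # a model fully explained by the confound is degenerate
  expect_error(partial_spearman(x, z, list(z)), class = "lexrsa_error_degenerate")
  expect_error(partial_spearman(1:3, 1:3), class = "lexrsa_error_parameter")
})

test_that("signed-rank test reproduces exact enumeration and drops zeros", {
  expect_equal(signed_rank_test(c(1, 2, 3, 4, 5))$p_value, 0.0625)
  set.seed(103)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    x <- round(rnorm(n), 2)
    x <- x[x != 0]
    if (length(x) < 5 || any(duplicated(abs(x)))) next
    expect_equal(
      signed_rank_test(x)$p_value,
      oracle_signed_rank_p(x),
      tolerance = 1e-12,
      info = paste(x, collapse = ",")
    )
  }
  # antisymmetric sample sits exactly at the null center
  x_anti <- c(-1, 1, -2, 2, -3, 3)
  expect_equal(signed_rank_test(x_anti)$p_value, 1)
  res <- signed_rank_test(c(0, 0, 1, 2, 3, 4, 5))
  expect_equal(res$n, 5)
  expect_equal(res$n_zero, 2)
  expect_error(signed_rank_test(c(0, 0, 1, 2, 3)), class = "lexrsa_error_parameter")
})

test_that("signed-rank rejection rate is calibrated under the null", {
  set.seed(104)
  p <- replicate(2000, signed_rank_test(rnorm(20))$p_value)
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("between-group tests match published summaries and a permutation oracle", {
  x <- c(1, 2, 3, 4)
  expect_equal(between_group_test(x, x)$statistic, 0)
  expect_equal(between_group_test(x, x)$p_value, 1)
  expect_error(between_group_test(rep(1, 3), rep(1, 3)), class = "lexrsa_error_degenerate")
  # shifted normals: t-test p agrees with a permutation test
  set.seed(105)
  a <- rnorm(20, mean = 0.8)
  b <- rnorm(22)
  bt <- between_group_test(a, b)
  pool <- c(a, b)
  obs <- mean(a) - mean(b)
  perm <- replicate(4000, {
    idx <- sample.int(42, 20)
    mean(pool[idx]) - mean(pool[-idx])
  })
  p_perm <- mean(abs(perm) >= abs(obs))
  expect_lt(abs(bt$p_value - p_perm), 0.02)
  # rank-sum branch
  expect_s3_class(between_group_test(a, b, "ranksum"), "tbl_df")
})

test_that("BH adjustment matches the step-up formula and stays monotone", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.2), 0.2)
  expect_equal(fdr_bh(rep(0.07, 5)), rep(0.07, 5))
  set.seed(106)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))
    q <- fdr_bh(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
  expect_error(fdr_bh(c(0.5, 1.2)), class = "lexrsa_error_parameter")
})

test_that("factorial F-tests reproduce classical ANOVA on balanced designs", {
  # balanced 2x2 with a pure group effect: model F is exactly 0
  d <- expand.grid(group = c("g1", "g2"), model = c("m1", "m2"), rep = 1:4)
  d$rho <- ifelse(d$group == "g1", 1, 2) + 0.1 * (d$rep %% 2) # rep jitter avoids zero residual
  fit <- fit_factorial(d, rho ~ group * model)
  tab <- tidy(fit)
  f_model <- tab$statistic[tab$term == "model"]
  expect_lt(f_model, 1e-20)
  # balanced design: Type II equals classical aov sums of squares
  set.seed(107)
  d$rho <- rnorm(nrow(d)) + as.numeric(d$group == "g1") * 0.5
  fit2 <- fit_factorial(d, rho ~ group * model)
  a <- summary(aov(rho ~ group * model, data = d))[[1]]
  tab2 <- tidy(fit2)
  for (term in c("group", "model", "group:model")) {
    expect_equal(
      tab2$statistic[tab2$term == term],
      a[paste0(trimws(rownames(a))) == term, "F value"],
      tolerance = 1e-10
    )
  }
  expect_equal(unique(tab2$df_residual), nrow(d) - 4)
  # degenerate / aliased inputs are rejected
  d$rho <- 1
  expect_error(fit_factorial(d, rho ~ group * model), class = "lexrsa_error_degenerate")
  d$rho <- rnorm(nrow(d))
  d$dup <- d$group
  expect_error(fit_factorial(d, rho ~ group + dup), class = "lexrsa_error_design")
})

test_that("ANCOVA with a covariate reports covariate and interaction terms", {
  set.seed(108)
  n <- 40
  d <- tibble::tibble(
    group = rep(c("dyslexic", "control"), each = n / 2),
    model = rep(c("SemModel", "OrthModel"), times = n / 2),
    fluency = rnorm(n, 450, 60)
  )
  d$rho <- 0.1 + 0.002 * (d$fluency - 450) +
    0.15 * (d$group == "control" & d$model == "SemModel") + rnorm(n, sd = 0.05)
  fit <- fit_factorial(d, rho ~ group * model + fluency)
  tab <- tidy(fit)
  expect_setequal(tab$term, c("group", "model", "fluency", "group:model"))
  expect_lt(tab$p_value[tab$term == "fluency"], 0.05)
  expect_equal(unique(tab$df_residual), n - 5)
  expect_equal(nrow(glance(fit)), 1)
})

test_that("Tukey post hoc reduces to the t-test at two cells and ranks outliers first", {
  set.seed(109)
  d <- tibble::tibble(
    cell = rep(c("a", "b"), each = 6),
    rho = rnorm(12) + rep(c(0, 0.5), each = 6)
  )
  fit <- fit_factorial(d, rho ~ cell)
  th <- tukey_posthoc(fit, ~cell)
  tt <- summary(fit$fit)$coefficients["cellb", "Pr(>|t|)"]
  expect_equal(th$p_value, tt, tolerance = 1e-10)
  # equal cell means -> adjusted p near 1
  d2 <- tibble::tibble(cell = rep(c("a", "b"), each = 4), rho = rep(c(1, 2, 1, 2), 2))
  expect_equal(tukey_posthoc(fit_factorial(d2, rho ~ cell), ~cell)$p_value, 1)
  # one outlying cell mean dominates the smallest adjusted p-values
  d4 <- tibble::tibble(
    cell = rep(c("a", "b", "c", "d"), each = 5),
    rho = rnorm(20, sd = 0.1) + rep(c(0, 0, 0, 3), each = 5)
  )
  th4 <- tukey_posthoc(fit_factorial(d4, rho ~ cell), ~cell)
  involves_d <- grepl("d", th4$contrast)
  expect_true(max(th4$p_value[involves_d]) < min(th4$p_value[!involves_d]))
})

test_that("subject-level correlations are exact when the neural RDM equals a model", {
  set.seed(110)
  words <- toy_words()
  emb <- toy_embeddings()
  sem <- sem_rdm(words, emb)
  orth <- orth_rdm(words)
  conf <- list(confound_rdm(words, "freq_pm"), confound_rdm(words, "length"))
  neural <- tibble::tibble(
    subject = c("s1", "s2"), group = "all", roi = "sim",
    rdm = list(sem, sem)
  )
  res <- rsa_correlations(neural, list(SemModel = sem, OrthModel = orth), conf)
  expect_equal(res$rho[res$model == "SemModel"], c(1, 1))
  expect_equal(nrow(res), 4)
  expect_true(all(abs(res$rho) <= 1))
})

test_that("group-level inference applies FDR within the declared family", {
  set.seed(111)
  correlations <- tidyr::expand_grid(
    subject = sprintf("s%02d", 1:20),
    roi = c("FG1", "FG2"),
    model = c("SemModel", "OrthModel")
  )
  correlations$group <- rep(c("control", "dyslexic"), each = nrow(correlations) / 2)
  correlations$subject <- paste(correlations$group, correlations$subject)
  correlations$rho <- rnorm(nrow(correlations), sd = 0.1) +
    ifelse(correlations$model == "SemModel" & correlations$group == "control", 0.3, 0)
  gt <- rsa_group_tests(correlations, alpha = 0.05)
  expect_true(all(gt$q_value >= gt$p_value - 1e-12))
  expect_true(all(gt$q_value <= 1))
  # within-family q-values are BH of exactly the family's p-values
  fam <- gt[gt$group == "control" & gt$roi == "FG1", ]
  expect_equal(fam$q_value, fdr_bh(fam$p_value))
  # between-group rows present for the two-group design
  expect_true(any(grepl(" vs ", gt$group)))
  sem_ctrl <- gt[gt$group == "control" & gt$model == "SemModel", ]
  expect_true(all(sem_ctrl$q_value < 0.05))
})

test_that("run_rsa orchestrates models, confounds, and tests end to end", {
  cfg <- sim_config(
    n_words = 10, n_voxels = 30, latent_dim = 4, n_subjects = 6, seed = 112,
    groups = list(control = list(w_sem = 0.9), dyslexic = list(w_sem = 0.2))
  )
  ds <- simulate_dataset(cfg)
  res <- run_rsa(ds)
  expect_s3_class(res, "lexrsa_rsa")
  expect_equal(nrow(res$correlations), 12 * 2)
  expect_equal(nrow(res$group_tests), 6)
  expect_identical(tidy(res), res$correlations)
  expect_identical(glance(res), res$group_tests)
  expect_s3_class(autoplot(res), "ggplot")
})
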