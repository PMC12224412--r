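test_that("rdm constructor enforces shape, symmetry, labels, and finiteness", {
  m <- matrix(c(0, 1, 1, 0), 2)
  r <- rdm(m, c("a", "b"))
  expect_s3_class(r, "rdm")
  expect_error(rdm(matrix(1:6, 2, 3), c("a", "b")), class = "lexrsa_error_rdm")
  expect_error(rdm(m, c("a", "a")), class = "lexrsa_error_rdm")
  expect_error(rdm(matrix(c(0, 1, 2, 0), 2), c("a", "b")), class = "lexrsa_error_rdm")
  expect_error(rdm(matrix(c(1, 1, 1, 1), 2), c("a", "b")), class = "lexrsa_error_rdm")
  expect_error(rdm(matrix(c(0, NA, NA, 0), 2), c("a", "b")), class = "lexrsa_error_rdm")
  expect_error(rdm(matrix(c(0, -1, -1, 0), 2), c("a", "b")), class = "lexrsa_error_rdm")
  expect_silent(rdm(matrix(c(0, -1, -1, 0), 2), c("a", "b"), allow_negative = TRUE))
})

test_that("rdm vectorization is the row-major strict lower triangle and round-trips", {
  m <- matrix(0, 4, 4)
  m[lower.tri(m)] <- c(21, 31, 41, 32, 42, 43) # column-major fill
  m <- m + t(m)
  r <- rdm(m, letters[1:4])
  expect_equal(rdm_vec(r), c(21, 31, 32, 41, 42, 43))
  expect_equal(unclass(as.matrix(rdm_unvec(rdm_vec(r), letters[1:4]))), unclass(as.matrix(r)))
})

test_that("orthographic RDM equals pairwise weighted distances and rejects duplicates", {
  words <- toy_words()
  r <- orth_rdm(words, w_edge = 2)
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_equal(
        unclass(r)[i, j],
        weighted_levenshtein(words$token[i], words$token[j], 2)
      )
    }
  }
  expect_equal(diag(unclass(r)), setNames(rep(0, 5), words$token))
  dup <- words
  dup$token[2] <- dup$token[1]
  expect_error(orth_rdm(dup), class = "lexrsa_error_schema")
})

test_that("semantic RDM computes embedding distances under both metrics", {
  words <- toy_words()[1:3, ]
  emb <- tibble::tibble(
    token = words$token,
    v1 = c(0, 3, 1), v2 = c(0, 4, 1)
  )
  r <- sem_rdm(words, emb)
  expect_equal(unclass(r)["arc", "art"], 5) # 3-4-5 triangle
  # identical vectors -> zero distance
  emb2 <- emb
  emb2$v1 <- c(1, 1, 2)
  emb2$v2 <- c(2, 2, 0)
  expect_equal(unclass(sem_rdm(words, emb2))["arc", "art"], 0)
  # brute-force double loop, 4 random vectors
  set.seed(21)
  w4 <- toy_words()[1:4, ]
  e4 <- toy_embeddings()[1:4, ]
  r4 <- sem_rdm(w4, e4)
  x <- as.matrix(e4[, -1])
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_equal(unclass(r4)[i, j], sqrt(sum((x[i, ] - x[j, ])^2)))
    }
  }
  # cosine metric bounded in [0, 2] and zero on the diagonal
  rc <- sem_rdm(w4, e4, metric = "cosine")
  expect_true(all(unclass(rc) >= 0 & unclass(rc) <= 2))
  # missing vector names the offending token
  expect_error(sem_rdm(toy_words(), e4), regexp = "tart", class = "lexrsa_error_schema")
})

test_that("category RDM is the between-category indicator", {
  words <- toy_words()
  r <- unclass(category_rdm(words))
  expect_equal(r["arc", "art"], 0)
  expect_equal(r["arc", "sea"], 1)
  expect_equal(r["sea", "lake"], 0)
  same <- words
  same$category <- "one"
  expect_true(all(unclass(category_rdm(same)) == 0))
})

test_that("confound RDMs are absolute covariate differences with the stated transforms", {
  w <- tibble::tibble(
    token = c("aa", "bb", "cc"), category = "x",
    freq_pm = c(1, 10, 100), x = c(1, 2, 4)
  )
  r_log <- confound_rdm(w, "freq_pm")
  expect_equal(sort(rdm_vec(r_log)), c(1, 1, 2))
  r_id <- confound_rdm(w, "x")
  expect_equal(sort(rdm_vec(r_id)), c(1, 2, 3))
  w$freq_pm <- c(5, 5, 5)
  expect_true(all(rdm_vec(confound_rdm(w, "freq_pm")) == 0))
  w$x <- c(-1, 2, 4)
  expect_error(confound_rdm(w, "x", transform = "log10"), class = "lexrsa_error_parameter")
})

test_that("confound averaging min-max scales each matrix before combining", {
  labs <- c("a", "b", "c")
  r1 <- rdm_unvec(c(1, 2, 3), labs)
  r2 <- rdm_unvec(c(10, 30, 20), labs)
  combined <- combine_confounds(list(r1, r2))
  # hand computation: scaled r1 = (0, .5, 1), scaled r2 = (0, 1, .5)
  expect_equal(rdm_vec(combined), (c(0, 0.5, 1) + c(0, 1, 0.5)) / 2)
  expect_equal(
    unclass(as.matrix(combine_confounds(list(r1, r1)))),
    unclass(as.matrix(combine_confounds(list(r1))))
  )
  r3 <- rdm_unvec(c(1, 2, 3), c("x", "y", "z"))
  expect_error(combine_confounds(list(r1, r3)), class = "lexrsa_error_labels")
  expect_error(combine_confounds(list(rdm_unvec(c(1, 1, 1), labs))), class = "lexrsa_error_degenerate")
})

test_that("second-order correlation behaves on identity, reversal, and a hand-ranked case", {
  set.seed(31)
  a <- rdm_unvec(runif(6), letters[1:4])
  expect_equal(rdm_correlate(a, a, "spearman"), 1)
  b <- rdm_unvec(2 - rdm_vec(a), letters[1:4])
  expect_equal(rdm_correlate(a, b, "spearman"), -1)
  # hand-set 4x4 pair: ranks computed manually over the 6 pairs
  x <- rdm_unvec(c(1, 2, 3, 4, 5, 6), letters[1:4])
  y <- rdm_unvec(c(2, 1, 4, 3, 6, 5), letters[1:4])
  # rank covariance by hand: sum((rx - 3.5)(ry - 3.5)) = 14.5; var = 17.5
  expect_equal(rdm_correlate(x, y, "spearman"), 14.5 / 17.5)
  expect_equal(rdm_correlate(x, y), rdm_correlate(y, x))
  z <- rdm_unvec(rep(1, 6), letters[1:4])
  expect_error(rdm_correlate(x, z), class = "lexrsa_error_degenerate")
})

test_that("classical MDS recovers collinear and planar configurations", {
  # three points on a line at 0, 1, 2
  line <- rdm(as.matrix(dist(c(0, 1, 2))), c("p", "q", "r"))
  coords <- classical_mds(line, 1)
  d <- as.numeric(dist(coords$dim1))
  expect_equal(sort(d), c(1, 1, 2), tolerance = 1e-10)
  # zero RDM -> all-zero coordinates
  z <- rdm(matrix(0, 3, 3), c("p", "q", "r"))
  expect_true(all(abs(as.matrix(classical_mds(z, 2)[, -1])) < 1e-10))
  # planar round trip
  set.seed(41)
  pts <- matrix(rnorm(8), 4, 2)
  r <- rdm(as.matrix(dist(pts)), letters[1:4])
  rec <- classical_mds(r, 2)
  expect_equal(as.matrix(dist(as.matrix(rec[, -1]))), unclass(as.matrix(r)),
    ignore_attr = TRUE, tolerance = 1e-8
  )
  expect_error(classical_mds(r, 4), class = "lexrsa_error_parameter")
  # non-Euclidean input warns about clipped eigenvalues
  ne <- rdm_unvec(c(1, 1, 1, 1, 1, 10), letters[1:4])
  expect_warning(classical_mds(ne, 2), "Euclidean")
})

test_that("design check fails identical models and passes independent ones at the nominal rate", {
  set.seed(51)
  a <- rdm_unvec(runif(21), letters[1:7])
  res <- design_check(a, a, n_perm = 200)
  expect_equal(res$rho, 1)
  expect_false(res$pass)
  # independent random RDMs: permutation test should usually pass
  passes <- replicate(30, {
    x <- rdm_unvec(runif(66), letters[1:12])
    y <- rdm_unvec(runif(66), letters[1:12])
    design_check(x, y, n_perm = 200)$pass
  })
  expect_gte(mean(passes), 0.85)
  small <- rdm_unvec(runif(3), letters[1:3])
  expect_error(design_check(small, small), class = "lexrsa_error_parameter")
})

test_that("rdm tidiers and plots produce the documented shapes", {
  r <- rdm_unvec(c(1, 2, 3), c("a", "b", "c"))
  td <- tidy(r)
  expect_equal(names(td), c("label_i", "label_j", "value"))
  expect_equal(nrow(td), 3)
  expect_equal(td$value, rdm_vec(r))
  expect_s3_class(autoplot(r), "ggplot")
})
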