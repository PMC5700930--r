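test_that("profile correlation reproduces closed-form cases", {
  set.seed(61)
  z <- rnorm(13)
  zh <- tsp_normalize(z)
  expect_equal(tsp_pearson(zh, zh), 1)
  expect_equal(tsp_pearson(zh, -zh), -1)
  e1 <- c(1, rep(0, 12)); e2 <- c(0, 1, rep(0, 11))
  expect_equal(tsp_pearson(e1, e2), -1 / 12, tolerance = 1e-12)
  # invariant under a common affine rescaling
  expect_equal(tsp_pearson(3 * zh + 0.5, zh), 1, tolerance = 1e-12)
  expect_error(tsp_pearson(rep(1, 13), zh), "constant")
  expect_error(tsp_pearson(zh, zh[1:5]), "different lengths")
})

test_that("profile distance maps r to the chord metric on [0, 2]", {
  expect_equal(tsp_distance(1), 0)
  expect_equal(tsp_distance(-1), 2)
  expect_equal(tsp_distance(0.5), 1)
  expect_equal(tsp_distance(1 + 1e-14), 0)  # clipped within tolerance
  expect_error(tsp_distance(1.01), "outside")
})

test_that("d satisfies the metric axioms on random unit-norm profiles", {
  set.seed(63)
  for (i in 1:50) {
    a <- tsp_normalize(rnorm(13))
    b <- tsp_normalize(rnorm(13))
    c_ <- tsp_normalize(rnorm(13))
    dab <- tsp_distance(tsp_pearson(a, b))
    dba <- tsp_distance(tsp_pearson(b, a))
    dac <- tsp_distance(tsp_pearson(a, c_))
    dcb <- tsp_distance(tsp_pearson(c_, b))
    expect_gte(dab, 0)
    expect_equal(dab, dba)
    expect_lte(dab, dac + dcb + 1e-12)
  }
  a <- tsp_normalize(rnorm(13))
  expect_equal(tsp_distance(tsp_pearson(a, a)), 0)
})

test_that("UPGMA reproduces a hand-traced merge order and cut semantics", {
  d <- matrix(c(0, 0.2, 1.5,
                0.2, 0, 1.5,
                1.5, 1.5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- tsp_upgma(d)
  expect_equal(sort(tree$height), c(0.2, 1.5))
  fam <- tsp_families(tree, 1.1)
  expect_equal(fam[["A"]], fam[["B"]])
  expect_false(fam[["C"]] == fam[["A"]])
  expect_equal(length(unique(tsp_families(tree, 2.5))), 1)
  expect_equal(length(unique(tsp_families(tree, 0))), 3)

  # all-identical items collapse into one family at any positive threshold
  d0 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(length(unique(tsp_families(tsp_upgma(d0), 0.1))), 1)

  bad <- d; bad[1, 2] <- 0.9
  expect_error(tsp_upgma(bad), "symmetric")
  expect_error(tsp_upgma(-d), "non-negative")
})

test_that("family assignment is a partition with non-decreasing merge heights", {
  set.seed(65)
  vecs <- lapply(1:8, function(i) tsp_normalize(rnorm(13)))
  names(vecs) <- paste0("w", 1:8)
  sim <- tsp_similarity_matrix(vecs)
  expect_equal(diag(sim$r_matrix), rep(1, 8), ignore_attr = TRUE)
  expect_equal(diag(sim$d_matrix), rep(0, 8), ignore_attr = TRUE)
  expect_true(all(abs(sim$r_matrix - t(sim$r_matrix)) < 1e-12))
  tree <- tsp_upgma(sim)
  expect_true(all(diff(tree$height) >= -1e-12))
  fam <- tsp_families(tree, 0.8)
  expect_setequal(names(fam), names(vecs))
  expect_true(all(fam >= 1))
})

test_that("model-vs-empirical correlation averages z vectors before correlating", {
  set.seed(67)
  z <- rnorm(13)
  expect_equal(model_vs_empirical_r(z, list(z, z, z)), 1)
  expect_equal(model_vs_empirical_r(z, list(-z, -z)), -1)
  # averaging happens component-wise: two opposite perturbations cancel
  eps <- rnorm(13)
  expect_equal(model_vs_empirical_r(z, list(z + eps, z - eps)), 1)
  expect_error(model_vs_empirical_r(z, list(z)), "at least 2")
  expect_error(model_vs_empirical_r(z, list(rep(1, 13), rep(1, 13))),
               "constant")
})
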