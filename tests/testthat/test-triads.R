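test_that("triad classification matches the named ecological prototypes", {
  expect_equal(classify_triad(food_web(cbind(c("a", "b"), c("b", "c")))), "S1")
  expect_equal(classify_triad(make_toy("omnivory-triangle")), "S2")
  expect_equal(classify_triad(make_toy("cycle3")), "S3")
  expect_equal(classify_triad(food_web(cbind(c("a", "b"), c("c", "c")))), "S4")
  expect_equal(classify_triad(food_web(cbind(c("c", "c"), c("a", "b")))), "S5")
  # mutual dyad plus one outgoing single link -> fixed D class per the
  # shipped ordering table
  expect_equal(classify_triad(food_web(cbind(c("a", "b", "b"),
                                             c("b", "a", "c")))), "D2")
  all_mut <- matrix(1, 3, 3); diag(all_mut) <- 0
  expect_equal(classify_triad(all_mut), "D8")
  expect_equal(classify_triad(matrix(0, 3, 3)), "disconnected")
  expect_error(classify_triad(food_web(cbind("a", "b"))), "3 nodes")
  expect_error(classify_triad(matrix(0, 2, 2)), "3 x 3")
})

test_that("classification is invariant under all node permutations (exhaustive)", {
  pos <- cbind(c(1, 1, 2, 2, 3, 3), c(2, 3, 1, 3, 1, 2))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  seen <- character(0)
  for (code in 0:63) {
    m <- matrix(0L, 3, 3)
    m[pos] <- bitwAnd(code %/% 2^(0:5), 1L)
    lab <- classify_triad(m)
    seen <- union(seen, lab)
    for (p in perms) {
      m2 <- matrix(0L, 3, 3); m2[p, p] <- m
      expect_identical(classify_triad(m2), lab)
    }
  }
  # the 64 labeled digraphs cover all 13 connected classes plus disconnected
  expect_setequal(seen, c(triad_classes(), "disconnected"))
})

test_that("census counts induced connected triples on hand-enumerated webs", {
  cen <- triad_census(make_toy("omnivory-triangle"))
  expect_equal(as.integer(cen), c(0, 1, rep(0, 11)))
  cen2 <- triad_census(make_toy("diamond"))
  expect_equal(as.integer(cen2[c("S1", "S4", "S5")]), c(2, 1, 1))
  expect_equal(sum(cen2), 4)
  expect_warning(z <- triad_census(food_web(cbind("a", "b"))), "fewer than 3")
  expect_true(all(z == 0))
})

test_that("fast census equals exhaustive enumeration on random webs", {
  set.seed(41)
  for (i in 1:30) {
    w <- if (i %% 2) random_digraph(sample(4:10, 1), 0.3) else
      make_random_dag(10, 2, 25)
    expect_identical(as.integer(triad_census(w)),
                     as.integer(triad_census(w, method = "enumerate")))
  }
})

test_that("rewiring preserves degree sequences and the chain is its own null", {
  set.seed(43)
  for (i in 1:10) {
    w <- random_digraph(12, 0.25)
    for (mode in c("plain", "mutual")) {
      r <- rewire_web(w, swaps_per_link = 10, mode = mode)
      expect_identical(in_degree(r), in_degree(w))
      expect_identical(out_degree(r), out_degree(w))
    }
  }
  ch <- make_toy("chain3")
  for (i in 1:5) expect_web_equal(rewire_web(ch, 20), ch)
  expect_error(rewire_web(food_web(cbind("a", "b"))), "2 links")
})

test_that("mutual-preserving mode conserves the number of mutual dyads", {
  n_mutual <- function(w) {
    n <- n_species(w); adj <- matrix(FALSE, n, n); adj[w$edges] <- TRUE
    sum(adj & t(adj)) / 2
  }
  set.seed(47)
  for (i in 1:10) {
    w <- random_digraph(10, 0.35)
    r <- rewire_web(w, swaps_per_link = 15, mode = "mutual")
    expect_identical(n_mutual(r), n_mutual(w))
    expect_identical(n_links(r), n_links(w))
  }
})

test_that("profile normalization and the degenerate-null policy behave as specified", {
  z <- c(3, 4, rep(0, 11))
  expect_equal(tsp_normalize(z), c(0.6, 0.8, rep(0, 11)))
  expect_true(all(is.na(tsp_normalize(rep(0, 13)))))

  # the 3-chain is the unique graph for its degree sequences: all sigma = 0
  ts <- triad_significance(make_toy("chain3"), ensemble_size = 20, seed = 1)
  expect_true(all(ts$z == 0))
  expect_false(ts$z_hat_defined)
  expect_setequal(ts$zero_sigma, triad_classes())
})

test_that("triad significance has unit-norm profiles and validates inputs", {
  set.seed(49)
  w <- make_random_dag(20, 4, 60)
  ts <- triad_significance(w, ensemble_size = 60, seed = 5)
  expect_equal(sqrt(sum(ts$z_hat^2)), 1, tolerance = 1e-12)
  expect_true(all(ts$null_sd >= 0))
  expect_equal(ts$ensemble_size, 60)
  # reproducible given the seed
  ts2 <- triad_significance(w, ensemble_size = 60, seed = 5)
  expect_identical(ts$z, ts2$z)
  expect_error(triad_significance(w, ensemble_size = 1), "at least 2")
  expect_error(triad_significance(food_web(cbind("a", "b"))), "3 nodes")
})

test_that("z-scores are stable in the ensemble size (self-consistency)", {
  set.seed(51)
  w <- gppm_generate(B = 3, N = 30, L = 120, T_ = 0.2)$web
  a <- triad_significance(w, ensemble_size = 100, seed = 7)
  b <- triad_significance(w, ensemble_size = 600, seed = 8)
  # Monte-Carlo agreement on the S2 score: sd of a z-score estimate from a
  # 100-network ensemble is well below 1 for webs of this size
  expect_lt(abs(a$z["S2"] - b$z["S2"]), 1.5)
})
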