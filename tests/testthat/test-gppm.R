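test_that("zero temperature yields perfectly coherent webs with intact skeleton", {
  set.seed(71)
  for (i in 1:5) {
    d <- gppm_generate(B = 4, N = 40, L = 200, T_ = 0)
    expect_identical(trophic_incoherence(d$web)$q, 0)
    # temporary levels coincide with the recomputed levels at T = 0
    expect_equal(unname(trophic_levels(d$web)), unname(d$s_hat))
    expect_gte(d$realized_links, 40 - 4)
  }
})

test_that("every draw is trophic-valid with basal nodes kept at in-degree 0", {
  set.seed(72)
  for (T_ in c(0, 0.3, 2)) {
    d <- gppm_generate(B = 6, N = 50, L = 300, T_ = T_)
    expect_true(validate_trophic(d$web)$valid)
    expect_equal(sum(in_degree(d$web)[1:6]), 0)
    expect_equal(length(basal_species(d$web)), 6)
  }
})

test_that("draws are reproducible given a seed and reject bad configurations", {
  a <- gppm_generate(B = 3, N = 30, L = 120, T_ = 0.5, seed = 5)
  b <- gppm_generate(B = 3, N = 30, L = 120, T_ = 0.5, seed = 5)
  expect_web_equal(a$web, b$web)
  expect_error(gppm_generate(B = 0, N = 10, L = 20, T_ = 1), "B < N")
  expect_error(gppm_generate(B = 3, N = 10, L = 5, T_ = 1), "at least N - B")
  expect_error(gppm_generate(B = 3, N = 10, L = 100, T_ = 1), "maximum possible")
  expect_error(gppm_generate(B = 3, N = 10, L = 20, T_ = -1), "non-negative")
})

test_that("the capped-probability normalization hits the expected link count", {
  set.seed(73)
  e <- gppm_ensemble_q(B = 5, N = 60, L = 400, T_ = 0.6, n_draws = 150)
  # realized links are a sum of independent Bernoullis; the mean over draws
  # must sit within 3 standard errors of the target L
  realized <- e$mean_links
  se <- sqrt(400) / sqrt(150)  # conservative bound on the SE of the mean
  expect_lt(abs(realized - 400), 3 * se)
})

test_that("the large-temperature limit matches a uniform extra-link null", {
  set.seed(74)
  B <- 3; N <- 60; L <- 400
  hot <- gppm_ensemble_q(B, N, L, T_ = 50, n_draws = 120)
  unif_q <- replicate(120, {
    s <- integer(N); s[1:B] <- 1L
    prey <- integer(N - B)
    for (j in (B + 1):N) {
      i <- sample.int(j - 1, 1); prey[j - B] <- i; s[j] <- s[i] + 1L
    }
    skel <- cbind(prey, (B + 1):N)
    jj <- rep((B + 1):N, each = N); ii <- rep(1:N, times = N - B)
    ok <- ii != jj & !(((ii - 1) * N + jj) %in% ((skel[, 1] - 1) * N + skel[, 2]))
    ii <- ii[ok]; jj <- jj[ok]
    keep <- runif(length(ii)) < (L - (N - B)) / length(ii)
    edges <- rbind(skel, cbind(ii[keep], jj[keep]))
    lab <- sprintf("n%02d", 1:N)
    w <- food_web(cbind(lab[edges[, 1]], lab[edges[, 2]]), nodes = lab)
    trophic_incoherence(w)$q
  })
  se <- sqrt(hot$sd_q^2 / 120 + var(unif_q) / 120)
  expect_lt(abs(hot$mean_q - mean(unif_q)), 3 * se)
})

test_that("temperature calibration is exact at zero and recovers a planted value", {
  f0 <- gppm_fit(B = 4, N = 40, L = 200, target_q = 0, seed = 75)
  expect_equal(f0$T_fit, 0)
  expect_equal(f0$mean_q, 0)

  set.seed(76)
  planted <- 0.45
  target <- gppm_ensemble_q(B = 6, N = 60, L = 400, T_ = planted,
                            n_draws = 400)$mean_q
  fit <- gppm_fit(B = 6, N = 60, L = 400, target_q = target, seed = 77,
                  n_coarse = 150, n_fine = 400)
  expect_lt(abs(fit$T_fit - planted), 0.05)
  expect_true(is.data.frame(fit$evaluations))
  expect_gt(nrow(fit$evaluations), 3)
})

test_that("an unattainable target q is reported as infeasible with the plateau", {
  expect_error(
    gppm_fit(B = 10, N = 20, L = 60, target_q = 8, seed = 78,
             n_coarse = 60, T_max = 4),
    "infeasible")
})

test_that("mean q at fixed T decreases with the basal ratio", {
  set.seed(79)
  lo <- gppm_ensemble_q(B = 10, N = 100, L = 900, T_ = 0.6, n_draws = 100)
  hi <- gppm_ensemble_q(B = 50, N = 100, L = 500, T_ = 0.6, n_draws = 100)
  se <- sqrt(lo$sd_q^2 / 100 + hi$sd_q^2 / 100)
  expect_gt(lo$mean_q - hi$mean_q, -2 * se)
  expect_gt(lo$mean_q, hi$mean_q)
})
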