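#' Generate a food web with tunable trophic coherence
#'
#' Implements the preferential-preying assembly model with a temperature
#' parameter. Starting from `B` basal nodes at temporary level
#' \eqn{\hat s = 1}, the remaining `N - B` nodes are added sequentially; each
#' new node picks exactly one prey uniformly at random among all existing
#' nodes and takes temporary level \eqn{\hat s_j = \hat s_i + 1}. This
#' skeleton of `N - B` links guarantees that every node is reachable from a
#' basal node. Extra links are then laid down over all ordered pairs
#' `(i, j)` with `j` non-basal (so basal nodes keep in-degree 0), `i != j`,
#' excluding the skeleton links, each added independently with probability
#' \deqn{P_{ij} = \min\{1,\; c \exp(-(\hat x_{ij} - 1)^2 / (2 T^2))\},}
#' where \eqn{\hat x_{ij} = \hat s_j - \hat s_i} and the constant `c` is
#' solved (exactly, from the piecewise-linear capped sum) so that the
#' expected total number of links is `L`. Finally the trophic levels are
#' recomputed from the assembled topology.
#'
#' `T` controls coherence: at `T = 0` only pairs at temporary distance
#' exactly 1 are candidates (implemented as the exact limit, avoiding 0/0),
#' so the final web is perfectly layered with incoherence `q = 0`; as `T`
#' grows, link probabilities flatten towards uniform and `q` increases
#' monotonically on average.
#'
#' @param B number of basal nodes (`1 <= B < N`)
#' @param N total number of nodes
#' @param L target expected number of links (`>= N - B`, the skeleton size)
#' @param T_ temperature (>= 0)
#' @param seed optional integer seed
#' @return an object of class `gppm_draw`: list with `web` (a `food_web`
#'   whose first `B` labels are the basal nodes), `s_hat` (temporary integer
#'   levels), `realized_links`, and the model parameters
#' @examples
#' d <- gppm_generate(B = 5, N = 50, L = 200, T_ = 0.3, seed = 1)
#' trophic_incoherence(d$web)$q
#' @export
gppm_generate <- function(B, N, L, T_, seed = NULL) {
  .check_gppm_config(B, N, L, T_)
  if (!is.null(seed)) set.seed(seed)
  s_hat <- integer(N)
  s_hat[1:B] <- 1L
  skel_prey <- integer(N - B)
  for (j in (B + 1):N) {
    i <- sample.int(j - 1, 1)
    skel_prey[j - B] <- i
    s_hat[j] <- s_hat[i] + 1L
  }
  skel <- cbind(skel_prey, (B + 1):N)
  M <- L - (N - B)
  extra <- NULL
  if (M > 0) {
    # candidate ordered pairs (i, j): j non-basal, i != j, not in skeleton
    jj <- rep((B + 1):N, each = N)
    ii <- rep(1:N, times = N - B)
    ok <- ii != jj
    key <- (ii - 1) * N + jj
    ok[key %in% ((skel[, 1] - 1) * N + skel[, 2])] <- FALSE
    ii <- ii[ok]; jj <- jj[ok]
    xhat <- s_hat[jj] - s_hat[ii]
    if (T_ == 0) {
      w <- as.numeric(xhat == 1)
    } else {
      w <- exp(-((xhat - 1)^2) / (2 * T_^2))
    }
    npos <- sum(w > 0)
    if (npos < M)
      stop(sprintf(paste0("target L = %d unreachable: at most %d extra links ",
                          "have positive probability (max total %d)"),
                   L, npos, npos + N - B))
    cc <- .solve_cap_scale(w, M)
    p <- pmin(1, cc * w)
    take <- stats::runif(length(p)) < p
    if (any(take)) extra <- cbind(ii[take], jj[take])
  }
  edges <- rbind(skel, extra)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  wdt <- nchar(as.character(N))
  labels <- sprintf("n%0*d", wdt, 1:N)
  web <- new_food_web(labels, edges)
  structure(list(web = web, s_hat = stats::setNames(s_hat, labels),
                 realized_links = nrow(edges),
                 B = B, N = N, L = L, T_ = T_, seed = seed),
            class = "gppm_draw")
}

#' @export
print.gppm_draw <- function(x, ...) {
  cat(sprintf("Preferential-preying draw: B=%d N=%d target L=%d T=%g -> %d links\n",
              x$B, x$N, x$L, x$T_, x$realized_links))
  invisible(x)
}

.check_gppm_config <- function(B, N, L, T_) {
  if (B < 1 || B >= N) stop("need 1 <= B < N")
  if (T_ < 0) stop("temperature must be non-negative")
  if (L < N - B) stop("L must be at least N - B (the skeleton already has N - B links)")
  max_links <- (N - B) * (N - 1)
  if (L > max_links)
    stop(sprintf("L = %d exceeds the maximum possible link count %d", L, max_links))
  invisible(TRUE)
}

# Solve sum(pmin(1, c * w)) = M for c, exactly, from the piecewise-linear
# structure: with weights sorted descending, on the segment where the k
# largest are capped at 1, the sum is k + c * (sum of the rest).
.solve_cap_scale <- function(w, M) {
  ws <- sort(w[w > 0], decreasing = TRUE)
  n <- length(ws)
  if (M >= n) return(1 / ws[n] + 1)        # everything capped
  tail_sum <- rev(cumsum(rev(ws)))          # tail_sum[k+1] = sum ws[(k+1):n]
  for (k in 0:(n - 1)) {
    cc <- (M - k) / tail_sum[k + 1]
    lo_ok <- k == 0 || cc * ws[k] >= 1 - 1e-12
    hi_ok <- cc * ws[k + 1] < 1 + 1e-12
    if (cc > 0 && lo_ok && hi_ok) return(cc)
  }
  stop("internal error: no solution for the link-probability scale")
}

#' Ensemble statistics of the incoherence parameter at fixed temperature
#'
#' Draws `n_draws` independent model webs and returns the sample mean and
#' standard deviation of their incoherence parameter `q`.
#'
#' @inheritParams gppm_generate
#' @param n_draws number of draws (>= 2)
#' @param seed optional integer master seed
#' @return list with `mean_q`, `sd_q`, `q` (the per-draw values) and
#'   `mean_links` (mean realized link count)
#' @export
gppm_ensemble_q <- function(B, N, L, T_, n_draws = 200, seed = NULL) {
  if (n_draws < 2) stop("n_draws must be at least 2")
  .check_gppm_config(B, N, L, T_)
  if (!is.null(seed)) set.seed(seed)
  q <- links <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    d <- gppm_generate(B, N, L, T_)
    q[i] <- trophic_incoherence(d$web)$q
    links[i] <- d$realized_links
  }
  list(mean_q = mean(q), sd_q = stats::sd(q), q = q, mean_links = mean(links))
}

#' Calibrate the model temperature to an empirical incoherence value
#'
#' Stochastic root finding for the temperature `T` at which the ensemble
#' mean of the model's incoherence parameter `q` matches a target value:
#' bracketing bisection on `T`, where each evaluation is a Monte-Carlo
#' ensemble mean (`n_coarse` draws while the bracket is wide, escalating to
#' `n_fine` draws once it narrows). The mean of `q` is monotone
#' non-decreasing in `T`, which makes bisection applicable despite the
#' sampling noise; every evaluation is logged in the result.
#'
#' @inheritParams gppm_generate
#' @param target_q empirical incoherence value to match (>= 0)
#' @param tol tolerance on the ensemble-mean q (default 0.01)
#' @param seed optional integer seed
#' @param n_coarse draws per evaluation during bracketing
#' @param n_fine draws per evaluation near convergence and for the final
#'   estimate
#' @param T_max upper limit of the search; a target above the large-T
#'   plateau of mean q is reported as infeasible
#' @return an object of class `gppm_fit`: `T_fit`, `mean_q`, `sd_q` at the
#'   fitted temperature, the `target_q`, and `evaluations` (a data frame
#'   logging every Monte-Carlo evaluation)
#' @export
gppm_fit <- function(B, N, L, target_q, tol = 0.01, seed = NULL,
                     n_coarse = 200, n_fine = 1000, T_max = 32) {
  .check_gppm_config(B, N, L, 0)
  if (target_q < 0) stop("target_q must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  log_env <- new.env()
  log_env$rows <- list()
  eval_q <- function(T_, n) {
    e <- gppm_ensemble_q(B, N, L, T_, n_draws = n)
    log_env$rows[[length(log_env$rows) + 1]] <-
      data.frame(T_ = T_, n_draws = n, mean_q = e$mean_q, sd_q = e$sd_q)
    e
  }
  finish <- function(T_fit, e) {
    structure(list(T_fit = T_fit, mean_q = e$mean_q, sd_q = e$sd_q,
                   target_q = target_q, tol = tol, B = B, N = N, L = L,
                   evaluations = do.call(rbind, log_env$rows)),
              class = "gppm_fit")
  }
  if (target_q <= tol) {
    # T = 0 is exact: q = 0 for every draw
    e <- eval_q(0, max(2, n_coarse %/% 4))
    return(finish(0, e))
  }
  # bracket [lo, hi] with mean_q(lo) < target <= mean_q(hi)
  lo <- 0; hi <- min(1, T_max)
  e_hi <- eval_q(hi, n_coarse)
  while (e_hi$mean_q < target_q && hi < T_max) {
    lo <- hi
    hi <- min(2 * hi, T_max)
    e_hi <- eval_q(hi, n_coarse)
  }
  if (e_hi$mean_q < target_q) {
    se <- e_hi$sd_q / sqrt(n_coarse)
    if (e_hi$mean_q + 3 * se < target_q)
      stop(sprintf(paste0("target q = %.3f is infeasible: mean q plateaus ",
                          "near %.3f (sd %.3f) at T = %g"),
                   target_q, e_hi$mean_q, e_hi$sd_q, hi))
  }
  while (hi - lo > 0.002) {
    mid <- (lo + hi) / 2
    n <- if (hi - lo > 0.04) n_coarse else n_fine
    e <- eval_q(mid, n)
    if (e$mean_q < target_q) lo <- mid else hi <- mid
  }
  T_fit <- (lo + hi) / 2
  e <- eval_q(T_fit, n_fine)
  finish(T_fit, e)
}

#' @export
print.gppm_fit <- function(x, ...) {
  cat(sprintf(
    "Temperature calibration (B=%d, N=%d, L=%d): target q = %.3f\n",
    x$B, x$N, x$L, x$target_q))
  cat(sprintf("  fitted T = %.4f; ensemble mean q = %.4f (sd %.4f); %d evaluations\n",
              x$T_fit, x$mean_q, x$sd_q, nrow(x$evaluations)))
  invisible(x)
}

#' Locate the omnivory (S2) over/under-representation transition
#'
#' For each basal ratio `B/N`, scans a temperature grid, generates
#' `n_draws` model webs per grid point, scores each web's triad significance
#' profile against the degree-preserving null, and tracks the ensemble mean
#' of the normalized feed-forward (S2) z-score \eqn{\hat z_{S2}} together
#' with the mean incoherence q. The critical temperature `T_c` (and the
#' corresponding `q_c`) is located by linear interpolation at the first sign
#' change of the mean \eqn{\hat z_{S2}} along the grid: below it the model
#' under-represents omnivory, above it omnivory is even or over-represented.
#'
#' @param ratios basal ratios `B/N` to scan, each in (0, 1)
#' @param N total nodes per web
#' @param mean_degree average non-basal degree `L / (N - B)`; sets
#'   `L = round(mean_degree * (N - B))`
#' @param n_draws model webs per (ratio, temperature) point
#' @param T_grid increasing temperature grid to scan
#' @param ensemble_size null-ensemble size per web (see
#'   [triad_significance()])
#' @param swaps_per_link swap-chain length per randomization
#' @param seed optional integer seed
#' @return an object of class `gppm_transition`: a data frame with one row
#'   per ratio (`ratio`, `B`, `L`, `T_c`, `q_c`, `bracketed`), with the full
#'   per-grid-point scan in `attr(, "scan")` (mean and standard error of
#'   \eqn{\hat z_{S2}} and of q at every point)
#' @export
gppm_s2_transition <- function(ratios, N = 100, mean_degree = 10,
                               n_draws = 100,
                               T_grid = c(0.05, 0.15, 0.3, 0.5, 0.75, 1, 1.5),
                               ensemble_size = 50, swaps_per_link = 10,
                               seed = NULL) {
  stopifnot(all(ratios > 0 & ratios < 1), all(diff(T_grid) > 0))
  if (!is.null(seed)) set.seed(seed)
  scan <- list()
  rows <- list()
  for (r in ratios) {
    B <- max(1L, as.integer(round(r * N)))
    L <- as.integer(round(mean_degree * (N - B)))
    mz <- sez <- mq <- seq_ <- numeric(length(T_grid))
    for (t in seq_along(T_grid)) {
      zs <- qs <- numeric(0)
      for (dr in seq_len(n_draws)) {
        d <- gppm_generate(B, N, L, T_grid[t])
        ts <- triad_significance(d$web, ensemble_size = ensemble_size,
                                 swaps_per_link = swaps_per_link)
        if (ts$z_hat_defined) zs <- c(zs, ts$z_hat["S2"])
        qs <- c(qs, trophic_incoherence(d$web)$q)
      }
      mz[t] <- mean(zs); sez[t] <- stats::sd(zs) / sqrt(length(zs))
      mq[t] <- mean(qs); seq_[t] <- stats::sd(qs) / sqrt(length(qs))
      scan[[length(scan) + 1]] <-
        data.frame(ratio = r, B = B, L = L, T_ = T_grid[t],
                   mean_zhat_s2 = mz[t], se_zhat_s2 = sez[t],
                   mean_q = mq[t], se_q = seq_[t], n_draws = n_draws)
    }
    cross <- which(mz[-length(mz)] < 0 & mz[-1] >= 0)
    if (length(cross) >= 1) {
      i <- cross[1]
      f <- -mz[i] / (mz[i + 1] - mz[i])
      T_c <- T_grid[i] + f * (T_grid[i + 1] - T_grid[i])
      q_c <- mq[i] + f * (mq[i + 1] - mq[i])
      rows[[length(rows) + 1]] <-
        data.frame(ratio = r, B = B, L = L, T_c = T_c, q_c = q_c,
                   bracketed = TRUE)
    } else {
      rows[[length(rows) + 1]] <-
        data.frame(ratio = r, B = B, L = L, T_c = NA_real_, q_c = NA_real_,
                   bracketed = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "scan") <- do.call(rbind, scan)
  class(out) <- c("gppm_transition", "data.frame")
  out
}
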