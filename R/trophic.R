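#' Trophic levels of a food web
#'
#' The trophic level \eqn{s_j} of species \eqn{j} is one plus the mean
#' trophic level of its prey,
#' \deqn{s_j = 1 + \frac{1}{k^{in}_j} \sum_i a_{ij} s_i,}
#' with \eqn{s_j = 1} on basal species (the ecological convention). When the
#' web has at least one basal node and every node is reachable from the basal
#' set, this linear system has a unique solution; it is obtained here by a
#' direct sparse LU solve on the reduced (non-basal) system, not by iteration.
#'
#' @param web a trophic-valid `food_web`
#' @return a named numeric vector of trophic levels (>= 1), one per node
#' @export
trophic_levels <- function(web) {
  assert_trophic_valid(web)
  n <- n_species(web)
  kin <- in_degree(web)
  basal <- which(kin == 0)
  s <- rep(1, n)
  names(s) <- web$nodes
  nb <- which(kin > 0)
  if (length(nb) == 0) return(s)
  # W[j, i] = a_ij / k^in_j restricted to non-basal rows j
  A <- Matrix::sparseMatrix(i = web$edges[, "prey"], j = web$edges[, "predator"],
                            x = 1, dims = c(n, n))
  W <- Matrix::t(A[, nb, drop = FALSE]) / kin[nb]
  rhs <- 1 + Matrix::rowSums(W[, basal, drop = FALSE])
  M <- Matrix::Diagonal(length(nb)) - W[, nb, drop = FALSE]
  s[nb] <- as.numeric(Matrix::solve(M, rhs))
  s
}

#' Trophic distances and the incoherence parameter q
#'
#' Each link carries a trophic distance \eqn{x_{ij} = s_j - s_i} (predator
#' level minus prey level). Its distribution has mean 1 identically; its
#' standard deviation
#' \deqn{q = \sqrt{\langle x^2 \rangle - 1}}
#' is the trophic incoherence parameter. `q = 0` characterises a perfectly
#' layered web in which every species feeds exactly one level below itself;
#' larger `q` means more cross-level feeding (omnivory). Averages are taken
#' over all `L` links (population form). A radicand within floating-point
#' solver tolerance (1e-12) of zero is clipped to 0, so perfectly layered
#' webs report `q = 0` exactly.
#'
#' @param web a trophic-valid `food_web` with at least one link
#' @return an object of class `trophic_profile`: list with `levels` (named
#'   numeric), `distances` (numeric, one per link, in `web$edges` order),
#'   `mean_distance`, and `q`.
#' @examples
#' tri <- make_toy("omnivory-triangle")
#' trophic_incoherence(tri)$q   # sqrt(1/6)
#' @export
trophic_incoherence <- function(web) {
  if (n_links(web) == 0)
    stop("q is undefined for a web with no links")
  s <- trophic_levels(web)
  x <- s[web$edges[, "predator"]] - s[web$edges[, "prey"]]
  names(x) <- NULL
  msq <- mean(x^2)
  rad <- msq - 1
  if (rad < -1e-9)
    stop("internal error: negative variance of trophic distances")
  # a radicand within solver precision of zero is zero: perfectly layered
  # webs must report q = 0 exactly
  if (rad < 1e-12) rad <- 0
  structure(list(levels = s, distances = x, mean_distance = mean(x),
                 q = sqrt(rad)),
            class = "trophic_profile")
}

#' @export
print.trophic_profile <- function(x, ...) {
  cat(sprintf("Trophic profile: %d species, %d links\n",
              length(x$levels), length(x$distances)))
  cat(sprintf("  levels in [%.3f, %.3f]; mean trophic distance %.6f\n",
              min(x$levels), max(x$levels), x$mean_distance))
  cat(sprintf("  incoherence q = %.4f\n", x$q))
  invisible(x)
}
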