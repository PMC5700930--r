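#' Pearson correlation between two triad significance profiles
#'
#' The sample Pearson coefficient over the 13 profile components,
#' \deqn{r = \frac{\sum_k (\hat z^a_k - \bar z^a)(\hat z^b_k - \bar z^b)}
#'              {(n - 1)\, \sigma_{\hat z^a} \sigma_{\hat z^b}},}
#' with the sample mean and the (n - 1)-normalized sample standard
#' deviation. `r` close to 1 means the same triads are over- and
#' under-represented in both webs; `r` close to -1 means anti-similar
#' profiles.
#'
#' @param a,b `triad_significance` objects (their normalized profiles are
#'   used) or plain numeric vectors of equal length
#' @return the correlation coefficient, in `[-1, 1]`
#' @export
tsp_pearson <- function(a, b) {
  va <- .profile_vector(a, "a")
  vb <- .profile_vector(b, "b")
  if (length(va) != length(vb))
    stop("profiles have different lengths")
  if (stats::sd(va) == 0) stop("profile `a` is constant; r is undefined")
  if (stats::sd(vb) == 0) stop("profile `b` is constant; r is undefined")
  stats::cor(va, vb)
}

.profile_vector <- function(x, which) {
  if (inherits(x, "triad_significance")) {
    if (!x$z_hat_defined)
      stop("profile `", which, "` has an undefined normalized TSP")
    x$z_hat
  } else {
    as.numeric(x)
  }
}

#' Distance between triad significance profiles
#'
#' \deqn{d = \sqrt{2 (1 - r)},} which is a Euclidean metric on unit-norm
#' profiles (it is the chord distance between the profile vectors). `r` is
#' clipped to `[-1, 1]` within floating tolerance; values beyond that are an
#' error.
#'
#' @param r Pearson coefficient(s) from [tsp_pearson()]
#' @return distance(s) in `[0, 2]`
#' @export
tsp_distance <- function(r) {
  if (any(r < -1 - 1e-12) || any(r > 1 + 1e-12))
    stop("correlation outside [-1, 1]")
  sqrt(2 * (1 - pmin(1, pmax(-1, r))))
}

#' Pairwise similarity and distance matrices for a set of profiles
#'
#' @param tsps a named list of `triad_significance` objects or numeric
#'   profile vectors
#' @return a list of class `tsp_similarity` with `r_matrix` and `d_matrix`
#'   (symmetric, diagonal 1 and 0 respectively)
#' @export
tsp_similarity_matrix <- function(tsps) {
  stopifnot(length(tsps) >= 2)
  labels <- names(tsps)
  if (is.null(labels)) labels <- as.character(seq_along(tsps))
  vecs <- lapply(seq_along(tsps), function(i) .profile_vector(tsps[[i]], labels[i]))
  m <- length(tsps)
  r <- diag(1, m)
  for (i in seq_len(m - 1))
    for (j in (i + 1):m)
      r[i, j] <- r[j, i] <- tsp_pearson(vecs[[i]], vecs[[j]])
  d <- matrix(tsp_distance(r), m, m)
  diag(d) <- 0
  dimnames(r) <- dimnames(d) <- list(labels, labels)
  structure(list(r_matrix = r, d_matrix = d), class = "tsp_similarity")
}

#' UPGMA clustering of webs by profile distance
#'
#' Average-linkage (UPGMA) agglomerative clustering on a profile distance
#' matrix, via [stats::hclust()]. Merge heights are non-decreasing; cutting
#' the dendrogram at a threshold distance partitions the webs into motif
#' families.
#'
#' @param d a symmetric distance matrix (e.g. `d_matrix` from
#'   [tsp_similarity_matrix()]), a [stats::dist] object, or a
#'   `tsp_similarity` object
#' @return an [stats::hclust] tree
#' @export
tsp_upgma <- function(d) {
  if (inherits(d, "tsp_similarity")) d <- d$d_matrix
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8))
      stop("distance matrix must be symmetric")
    if (any(d < 0)) stop("distances must be non-negative")
    d <- stats::as.dist(d)
  }
  stats::hclust(d, method = "average")
}

#' Cut a dendrogram into motif families
#'
#' Families are the clusters whose internal merge heights lie below the
#' threshold `d_c`; every web is assigned to exactly one family.
#'
#' @param tree an [stats::hclust] tree from [tsp_upgma()]
#' @param d_c threshold distance (> 0)
#' @return named integer vector of family memberships
#' @export
tsp_families <- function(tree, d_c) {
  if (!is.numeric(d_c) || d_c < 0) stop("d_c must be a non-negative number")
  if (d_c == 0)
    return(stats::setNames(seq_along(tree$labels), tree$labels))
  stats::cutree(tree, h = d_c - 1e-12)
}

#' Correlation between an empirical profile and a model ensemble
#'
#' Averages the model z-score vectors component-wise and computes the
#' Pearson coefficient between the empirical z-score vector and that mean
#' vector. By default the raw z vectors are averaged; `use = "z_hat"`
#' averages the unit-normalized profiles instead.
#'
#' @param empirical a `triad_significance` object (or numeric z vector)
#' @param model_tsps list of at least 2 `triad_significance` objects (or
#'   numeric z vectors) from the model ensemble
#' @param use `"z"` (average raw z-scores) or `"z_hat"` (average normalized
#'   profiles)
#' @return the Pearson coefficient
#' @export
model_vs_empirical_r <- function(empirical, model_tsps, use = c("z", "z_hat")) {
  use <- match.arg(use)
  if (length(model_tsps) < 2) stop("need at least 2 model profiles")
  pick <- function(x) {
    if (inherits(x, "triad_significance")) {
      if (use == "z") x$z else x$z_hat
    } else as.numeric(x)
  }
  vecs <- lapply(model_tsps, pick)
  vecs <- vecs[!vapply(vecs, anyNA, logical(1))]
  if (length(vecs) < 2) stop("fewer than 2 usable model profiles")
  mean_vec <- Reduce(`+`, vecs) / length(vecs)
  emp <- pick(empirical)
  if (stats::sd(mean_vec) == 0)
    stop("model ensemble mean profile is constant; r is undefined")
  if (stats::sd(emp) == 0)
    stop("empirical profile is constant; r is undefined")
  stats::cor(emp, mean_vec)
}
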