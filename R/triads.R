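#' The 13 connected triad classes
#'
#' Directed graphs on three nodes fall into 16 isomorphism classes, 13 of
#' which are weakly connected. Five contain only single links: `S1` the food
#' chain (i -> j -> k), `S2` the feed-forward loop (omnivory: a predator
#' preying on two species at different trophic levels), `S3` the directed
#' 3-cycle, `S4` two prey sharing a predator (i -> k <- j, apparent
#' competition) and `S5` two predators sharing a prey (i <- k -> j, direct
#' competition). The eight classes `D1`-`D8` contain at least one mutual
#' (double) link, i.e. a pair of mutually predating species; they are ordered
#' by increasing number of double links, then total links: `D1` dyad plus an
#' incoming single link, `D2` dyad plus an outgoing single link, `D3` dyad
#' fed by a shared prey, `D4` dyad feeding a shared predator, `D5` dyad on a
#' directed path, `D6` two dyads, `D7` two dyads plus a single link, `D8`
#' all links mutual.
#'
#' @return character vector of the 13 class labels, in profile order
#' @export
triad_classes <- function() TRIAD_CLASSES

TRIAD_CLASSES <- c("S1", "S2", "S3", "S4", "S5",
                   "D1", "D2", "D3", "D4", "D5", "D6", "D7", "D8")

# Prototype edge lists (rows: prey -> predator) for each connected class.
TRIAD_PROTOTYPES <- list(
  S1 = rbind(c(1, 2), c(2, 3)),
  S2 = rbind(c(1, 2), c(2, 3), c(1, 3)),
  S3 = rbind(c(1, 2), c(2, 3), c(3, 1)),
  S4 = rbind(c(1, 3), c(2, 3)),
  S5 = rbind(c(3, 1), c(3, 2)),
  D1 = rbind(c(1, 2), c(2, 1), c(3, 1)),
  D2 = rbind(c(1, 2), c(2, 1), c(1, 3)),
  D3 = rbind(c(1, 2), c(2, 1), c(3, 1), c(3, 2)),
  D4 = rbind(c(1, 2), c(2, 1), c(1, 3), c(2, 3)),
  D5 = rbind(c(1, 2), c(2, 1), c(3, 1), c(2, 3)),
  D6 = rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 2)),
  D7 = rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 2), c(1, 3)),
  D8 = rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 2), c(1, 3), c(3, 1))
)

# Off-diagonal positions, fixed bit order for the 6-bit triad code.
.TRIAD_POS <- cbind(c(1, 1, 2, 2, 3, 3), c(2, 3, 1, 3, 1, 2))

.triad_code <- function(m) as.integer(sum(2^(0:5) * (m[.TRIAD_POS] != 0)))

.triad_mat <- function(code) {
  m <- matrix(0L, 3, 3)
  m[.TRIAD_POS] <- bitwAnd(code %/% 2^(0:5), 1L)
  m
}

# Canonical code (minimum over the 6 node permutations) for each of the 64
# labeled 3-node digraphs, plus the canonical-code -> class-label lookup,
# built once by exhaustive enumeration.
.TRIAD_TABLES <- local({
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  canon <- integer(64)
  for (code in 0:63) {
    m <- .triad_mat(code)
    imgs <- vapply(perms, function(p) {
      m2 <- matrix(0L, 3, 3); m2[p, p] <- m; .triad_code(m2)
    }, integer(1))
    canon[code + 1] <- min(imgs)
  }
  label <- character(64)
  for (k in seq_along(TRIAD_PROTOTYPES)) {
    m <- matrix(0L, 3, 3)
    m[TRIAD_PROTOTYPES[[k]]] <- 1L
    label[canon[.triad_code(m) + 1] + 1] <- names(TRIAD_PROTOTYPES)[k]
  }
  list(canon = canon, label = label)
})

#' Classify a three-node directed graph into its triad class
#'
#' Classification is by canonical form: the minimum 6-bit adjacency code over
#' all node permutations, looked up in a table built by exhaustive
#' enumeration of the 64 labeled 3-node digraphs, so the result is invariant
#' under node relabeling.
#'
#' @param x a `food_web` with exactly 3 nodes, or a 3 x 3 binary adjacency
#'   matrix (entry `[i, j] = 1` for a link from prey `i` to predator `j`,
#'   zero diagonal)
#' @return one of the labels in [triad_classes()], or `"disconnected"` for
#'   the three non-connected patterns (empty, single link, lone mutual dyad)
#' @export
classify_triad <- function(x) {
  if (inherits(x, "food_web")) {
    if (n_species(x) != 3)
      stop("classify_triad() needs exactly 3 nodes, got ", n_species(x))
    m <- matrix(0L, 3, 3)
    m[x$edges] <- 1L
  } else {
    m <- as.matrix(x)
    if (!all(dim(m) == c(3, 3)))
      stop("adjacency matrix must be 3 x 3")
    if (any(diag(m) != 0)) stop("self-loops are not allowed in a triad")
  }
  lab <- .TRIAD_TABLES$label[.TRIAD_TABLES$canon[.triad_code(m) + 1] + 1]
  if (lab == "") "disconnected" else lab
}

# Lazy cache: position of each connected class within igraph's 16-class
# Davis-Leinhardt triad census, found by running the census on each prototype.
.triad_env <- new.env(parent = emptyenv())

.dl_index <- function() {
  if (is.null(.triad_env$dl_index)) {
    idx <- vapply(TRIAD_PROTOTYPES, function(e) {
      g <- igraph::make_graph(t(e), n = 3, directed = TRUE)
      which(igraph::triad_census(g) == 1L)
    }, integer(1))
    stopifnot(!anyDuplicated(idx))
    .triad_env$dl_index <- idx
  }
  .triad_env$dl_index
}

#' Census of connected three-node subgraphs
#'
#' Counts the induced connected 3-node subgraphs of a food web by triad
#' class; each unordered node triple is counted exactly once, in the class of
#' the subgraph it induces (the convention of the standard motif-detection
#' tools). The default method maps [igraph::triad_census()]'s 16-class census
#' onto the 13 connected classes; `method = "enumerate"` classifies every
#' node triple explicitly with [classify_triad()] and serves as a slow,
#' independent reference.
#'
#' @param web a `food_web`
#' @param method `"igraph"` (fast) or `"enumerate"` (exhaustive reference)
#' @return an object of class `triad_census`: a named integer vector of
#'   counts over [triad_classes()]
#' @export
triad_census <- function(web, method = c("igraph", "enumerate")) {
  method <- match.arg(method)
  counts <- integer(13)
  names(counts) <- TRIAD_CLASSES
  if (n_species(web) < 3) {
    warning("fewer than 3 nodes: census is all zero")
    return(structure(counts, class = "triad_census"))
  }
  if (method == "igraph") {
    tc <- igraph::triad_census(as_igraph(web))
    counts[] <- tc[.dl_index()]
  } else {
    n <- n_species(web)
    adj <- matrix(0L, n, n)
    adj[web$edges] <- 1L
    triples <- utils::combn(n, 3)
    for (t in seq_len(ncol(triples))) {
      lab <- classify_triad(adj[triples[, t], triples[, t]])
      if (lab != "disconnected") counts[lab] <- counts[lab] + 1L
    }
  }
  structure(counts, class = "triad_census")
}

#' @export
print.triad_census <- function(x, ...) {
  cat("Triad census (connected induced 3-node subgraphs):\n")
  print(unclass(x))
  invisible(x)
}

#' Degree-preserving randomization of a food web
#'
#' Randomizes the links of a web while preserving every node's in- and
#' out-degree, via a Markov chain of double-edge swaps: two links a -> b and
#' c -> d are rewired to a -> d and c -> b; a swap is rejected (and counted
#' as attempted) whenever it would create a self-loop or a duplicate link.
#' This is the configuration-model null used to score triad significance.
#'
#' Two modes are available. `"plain"` preserves only the degree sequences
#' (delegated to [igraph::rewire()] with `keeping_degseq`). `"mutual"`
#' additionally preserves the number of mutual (double) links, swapping
#' single links only among single links and mutual dyads only among mutual
#' dyads — the stricter null used by classic motif-detection software, which
#' matters for webs containing mutual predation.
#'
#' @param web a `food_web` with at least 2 links
#' @param swaps_per_link attempted swaps per link; the chain makes
#'   `swaps_per_link * n_links(web)` attempts
#' @param mode `"plain"` or `"mutual"`
#' @return a randomized `food_web` on the same node set
#' @export
rewire_web <- function(web, swaps_per_link = 10, mode = c("plain", "mutual")) {
  mode <- match.arg(mode)
  L <- n_links(web)
  if (L < 2) stop("rewiring needs at least 2 links")
  n_att <- as.integer(ceiling(swaps_per_link * L))
  if (mode == "plain") {
    g <- igraph::rewire(as_igraph(web),
                        igraph::keeping_degseq(loops = FALSE, niter = n_att))
    return(from_igraph(g, web$nodes))
  }
  .rewire_mutual(web, n_att)
}

# Mutual-dyad-preserving swap chain. Single links swap with single links
# (rejecting swaps that would create a mutual pair); mutual dyads swap with
# mutual dyads as undirected edges.
.rewire_mutual <- function(web, n_att) {
  n <- n_species(web)
  adj <- matrix(FALSE, n, n)
  adj[web$edges] <- TRUE
  mut <- adj & t(adj)
  singles <- which(adj & !mut, arr.ind = TRUE)
  dyads <- which(mut & upper.tri(mut), arr.ind = TRUE)
  ns <- nrow(singles); nd <- nrow(dyads)
  can_s <- ns >= 2; can_d <- nd >= 2
  if (!can_s && !can_d) return(web)
  p_single <- if (can_s && can_d) ns / (ns + 2 * nd) else as.numeric(can_s)
  for (t in seq_len(n_att)) {
    if (stats::runif(1) < p_single) {
      e <- sample.int(ns, 2)
      a <- singles[e[1], 1]; b <- singles[e[1], 2]
      c_ <- singles[e[2], 1]; d <- singles[e[2], 2]
      if (a == d || c_ == b) next
      if (adj[a, d] || adj[c_, b] || adj[d, a] || adj[b, c_]) next
      adj[a, b] <- FALSE; adj[c_, d] <- FALSE
      adj[a, d] <- TRUE;  adj[c_, b] <- TRUE
      singles[e[1], 2] <- d; singles[e[2], 2] <- b
    } else {
      e <- sample.int(nd, 2)
      a <- dyads[e[1], 1]; b <- dyads[e[1], 2]
      c_ <- dyads[e[2], 1]; d <- dyads[e[2], 2]
      if (a == d || b == c_ || a == c_ || b == d) next
      if (adj[a, d] || adj[d, a] || adj[c_, b] || adj[b, c_]) next
      adj[a, b] <- adj[b, a] <- FALSE
      adj[c_, d] <- adj[d, c_] <- FALSE
      adj[a, d] <- adj[d, a] <- TRUE
      adj[c_, b] <- adj[b, c_] <- TRUE
      dyads[e[1], 2] <- d; dyads[e[2], 2] <- b
    }
  }
  e <- which(adj, arr.ind = TRUE)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  new_food_web(web$nodes, e)
}

#' Normalize a triad significance profile to unit length
#'
#' \deqn{\hat z_k = z_k / \sqrt{\sum_k z_k^2}.}
#'
#' @param z numeric vector of 13 z-scores
#' @return the unit-norm profile, or a vector of `NA` when `z` is identically
#'   zero (the normalized profile is then undefined)
#' @export
tsp_normalize <- function(z) {
  nrm <- sqrt(sum(z^2))
  if (nrm == 0) return(rep(NA_real_, length(z)))
  z / nrm
}

#' Triad significance profile of a food web
#'
#' Scores each of the 13 connected triad classes against a degree-preserving
#' randomized ensemble:
#' \deqn{z_k = (N_k - \langle N_k \rangle_{rand}) / \sigma_{rand},}
#' where the ensemble statistics come from `ensemble_size` independent
#' randomizations of the web (each an independent swap chain started from the
#' original web, see [rewire_web()]). The normalized profile \eqn{\hat z}
#' (unit Euclidean norm) is what is compared across webs of different sizes.
#'
#' A class whose count is identical across the whole null ensemble has
#' \eqn{\sigma_{rand} = 0}; its z-score is set to 0 (the class carries no
#' signal relative to this null) and recorded in `zero_sigma`. If every class
#' is degenerate — e.g. the web is the unique graph with its degree
#' sequences — the normalized profile is undefined and flagged.
#'
#' @param web a `food_web` with at least 3 nodes and 2 links
#' @param ensemble_size number of randomized webs (>= 2); 1000 matches
#'   common practice, smaller values trade precision for speed
#' @param swaps_per_link attempted swaps per link per randomization
#' @param mode randomization mode, see [rewire_web()]
#' @param seed optional integer seed (recorded in the result)
#' @param method census method, see [triad_census()]
#' @return an object of class `triad_significance` with components `census`,
#'   `null_mean`, `null_sd`, `z`, `z_hat`, `z_hat_defined`, `zero_sigma`,
#'   and the ensemble settings
#' @export
triad_significance <- function(web, ensemble_size = 1000, swaps_per_link = 10,
                               mode = c("plain", "mutual"), seed = NULL,
                               method = c("igraph", "enumerate")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (n_species(web) < 3) stop("triad significance needs at least 3 nodes")
  if (n_links(web) < 2) stop("triad significance needs at least 2 links")
  if (ensemble_size < 2) stop("ensemble_size must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  obs <- triad_census(web, method)
  mat <- matrix(0L, nrow = 13, ncol = ensemble_size,
                dimnames = list(TRIAD_CLASSES, NULL))
  for (m in seq_len(ensemble_size))
    mat[, m] <- triad_census(rewire_web(web, swaps_per_link, mode), method)
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1, stats::sd)
  z <- ifelse(sdv > 0, (as.numeric(obs) - mu) / sdv, 0)
  names(z) <- TRIAD_CLASSES
  z_hat <- tsp_normalize(z)
  names(z_hat) <- TRIAD_CLASSES
  structure(list(census = obs, null_mean = mu, null_sd = sdv,
                 z = z, z_hat = z_hat,
                 z_hat_defined = !all(z == 0),
                 zero_sigma = TRIAD_CLASSES[sdv == 0],
                 ensemble_size = ensemble_size,
                 swaps_per_link = swaps_per_link,
                 mode = mode, seed = seed),
            class = "triad_significance")
}

#' @export
print.triad_significance <- function(x, ...) {
  cat(sprintf("Triad significance profile (%s null, %d randomizations)\n",
              x$mode, x$ensemble_size))
  df <- data.frame(count = as.integer(x$census),
                   null_mean = round(x$null_mean, 2),
                   null_sd = round(x$null_sd, 2),
                   z = round(x$z, 2),
                   z_hat = round(x$z_hat, 3))
  rownames(df) <- TRIAD_CLASSES
  print(df)
  if (!x$z_hat_defined)
    cat("normalized profile undefined (all z-scores zero)\n")
  invisible(x)
}
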