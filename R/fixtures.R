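#' Perfectly layered synthetic food web
#'
#' Builds a web of `levels` trophic layers with `width` species each; every
#' species above the first layer receives one random prey from the layer
#' directly below, plus `extra_links` additional randomly placed
#' adjacent-layer links. All links connect adjacent layers, so the web is
#' perfectly coherent: `q = 0` exactly, with `B = width` basal species.
#' `skip_link = TRUE` adds a single layer-skipping link (layer 1 to layer 3),
#' the minimal perturbation that makes `q > 0` — useful as a
#' coherence-breaking control.
#'
#' @param levels number of layers (>= 2; >= 3 when `skip_link`)
#' @param width species per layer (>= 1)
#' @param extra_links extra adjacent-layer links to add (capped at the
#'   number of available pairs)
#' @param seed optional integer seed
#' @param skip_link add one level-skipping link
#' @return a `food_web`
#' @export
make_layered <- function(levels, width, extra_links = 0, seed = NULL,
                         skip_link = FALSE) {
  stopifnot(levels >= 2, width >= 1)
  if (skip_link && levels < 3) stop("skip_link needs at least 3 levels")
  if (!is.null(seed)) set.seed(seed)
  lab <- function(l, i) sprintf("v%02d_%02d", l, i)
  id <- function(l, i) (l - 1) * width + i           # node index
  prey <- pred <- integer(0)
  for (l in 2:levels)
    for (i in 1:width) {
      prey <- c(prey, id(l - 1, sample.int(width, 1)))
      pred <- c(pred, id(l, i))
    }
  have <- paste(prey, pred)
  # candidate extra adjacent-layer pairs not yet present
  cand_prey <- cand_pred <- integer(0)
  for (l in 2:levels) {
    cp <- rep(id(l - 1, 1:width), times = width)
    cq <- rep(id(l, 1:width), each = width)
    keep <- !(paste(cp, cq) %in% have)
    cand_prey <- c(cand_prey, cp[keep]); cand_pred <- c(cand_pred, cq[keep])
  }
  n_extra <- min(extra_links, length(cand_prey))
  if (n_extra > 0) {
    pick <- sample.int(length(cand_prey), n_extra)
    prey <- c(prey, cand_prey[pick]); pred <- c(pred, cand_pred[pick])
  }
  if (skip_link) {
    prey <- c(prey, id(1, 1)); pred <- c(pred, id(3, 1))
  }
  nodes <- as.vector(vapply(1:levels, function(l)
    vapply(1:width, function(i) lab(l, i), character(1)), character(width)))
  food_web(cbind(nodes[prey], nodes[pred]), nodes = nodes)
}

#' Small fixed toy webs
#'
#' Seedless constant fixtures with known analytic properties:
#' \describe{
#'   \item{`"chain3"`}{a -> b -> c; q = 0.}
#'   \item{`"omnivory-triangle"`}{b -> m, b -> t, m -> t; levels 1, 2, 2.5;
#'     trophic distances 1, 1.5, 0.5; q = sqrt(1/6).}
#'   \item{`"diamond"`}{1 -> 2, 1 -> 3, 2 -> 4, 3 -> 4; all distances 1,
#'     q = 0.}
#'   \item{`"cycle3"`}{a -> b -> c -> a; no basal node, trophic-invalid.}
#' }
#'
#' @param kind one of the names above
#' @return a `food_web`
#' @export
make_toy <- function(kind = c("chain3", "omnivory-triangle", "diamond",
                              "cycle3")) {
  kind <- match.arg(kind)
  e <- switch(kind,
    "chain3" = cbind(c("a", "b"), c("b", "c")),
    "omnivory-triangle" = cbind(c("b", "b", "m"), c("m", "t", "t")),
    "diamond" = cbind(c("w1", "w1", "w2", "w3"), c("w2", "w3", "w4", "w4")),
    "cycle3" = cbind(c("a", "b", "c"), c("b", "c", "a")))
  food_web(e)
}

#' Random trophic-valid directed acyclic web with exact counts
#'
#' Nodes are ordered; the first `B` are basal. Every non-basal node gets one
#' prey among the nodes before it (a random skeleton guaranteeing
#' reachability from the basal set and in-degree 0 on basal nodes), then
#' extra forward links are sampled without replacement until exactly `L`
#' links exist. The result is acyclic with exactly the requested `N`, `B`
#' and `L`.
#'
#' @param N total nodes
#' @param B basal nodes (`1 <= B < N`)
#' @param L total links (`N - B <= L <= B*(N-B) + choose(N-B, 2) + N - B`
#'   bounded by the number of forward non-basal-target pairs)
#' @param seed optional integer seed
#' @return a `food_web`
#' @export
make_random_dag <- function(N, B, L, seed = NULL) {
  stopifnot(B >= 1, B < N)
  if (!is.null(seed)) set.seed(seed)
  max_links <- sum(pmax(0, (B + 1):N - 1))   # forward pairs into non-basal nodes
  if (L < N - B || L > max_links)
    stop(sprintf("infeasible L = %d: need %d <= L <= %d", L, N - B, max_links))
  prey <- vapply((B + 1):N, function(j) sample.int(j - 1, 1), integer(1))
  skel <- cbind(prey, (B + 1):N)
  M <- L - (N - B)
  extra <- NULL
  if (M > 0) {
    jj <- unlist(lapply((B + 1):N, function(j) rep(j, j - 1)))
    ii <- unlist(lapply((B + 1):N, function(j) seq_len(j - 1)))
    key <- (ii - 1) * N + jj
    free <- !(key %in% ((skel[, 1] - 1) * N + skel[, 2]))
    pick <- sample(which(free), M)
    extra <- cbind(ii[pick], jj[pick])
  }
  edges <- rbind(skel, extra)
  wdt <- nchar(as.character(N))
  labels <- sprintf("s%0*d", wdt, 1:N)
  food_web(cbind(labels[edges[, 1]], labels[edges[, 2]]), nodes = labels)
}
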