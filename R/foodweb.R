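#' Construct a food web
#'
#' A food web is a simple directed graph whose links point from prey to
#' predator. Nodes are identified by character labels and stored in a
#' canonical (C-locale lexicographic) order so that adjacency-matrix indexing
#' is reproducible across runs. Duplicate links are collapsed and self-loops
#' (cannibalism) are dropped, each with a warning: the formalism underlying
#' trophic-level analysis is a binary adjacency matrix, and self-loops make
#' the trophic-level linear system ill-conditioned.
#'
#' @param edges a two-column matrix or data frame of character labels; column
#'   1 is the prey, column 2 the predator. May have zero rows.
#' @param nodes optional character vector of node labels; labels appearing in
#'   `edges` are added automatically. Use this to retain isolated nodes.
#' @return an object of class `food_web` with components `nodes` (character
#'   vector, canonical order) and `edges` (integer matrix, columns `prey`
#'   and `predator`, indices into `nodes`).
#' @seealso [read_edge_list()], [basal_species()], [validate_trophic()]
#' @export
food_web <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) {
    edges <- matrix(character(0), ncol = 2)
  }
  edges <- as.matrix(edges)
  if (length(edges) > 0 && ncol(edges) != 2)
    stop("`edges` must have exactly two columns (prey, predator)")
  storage.mode(edges) <- "character"
  labels <- sort(unique(c(nodes, as.vector(edges))), method = "radix")
  if (length(labels) < 1)
    stop("a food web needs at least one node")
  prey <- match(edges[, 1], labels)
  pred <- match(edges[, 2], labels)
  self <- prey == pred
  if (any(self)) {
    warning(sprintf("dropped %d self-loop(s) (cannibalistic links)", sum(self)))
    prey <- prey[!self]; pred <- pred[!self]
  }
  key <- (prey - 1) * length(labels) + pred
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate link(s)", sum(dup)))
    prey <- prey[!dup]; pred <- pred[!dup]
  }
  o <- order(prey, pred)
  new_food_web(labels, cbind(prey = prey[o], predator = pred[o]))
}

# Trusted constructor: labels already unique/sorted, edges an integer matrix
# with no loops or duplicates. Hot paths (model draws, rewiring) use this.
new_food_web <- function(nodes, edge_idx) {
  storage.mode(edge_idx) <- "integer"
  colnames(edge_idx) <- c("prey", "predator")
  structure(list(nodes = nodes, edges = edge_idx), class = "food_web")
}

#' @export
print.food_web <- function(x, ...) {
  cat(sprintf("Food web: %d species (%d basal), %d trophic links\n",
              n_species(x), length(basal_species(x)), n_links(x)))
  invisible(x)
}

#' Species, basal-species and link counts of a food web
#'
#' Basal species are the nodes with in-degree zero (no prey): the autotrophs
#' or producers of the web.
#'
#' @param web a `food_web`
#' @return `n_species()` and `n_links()` return single integers;
#'   `basal_species()` a character vector of labels; `in_degree()` and
#'   `out_degree()` named integer vectors over all nodes.
#' @export
n_species <- function(web) length(web$nodes)

#' @rdname n_species
#' @export
n_links <- function(web) nrow(web$edges)

#' @rdname n_species
#' @export
in_degree <- function(web) {
  k <- tabulate(web$edges[, "predator"], nbins = n_species(web))
  names(k) <- web$nodes
  k
}

#' @rdname n_species
#' @export
out_degree <- function(web) {
  k <- tabulate(web$edges[, "prey"], nbins = n_species(web))
  names(k) <- web$nodes
  k
}

#' @rdname n_species
#' @export
basal_species <- function(web) web$nodes[in_degree(web) == 0]

#' Convert a food web to an igraph graph
#'
#' @param web a `food_web`
#' @return a directed [igraph::igraph] graph; vertex order matches
#'   `web$nodes`.
#' @export
as_igraph <- function(web) {
  igraph::make_graph(t(web$edges), n = n_species(web), directed = TRUE)
}

# Inverse of as_igraph for graphs that kept the vertex count.
from_igraph <- function(g, nodes) {
  e <- igraph::as_edgelist(g, names = FALSE)
  new_food_web(nodes, e)
}

#' Check the preconditions for trophic-level analysis
#'
#' Trophic levels are only defined when the web has at least one basal
#' species and every node can be reached from some basal node by a directed
#' path. This returns a report rather than raising; downstream computations
#' raise on invalid webs.
#'
#' @param web a `food_web`
#' @return a list of class `trophic_validation`: `valid` (logical),
#'   `n_basal`, `unreachable` (labels of nodes with no directed path from any
#'   basal node) and `reason` (`NA` when valid).
#' @export
validate_trophic <- function(web) {
  basal <- which(in_degree(web) == 0)
  if (length(basal) == 0) {
    out <- list(valid = FALSE, n_basal = 0L, unreachable = web$nodes,
                reason = "no basal node (every species has at least one prey)")
  } else if (n_links(web) == 0) {
    out <- list(valid = TRUE, n_basal = length(basal),
                unreachable = character(0), reason = NA_character_)
  } else {
    g <- as_igraph(web)
    d <- igraph::distances(g, v = basal, mode = "out")
    reach <- apply(is.finite(d), 2, any)
    unreachable <- web$nodes[!reach]
    out <- list(valid = length(unreachable) == 0, n_basal = length(basal),
                unreachable = unreachable,
                reason = if (length(unreachable) == 0) NA_character_ else
                  "nodes unreachable from the basal set")
  }
  structure(out, class = "trophic_validation")
}

#' @export
print.trophic_validation <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("trophic-valid web (%d basal species)\n", x$n_basal))
  } else {
    cat("NOT trophic-valid:", x$reason, "\n")
    if (length(x$unreachable) && x$n_basal > 0)
      cat("  unreachable:", paste(x$unreachable, collapse = ", "), "\n")
  }
  invisible(x)
}

assert_trophic_valid <- function(web) {
  v <- validate_trophic(web)
  if (!v$valid) {
    if (v$n_basal == 0)
      stop("web is not trophic-valid: no basal node (zero in-degree) exists")
    stop(sprintf(
      "web is not trophic-valid: %d node(s) unreachable from any basal node (%s)",
      length(v$unreachable),
      paste(utils::head(v$unreachable, 5), collapse = ", ")))
  }
  invisible(v)
}

#' Read a food web from a plain-text edge list
#'
#' The format is one whitespace-separated `prey predator` pair per line,
#' `#` comments, UTF-8. An optional header line `#nodes: a b c ...` declares
#' the full node set so that isolated nodes survive a round trip. Datasets
#' using the opposite column convention (predator first) can be ingested with
#' `flip = TRUE`.
#'
#' @param path path to the edge-list file
#' @param flip if `TRUE`, treat column 1 as the predator and column 2 as the
#'   prey
#' @return a `food_web`
#' @export
read_edge_list <- function(path, flip = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  nodes <- character(0)
  hdr <- grepl("^#nodes:", lines)
  for (h in lines[hdr]) {
    toks <- strsplit(sub("^#nodes:", "", h), "[[:space:]]+")[[1]]
    nodes <- c(nodes, toks[nzchar(toks)])
  }
  body <- sub("#.*$", "", lines)
  body[hdr] <- ""
  keep <- which(grepl("[^[:space:]]", body))
  if (length(keep) == 0 && length(nodes) == 0)
    stop("empty edge list: ", path)
  prey <- pred <- character(length(keep))
  for (i in seq_along(keep)) {
    toks <- strsplit(trimws(body[keep[i]]), "[[:space:]]+")[[1]]
    if (length(toks) != 2)
      stop(sprintf("parse error at line %d of %s: expected 2 tokens, found %d",
                   keep[i], path, length(toks)))
    prey[i] <- toks[1]; pred[i] <- toks[2]
  }
  if (flip) { tmp <- prey; prey <- pred; pred <- tmp }
  food_web(cbind(prey, pred), nodes = nodes)
}

#' Write a food web as a plain-text edge list
#'
#' Writes a `#nodes:` header (so the node set, including isolated nodes,
#' survives a round trip) followed by one `prey predator` pair per line.
#' `read_edge_list(write_edge_list(web, f))` reproduces `web` exactly.
#'
#' @param web a `food_web`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_edge_list <- function(web, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste("#nodes:", paste(web$nodes, collapse = " ")), con)
  if (n_links(web) > 0)
    writeLines(paste(web$nodes[web$edges[, "prey"]],
                     web$nodes[web$edges[, "predator"]]), con)
  invisible(path)
}

#' Read a food web from a dense adjacency matrix (CSV)
#'
#' Expects a header row and a first column of node labels; entry 1 in row
#' `i`, column `j` encodes a link from prey `i` to predator `j`.
#'
#' @param path path to the CSV file
#' @return a `food_web`
#' @export
read_adjacency_matrix <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  if (nrow(m) != ncol(m) || !all(rownames(m) == colnames(m)))
    stop("adjacency matrix must be square with matching row/column labels")
  idx <- which(m != 0, arr.ind = TRUE)
  food_web(cbind(rownames(m)[idx[, 1]], colnames(m)[idx[, 2]]),
           nodes = rownames(m))
}

#' @export
`==.food_web` <- function(e1, e2) {
  identical(e1$nodes, e2$nodes) && identical(e1$edges, e2$edges)
}
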