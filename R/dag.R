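#' Directed acyclic graphs over symptom variables
#'
#' A `dag` is a lightweight container for a labelled directed acyclic graph:
#' an ordered character vector of node names plus an adjacency matrix.
#' `amat[i, j]` is `TRUE` when the graph contains the arc i -> j. The
#' constructor rejects self-loops, duplicated arcs, arcs over unknown nodes,
#' and any edge set admitting no topological order.
#'
#' @param nodes character vector of unique node names (order is preserved and
#'   used for deterministic tie-breaking throughout the package).
#' @param arcs a two-column `data.frame` or matrix (`from`, `to`), or `NULL`
#'   for the empty graph.
#' @return an object of class `dag`.
#' @examples
#' g <- dag(c("A", "B", "C"), data.frame(from = "A", to = "B"))
#' arcs(g)
#' @export
dag <- function(nodes, arcs = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicated node names")
  p <- length(nodes)
  amat <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  if (!is.null(arcs) && NROW(arcs) > 0) {
    arcs <- as.data.frame(arcs, stringsAsFactors = FALSE)
    from <- as.character(arcs[[1]])
    to <- as.character(arcs[[2]])
    bad <- setdiff(c(from, to), nodes)
    if (length(bad)) stop("arc endpoints not in node set: ", toString(bad))
    if (any(from == to)) stop("self-loops are not allowed")
    key <- paste(from, to)
    if (anyDuplicated(key)) stop("duplicated arcs")
    amat[cbind(match(from, nodes), match(to, nodes))] <- TRUE
  }
  g <- structure(list(nodes = nodes, amat = amat), class = "dag")
  if (is.null(topo_sort(g))) stop("arc set contains a cycle")
  g
}

#' @rdname dag
#' @export
empty_dag <- function(nodes) dag(nodes)

#' Arcs of a DAG
#'
#' @param g a `dag`.
#' @return `data.frame` with character columns `from` and `to`, ordered by
#'   (from, to) in node order.
#' @export
arcs <- function(g) {
  stopifnot(inherits(g, "dag"))
  idx <- which(g$amat, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(from = g$nodes[idx[, 1]], to = g$nodes[idx[, 2]],
                    stringsAsFactors = FALSE)
  out[order(idx[, 1], idx[, 2]), , drop = FALSE][, c("from", "to")]
}

#' @export
print.dag <- function(x, ...) {
  a <- arcs(x)
  cat("dag with", length(x$nodes), "nodes and", nrow(a), "arcs\n")
  if (nrow(a)) {
    cat(paste0("  ", a$from, " -> ", a$to, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Number of arcs
#' @param g a `dag`.
#' @export
narcs <- function(g) sum(g$amat)

#' Parents of a node
#' @param g a `dag`.
#' @param node node name.
#' @export
parents <- function(g, node) {
  stopifnot(node %in% g$nodes)
  g$nodes[g$amat[, node]]
}

#' Topological sort
#'
#' Kahn's algorithm over the adjacency matrix.
#'
#' @param g a `dag` (or a square logical adjacency matrix).
#' @return the node names in a topological order, or `NULL` if the graph is
#'   cyclic.
#' @export
topo_sort <- function(g) {
  amat <- if (inherits(g, "dag")) g$amat else g
  p <- nrow(amat)
  if (p == 0) return(character())
  indeg <- colSums(amat)
  order <- integer(0)
  active <- rep(TRUE, p)
  repeat {
    src <- which(active & indeg == 0)
    if (!length(src)) break
    order <- c(order, src)
    active[src] <- FALSE
    # removing the sources drops their out-arcs
    if (length(src) == 1) {
      indeg <- indeg - amat[src, ]
    } else {
      indeg <- indeg - colSums(amat[src, , drop = FALSE])
    }
    indeg[!active] <- 1L  # keep processed nodes out of the source set
    if (all(!active)) break
  }
  if (any(active)) return(NULL)
  rownames(amat)[order]
}

#' @rdname topo_sort
#' @export
is_acyclic <- function(g) !is.null(topo_sort(g))

# TRUE when a directed path from -> ... -> to exists in amat (DFS).
has_path <- function(amat, from, to) {
  if (from == to) return(TRUE)
  p <- nrow(amat)
  seen <- rep(FALSE, p)
  stack <- from
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v == to) return(TRUE)
    if (seen[v]) next
    seen[v] <- TRUE
    nxt <- which(amat[v, ] & !seen)
    if (length(nxt)) stack <- c(stack, nxt)
  }
  FALSE
}

set_arc <- function(g, from, to, value) {
  g$amat[from, to] <- value
  g
}

#' Structural Hamming distance between skeletons
#'
#' Counts the unordered node pairs adjacent in exactly one of the two graphs,
#' i.e. the number of edge insertions/deletions needed to turn one skeleton
#' into the other (orientation is ignored).
#'
#' @param g1,g2 `dag` objects over the same node set.
#' @export
shd_skeleton <- function(g1, g2) {
  if (!setequal(g1$nodes, g2$nodes)) stop("node sets differ")
  sk <- function(g) {
    a <- arcs(g)
    unique(paste(pmin(a$from, a$to), pmax(a$from, a$to)))
  }
  s1 <- sk(g1); s2 <- sk(g2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}
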