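#' Hill-climbing structure search under a decomposable BIC score
#'
#' Greedy local search over DAGs, the estimator used for the symptom
#' networks: starting from the empty graph, all single-arc additions,
#' deletions and reversals that keep the graph acyclic are enumerated, and
#' the move with the largest score improvement is applied while the best
#' improvement exceeds `epsilon`. Score deltas use decomposability: an
#' addition or deletion re-scores only the child, a reversal re-scores both
#' endpoints. The search is fully deterministic: ties on the score delta are
#' broken by move type (add < delete < reverse) and then by the (from, to)
#' position in column order.
#'
#' @inheritParams make_scorer
#' @param epsilon minimum score improvement for a move to be accepted
#'   (strict `>`); default 0.
#' @param restarts number of additional random restarts from perturbed
#'   graphs; 0 (the default) reproduces plain hill-climbing. Each restart
#'   perturbs the current optimum by `perturb` random arc flips and climbs
#'   again, keeping the best-scoring result.
#' @param perturb arc flips per restart.
#' @param seed RNG seed used only when `restarts > 0`.
#' @return a [dag()] with attributes `score` (total network score) and
#'   `trace` (score after each accepted move, strictly increasing).
#' @seealso [exhaustive_best_dag()] for the exact small-graph oracle,
#'   [arc_strength()] for score-based edge weights.
#' @export
hill_climb <- function(data, score_kind = c("bic_gaussian", "bic_discrete"),
                       epsilon = 0, restarts = 0, perturb = 4, seed = NULL) {
  score_kind <- match.arg(score_kind)
  scorer <- make_scorer(data, score_kind)
  nodes <- colnames(as.matrix(data))
  climb <- function(g) hc_climb(g, scorer, nodes, epsilon)
  best <- climb(empty_dag(nodes))
  if (restarts > 0) {
    if (!is.null(seed)) set.seed(seed)
    for (r in seq_len(restarts)) {
      cand <- climb(hc_perturb(best, perturb))
      if (attr(cand, "score") > attr(best, "score")) best <- cand
    }
  }
  best
}

# one greedy climb from a starting dag
hc_climb <- function(g, scorer, nodes, epsilon) {
  p <- length(nodes)
  amat <- g$amat
  ls <- vapply(nodes, function(nd) scorer(nd, nodes[amat[, nd]]), numeric(1))
  trace <- numeric(0)
  repeat {
    best <- NULL  # list(delta, rank, from, to); ties by type then names
    consider <- function(delta, rank, i, j) {
      ni <- nodes[i]; nj <- nodes[j]
      if (is.null(best) ||
          delta > best$delta + 1e-12 ||
          (abs(delta - best$delta) <= 1e-12 &&
           (rank < best$rank ||
            (rank == best$rank &&
             (ni < nodes[best$i] ||
              (ni == nodes[best$i] && nj < nodes[best$j]))))))
        best <<- list(delta = delta, rank = rank, i = i, j = j)
    }
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (i == j) next
      pj <- nodes[amat[, j]]
      if (!amat[i, j] && !amat[j, i]) {          # addition i -> j
        if (has_path(amat, j, i)) next
        d <- try_score(scorer, nodes[j], c(pj, nodes[i])) - ls[j]
        if (!is.na(d)) consider(d, 1L, i, j)
      } else if (amat[i, j]) {
        d_del <- try_score(scorer, nodes[j], setdiff(pj, nodes[i])) - ls[j]
        if (!is.na(d_del)) consider(d_del, 2L, i, j)   # deletion
        amat2 <- amat; amat2[i, j] <- FALSE            # reversal i->j to j->i
        if (!has_path(amat2, i, j)) {
          pi_ <- nodes[amat[, i]]
          d_rev <- d_del +
            try_score(scorer, nodes[i], c(pi_, nodes[j])) - ls[i]
          if (!is.na(d_rev)) consider(d_rev, 3L, i, j)
        }
      }
    }
    if (is.null(best) || best$delta <= epsilon) break
    i <- best$i; j <- best$j
    if (best$rank == 1L) {
      amat[i, j] <- TRUE
    } else if (best$rank == 2L) {
      amat[i, j] <- FALSE
    } else {
      amat[i, j] <- FALSE; amat[j, i] <- TRUE
      ls[i] <- scorer(nodes[i], nodes[amat[, i]])
    }
    ls[j] <- scorer(nodes[j], nodes[amat[, j]])
    trace <- c(trace, sum(ls))
  }
  out <- structure(list(nodes = nodes, amat = amat), class = "dag")
  attr(out, "score") <- sum(ls)
  attr(out, "trace") <- trace
  out
}

# NA when the candidate parent set is unscorable (e.g. collinear parents);
# such moves are simply not available.
try_score <- function(scorer, node, pa) {
  tryCatch(scorer(node, pa), error = function(e) NA_real_)
}

hc_perturb <- function(g, k) {
  nodes <- g$nodes
  p <- length(nodes)
  amat <- g$amat
  for (it in seq_len(k)) {
    i <- sample.int(p, 1); j <- sample.int(p, 1)
    if (i == j) next
    if (amat[i, j]) {
      amat[i, j] <- FALSE
    } else if (!amat[j, i]) {
      amat[i, j] <- TRUE
      if (is.null(topo_sort(amat))) amat[i, j] <- FALSE
    }
  }
  structure(list(nodes = nodes, amat = amat), class = "dag")
}

#' Enumerate every DAG on a small node set
#'
#' Recursive enumeration by per-node parent-set assignment with incremental
#' acyclicity pruning. The number of labelled DAGs grows super-exponentially
#' (1, 3, 25, 543, 29281 for p = 1..5), so this is restricted to p <= 5.
#'
#' @param nodes character vector of node names, length <= 5.
#' @return list of [dag()] objects in a canonical deterministic order.
#' @export
enumerate_dags <- function(nodes) {
  p <- length(nodes)
  if (p > 5) stop("enumeration is restricted to p <= 5 nodes")
  out <- list()
  amat <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  subsets <- function(set) {
    if (!length(set)) return(list(integer(0)))
    unlist(lapply(0:length(set), function(k)
      utils::combn(set, k, simplify = FALSE)), recursive = FALSE)
  }
  recurse <- function(m, amat) {
    if (m > p) {
      g <- structure(list(nodes = nodes, amat = amat), class = "dag")
      out[[length(out) + 1L]] <<- g
      return(invisible())
    }
    for (pa in subsets(setdiff(seq_len(p), m))) {
      amat[, m] <- FALSE
      amat[pa, m] <- TRUE
      if (!is.null(topo_sort(amat))) recurse(m + 1L, amat)
    }
  }
  recurse(1L, amat)
  out
}

#' Exact structure search by exhaustive enumeration
#'
#' Scores every DAG on the dataset's columns and returns a maximiser; the
#' test oracle against which [hill_climb()] is validated. Ties (e.g. between
#' score-equivalent DAGs) are broken by the canonical enumeration order, so
#' the result is deterministic. Refuses more than 5 columns.
#'
#' @inheritParams make_scorer
#' @return a [dag()] with attribute `score`.
#' @export
exhaustive_best_dag <- function(data,
                                score_kind = c("bic_gaussian",
                                               "bic_discrete")) {
  score_kind <- match.arg(score_kind)
  nodes <- colnames(as.matrix(data))
  if (length(nodes) > 5) stop("exhaustive search is restricted to p <= 5")
  scorer <- make_scorer(data, score_kind)
  best <- NULL
  best_score <- -Inf
  for (g in enumerate_dags(nodes)) {
    sc <- 0
    ok <- TRUE
    for (nd in nodes) {
      s <- try_score(scorer, nd, parents(g, nd))
      if (is.na(s)) { ok <- FALSE; break }
      sc <- sc + s
    }
    if (ok && sc > best_score + 1e-12) {
      best <- g
      best_score <- sc
    }
  }
  attr(best, "score") <- best_score
  best
}

#' Score-based arc strengths
#'
#' The strength of an arc is the change in the network score caused by
#' removing it: `score(dag without arc) - score(dag)`. Negative values mean
#' the arc improves the fit (removal worsens the score) — the convention in
#' which supported arcs of a locally optimal graph are all negative. By
#' decomposability the delta reduces to the child's local-score difference,
#' which is how it is computed.
#'
#' @inheritParams make_scorer
#' @param g a [dag()] over the dataset columns.
#' @return `data.frame` with columns `from`, `to`, `strength`, one row per
#'   arc of `g` (zero rows for an empty graph).
#' @export
arc_strength <- function(data, g,
                         score_kind = c("bic_gaussian", "bic_discrete")) {
  score_kind <- match.arg(score_kind)
  if (!setequal(g$nodes, colnames(data)))
    stop("dag nodes must match dataset columns")
  scorer <- make_scorer(data, score_kind)
  a <- arcs(g)
  a$strength <- vapply(seq_len(nrow(a)), function(r) {
    pa <- parents(g, a$to[r])
    scorer(a$to[r], setdiff(pa, a$from[r])) - scorer(a$to[r], pa)
  }, numeric(1))
  a
}
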