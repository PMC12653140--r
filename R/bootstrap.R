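#' Bootstrap replication of structure learning
#'
#' Learns one network per nonparametric bootstrap resample (rows drawn with
#' replacement, resample size = n). Each replicate uses its own RNG substream:
#' a vector of replicate seeds is drawn once from the master `seed`, so
#' replicate r is reproducible in isolation and the full collection is
#' reproducible from `(seed, R, data)` alone. A replicate whose resample is
#' unscorable (e.g. a resampled column goes constant) is logged and retried
#' with a fresh resample from the same substream, at most `max_retries`
#' times; it is never silently dropped.
#'
#' @inheritParams make_scorer
#' @param R number of bootstrap replicates (the reference analysis uses
#'   5000; reduced values are appropriate for tests and exploration).
#' @param seed master seed (integer).
#' @param epsilon passed to [hill_climb()].
#' @param max_retries resample retries per replicate before failing.
#' @return list of `R` [dag()] objects.
#' @export
bootstrap_networks <- function(data, R = 5000, seed = 1,
                               score_kind = c("bic_gaussian", "bic_discrete"),
                               epsilon = 0, max_retries = 3) {
  score_kind <- match.arg(score_kind)
  stopifnot(R >= 1)
  x <- as.data.frame(data)
  n <- nrow(x)
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, R)
  lapply(seq_len(R), function(r) {
    set.seed(rep_seeds[r])
    for (attempt in 0:max_retries) {
      idx <- sample.int(n, n, replace = TRUE)
      g <- tryCatch(hill_climb(x[idx, , drop = FALSE], score_kind,
                               epsilon = epsilon),
                    error = function(e) e)
      if (inherits(g, "dag")) return(g)
      message("replicate ", r, " attempt ", attempt + 1, " failed: ",
              conditionMessage(g), "; retrying with a fresh resample")
    }
    stop("replicate ", r, " failed after ", max_retries, " retries")
  })
}

#' Edge presence and direction frequencies across replicate networks
#'
#' For every unordered node pair, `strength` is the fraction of replicate
#' graphs containing the pair in either orientation; `direction` is the
#' fraction of those containing graphs that orient it `from -> to`
#' (conditional on presence, so the two orientations sum to 1). Pairs never
#' appearing are reported with strength 0 and direction `NA`.
#'
#' @param dags list of [dag()] objects sharing one node set.
#' @return `data.frame` with columns `from`, `to` (from < to in node order),
#'   `strength`, `direction`.
#' @export
edge_stability <- function(dags) {
  if (!length(dags)) stop("no replicate networks supplied")
  nodes <- dags[[1]]$nodes
  for (g in dags) {
    if (!identical(g$nodes, nodes)) stop("replicates have mismatched node sets")
  }
  p <- length(nodes)
  R <- length(dags)
  present <- matrix(0L, p, p)  # upper triangle: either-direction counts
  forward <- matrix(0L, p, p)  # upper triangle: i -> j counts
  for (g in dags) {
    a <- g$amat
    either <- a | t(a)
    present <- present + (upper.tri(present) & either)
    forward <- forward + (upper.tri(forward) & a)
  }
  idx <- which(upper.tri(present), arr.ind = TRUE)
  out <- data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                    strength = present[idx] / R,
                    direction = ifelse(present[idx] > 0,
                                       forward[idx] / present[idx], NA_real_),
                    stringsAsFactors = FALSE)
  out <- out[order(idx[, 1], idx[, 2]), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nodes") <- nodes
  out
}

#' Threshold-averaged network
#'
#' Builds the consensus graph from bootstrap stability frequencies: a node
#' pair is retained when its presence frequency meets `strength_threshold`
#' (default 0.85), and is oriented in the direction whose conditional
#' frequency meets `direction_threshold` (default 0.5). At the default
#' threshold exactly one orientation qualifies except at an exact 50/50 tie,
#' which is resolved towards the lexicographically smaller source node and
#' flagged with a warning and in the `tie` column. With a direction threshold
#' above 0.5 a retained pair may have no qualifying orientation; such pairs
#' are dropped from the graph and listed in the `undirected` attribute.
#'
#' @param stability output of [edge_stability()].
#' @param strength_threshold minimum presence frequency, in `[0, 1]`.
#' @param direction_threshold minimum conditional direction frequency.
#' @return list of class `averaged_network`: `dag`, `retained` (the decision
#'   table), `strength_threshold`, `direction_threshold`. Errors if the
#'   retained orientations form a cycle, listing it.
#' @export
averaged_network <- function(stability, strength_threshold = 0.85,
                             direction_threshold = 0.5) {
  stopifnot(strength_threshold >= 0, strength_threshold <= 1,
            direction_threshold >= 0, direction_threshold <= 1)
  nodes <- attr(stability, "nodes") %||%
    unique(c(stability$from, stability$to))
  keep <- stability[stability$strength >= strength_threshold &
                      stability$strength > 0, , drop = FALSE]
  from <- to <- character(0)
  tie <- logical(0)
  undirected <- keep[0, ]
  for (r in seq_len(nrow(keep))) {
    d_ab <- keep$direction[r]
    d_ba <- 1 - d_ab
    is_tie <- isTRUE(all.equal(d_ab, 0.5)) && direction_threshold <= 0.5
    if (is_tie) {
      warning("direction tie at 0.5 for pair ", keep$from[r], "-",
              keep$to[r], "; oriented by lexicographic node order")
      pair <- sort(c(keep$from[r], keep$to[r]))
      from <- c(from, pair[1]); to <- c(to, pair[2]); tie <- c(tie, TRUE)
    } else if (d_ab >= direction_threshold && d_ab >= d_ba) {
      from <- c(from, keep$from[r]); to <- c(to, keep$to[r])
      tie <- c(tie, FALSE)
    } else if (d_ba >= direction_threshold) {
      from <- c(from, keep$to[r]); to <- c(to, keep$from[r])
      tie <- c(tie, FALSE)
    } else {
      undirected <- rbind(undirected, keep[r, ])
      next
    }
  }
  amat <- matrix(FALSE, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
  amat[cbind(match(from, nodes), match(to, nodes))] <- TRUE
  if (is.null(topo_sort(amat))) {
    cyc <- find_cycle(amat)
    stop("averaged orientations form a cycle: ",
         paste(nodes[cyc], collapse = " -> "))
  }
  g <- structure(list(nodes = nodes, amat = amat), class = "dag")
  retained <- data.frame(from = from, to = to,
                         strength = keep$strength[
                           match(paste(pmin(from, to), pmax(from, to)),
                                 paste(pmin(keep$from, keep$to),
                                       pmax(keep$from, keep$to)))],
                         tie = tie, stringsAsFactors = FALSE)
  structure(list(dag = g, retained = retained,
                 strength_threshold = strength_threshold,
                 direction_threshold = direction_threshold,
                 undirected = undirected),
            class = "averaged_network")
}

#' @export
print.averaged_network <- function(x, ...) {
  cat(sprintf("averaged network (strength >= %.2f, direction >= %.2f)\n",
              x$strength_threshold, x$direction_threshold))
  print(x$dag)
  invisible(x)
}

# returns node indices of one directed cycle (for diagnostics)
find_cycle <- function(amat) {
  p <- nrow(amat)
  color <- integer(p)  # 0 white, 1 grey, 2 black
  stack <- integer(0)
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return(invisible())
    color[v] <<- 1L
    stack <<- c(stack, v)
    for (w in which(amat[v, ])) {
      if (!is.null(found)) break
      if (color[w] == 1L) {
        found <<- c(stack[which(stack == w)[1]:length(stack)], w)
      } else if (color[w] == 0L) visit(w)
    }
    stack <<- stack[-length(stack)]
    color[v] <<- 2L
  }
  for (v in seq_len(p)) if (color[v] == 0L && is.null(found)) visit(v)
  found
}
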