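# -- Markov blanket resampling ------------------------------------------------
#
# Large MCMC move: pick a GE node X, detach its parent set and its children's
# parent sets, then resample them sequentially from the BGe-score-proportional
# distribution over admissible, acyclicity-preserving, cap-respecting parent
# sets. The exact log proposal ratio is obtained by replaying the reverse
# construction (restoring the original parent sets) under the same kernel.

# enumerate all admissible parent sets of node j under the caps; cached.
# Returns list(sets = list of integer vectors, inc = incidence matrix
# n_sets x N, scores = NULL until first scored)
.node_parent_sets <- function(pm, j, max_sets = 50000L) {
  key <- paste0("psets_", j)
  got <- pm$cache[[key]]
  if (!is.null(got)) return(got)
  cand <- pm$cand[[j]]
  cs <- pm$constraints
  subsets_upto <- function(x, k) {
    x <- as.integer(x)
    out <- list(integer(0))
    k <- min(k, length(x))
    if (k >= 1 && length(x)) {
      for (r in seq_len(k)) {
        cmb <- utils::combn(seq_along(x), r, simplify = FALSE)  # indices: safe for length-1 x
        out <- c(out, lapply(cmb, function(ii) x[ii]))
      }
    }
    out
  }
  ge_sets <- subsets_upto(cand$ge, cs$max_ge_parents)
  cnv_sets <- subsets_upto(cand$cnv, cs$max_cnv_parents)
  meth_cap <- if (is.finite(cs$max_meth_parents)) cs$max_meth_parents else length(cand$meth)
  meth_sets <- subsets_upto(cand$meth, meth_cap)
  n_tot <- length(ge_sets) * length(cnv_sets) * length(meth_sets)
  if (n_tot > max_sets)
    stop(sprintf("node %d has %d admissible parent sets (> max_sets = %d)",
                 j, n_tot, max_sets))
  sets <- vector("list", n_tot)
  k <- 0L
  for (g in ge_sets) for (cv in cnv_sets) for (mt in meth_sets) {
    k <- k + 1L
    sets[[k]] <- c(g, cv, mt)
  }
  inc <- matrix(FALSE, n_tot, pm$N)
  for (s in seq_len(n_tot)) inc[s, sets[[s]]] <- TRUE
  lookup <- new.env(parent = emptyenv(), hash = TRUE)
  for (s in seq_len(n_tot))
    lookup[[paste0("s", paste(sort.int(sets[[s]]), collapse = ","))]] <- s
  res <- list(sets = sets, inc = inc, lookup = lookup)
  pm$cache[[key]] <- res
  res
}

# BGe scores of all parent sets of node j (computed once, cached)
.node_set_scores <- function(pm, sc, j) {
  key <- paste0("pscores_", j)
  got <- pm$cache[[key]]
  if (!is.null(got)) return(got)
  ps <- .node_parent_sets(pm, j)
  scores <- vapply(ps$sets, function(s) bge_node_score(sc, j, s), numeric(1))
  pm$cache[[key]] <- scores
  scores
}

# index of a parent set within the enumeration of node j
.find_set_index <- function(ps, parents) {
  idx <- ps$lookup[[paste0("s", paste(sort.int(as.integer(parents)), collapse = ","))]]
  if (is.null(idx)) NA_integer_ else idx
}

.logsumexp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

# one sequential blanket construction. If `forced` is NULL the sets are
# sampled; otherwise the given parent-set choices are replayed and only their
# log probability is accumulated (reverse-path probability).
.mbr_construct <- function(pm, sc, A, X, ch, forced = NULL) {
  G <- A
  G[, X] <- 0
  if (length(ch)) G[, ch] <- 0
  logp <- 0
  pieces <- vector("list", 1L + length(ch))
  targets <- c(X, ch)
  for (t in seq_along(targets)) {
    nd <- targets[t]
    ps <- .node_parent_sets(pm, nd)
    scores <- .node_set_scores(pm, sc, nd)
    desc <- which(.reach_mat(G)[nd, ])
    forb <- if (nd == X) union(desc, ch) else desc
    ok <- if (length(forb)) !(ps$inc[, forb, drop = FALSE] %*% rep(1, length(forb)) > 0)
          else rep(TRUE, length(ps$sets))
    if (nd != X) ok <- ok & ps$inc[, X]           # children must keep X as parent
    ok <- which(ok)
    if (!length(ok)) return(NULL)                 # no admissible reassignment
    if (is.null(forced)) {
      w <- scores[ok]
      pick <- ok[sample.int(length(ok), 1L, prob = exp(w - max(w)))]
    } else {
      pick <- .find_set_index(ps, forced[[t]])
      if (is.na(pick) || !(pick %in% ok)) return(list(logp = -Inf))
    }
    logp <- logp + scores[pick] - .logsumexp(scores[ok])
    newpa <- ps$sets[[pick]]
    G[, nd] <- 0
    if (length(newpa)) G[newpa, nd] <- 1
    pieces[[t]] <- newpa
  }
  list(G = G, logp = logp, pieces = pieces)
}

#' Propose a Markov-blanket-resampling move
#'
#' Picks a resampling node uniformly among GE nodes, detaches its parent set
#' and its children's parent sets, and redraws them sequentially in
#' proportion to `exp(BGe node score)` over the admissible,
#' acyclicity-preserving, cap-respecting parent sets (children are required
#' to retain the resampled node as a parent). The returned log proposal
#' ratio is the exact probability ratio of the reverse construction that
#' restores the original parent sets. When no admissible reassignment exists
#' the identity move is returned with ratio 0.
#'
#' @param pm a `bn_problem`.
#' @param sc a [bge_scorer()] on the problem data.
#' @param A current adjacency matrix.
#' @return list with `A` (candidate), `move` (kind `"mbr"`, resampled node,
#'   affected nodes), `log_q_ratio`.
#' @export
mbr_propose <- function(pm, sc, A) {
  if (!length(pm$ge_idx)) stop("no GE nodes to resample")
  X <- pm$ge_idx[sample.int(length(pm$ge_idx), 1L)]
  ch <- which(A[X, ] > 0)
  fwd <- .mbr_construct(pm, sc, A, X, ch, forced = NULL)
  if (is.null(fwd))
    return(list(A = A, move = list(kind = "mbr", node = X, targets = integer()),
                log_q_ratio = 0))
  old_sets <- lapply(c(X, ch), function(nd) which(A[, nd] > 0))
  rev <- .mbr_construct(pm, sc, A, X, ch, forced = old_sets)
  lqr <- (if (is.null(rev)) -Inf else rev$logp) - fwd$logp
  list(A = fwd$G, move = list(kind = "mbr", node = X, targets = c(X, ch),
                              new_sets = fwd$pieces, old_sets = old_sets),
       log_q_ratio = lqr)
}
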