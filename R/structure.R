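# -- basic DAG utilities on 0/1 adjacency matrices (A[i, j] = edge i -> j) --

# reachability by non-trivial directed path; R[i, j] TRUE iff i ~> j
.reach_mat <- function(A) {
  R <- A > 0
  repeat {
    R2 <- R | (R %*% A > 0)
    if (sum(R2) == sum(R)) break
    R <- R2
  }
  R
}

.has_cycle <- function(A) {
  any(diag(.reach_mat(A)))
}

# directed path from -> to using DFS (edges of A, length >= 1)
.has_path <- function(A, from, to) {
  stack <- which(A[from, ] > 0)
  if (!length(stack)) return(FALSE)
  seen <- logical(ncol(A)); seen[stack] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v == to) return(TRUE)
    nx <- which(A[v, ] > 0 & !seen)
    if (length(nx)) { seen[nx] <- TRUE; stack <- c(stack, nx) }
  }
  FALSE
}

#' Enumerate the single-edge move neighbourhood of a structure
#'
#' Lists all edge additions that keep acyclicity and respect type
#' admissibility and parent-count caps, all deletions of existing edges, and
#' all reversals that keep acyclicity, respect caps, and whose reversed pair
#' is itself admissible (in practice only GE-GE edges are reversible).
#'
#' @param pm a `bn_problem`.
#' @param A adjacency matrix.
#' @return integer matrix with columns `kind` (1 add, 2 delete, 3 reverse),
#'   `i`, `j`.
#' @export
enumerate_neighborhood <- function(pm, A) {
  parts <- .neighborhood_parts(pm, A)
  adds <- which(parts$M, arr.ind = TRUE)
  dels <- which(A > 0, arr.ind = TRUE)
  out <- rbind(
    if (nrow(adds)) cbind(1L, adds),
    if (nrow(dels)) cbind(2L, dels),
    if (any(parts$rev_ok)) cbind(3L, dels[parts$rev_ok, , drop = FALSE]))
  if (is.null(out)) out <- matrix(integer(), 0, 3)
  dimnames(out) <- list(NULL, c("kind", "i", "j"))
  out
}

# shared machinery of enumeration and counting: the add-candidate matrix M
# and, aligned with which(A > 0), the reversibility flags.
# A reversal i -> j is acyclic iff no alternative directed path i ~> j
# exists; such a path must start with an edge i -> k (k a child, k != i),
# and since k ~> i is impossible in a DAG it never uses the edge i -> j, so
# the check reduces to ((A %*% reach) > 0)[i, j].
.neighborhood_parts <- function(pm, A) {
  cs <- pm$constraints
  Rh <- .reach_mat(A)
  M <- pm$adm & (A == 0) & !t(Rh)
  pcge <- colSums(A[pm$ge_idx, , drop = FALSE] > 0)
  if (length(pm$ge_idx)) M[pm$ge_idx, pcge >= cs$max_ge_parents] <- FALSE
  if (length(pm$cnv_idx)) {
    pccnv <- colSums(A[pm$cnv_idx, , drop = FALSE] > 0)
    M[pm$cnv_idx, pccnv >= cs$max_cnv_parents] <- FALSE
  }
  if (length(pm$meth_idx) && is.finite(cs$max_meth_parents)) {
    pcmeth <- colSums(A[pm$meth_idx, , drop = FALSE] > 0)
    M[pm$meth_idx, pcmeth >= cs$max_meth_parents] <- FALSE
  }
  eidx <- which(A > 0)
  rev_ok <- logical(length(eidx))
  if (length(eidx)) {
    dels <- arrayInd(eidx, dim(A))
    ALT <- (A %*% Rh) > 0
    rev_ok <- pm$adm[cbind(dels[, 2], dels[, 1])] &
      pcge[dels[, 1]] < cs$max_ge_parents & !ALT[eidx]
  }
  list(M = M, rev_ok = rev_ok)
}

# |N(G)| without materialising the move list
.neighborhood_count <- function(pm, A) {
  parts <- .neighborhood_parts(pm, A)
  sum(parts$M) + sum(A > 0) + sum(parts$rev_ok)
}

.move_kinds <- c("add", "delete", "reverse")

#' Apply a single-edge move to an adjacency matrix
#'
#' @param A adjacency matrix.
#' @param move list with `kind` ("add"/"delete"/"reverse") and endpoints
#'   `i`, `j`.
#' @return the modified adjacency matrix.
#' @export
apply_move <- function(A, move) {
  i <- move$i; j <- move$j
  switch(move$kind,
    add = { if (A[i, j] > 0) stop("edge already present"); A[i, j] <- 1 },
    delete = { if (A[i, j] == 0) stop("edge not present"); A[i, j] <- 0 },
    reverse = {
      if (A[i, j] == 0) stop("edge not present")
      A[i, j] <- 0; A[j, i] <- 1
    },
    stop("unknown move kind"))
  A
}

#' Propose a uniformly drawn single-edge move with its Hastings ratio
#'
#' Draws uniformly over [enumerate_neighborhood()] and returns the candidate
#' structure together with the exact log proposal ratio
#' `log |N(G_s)| - log |N(G_c)|`.
#'
#' @param pm a `bn_problem`.
#' @param A current adjacency matrix.
#' @param nb optionally, a precomputed `enumerate_neighborhood(pm, A)` (an
#'   optimisation for chains that cache the current neighbourhood).
#' @return list with `A` (candidate), `move`, `log_q_ratio`, `n_nbhd`.
#' @export
propose_single_edge <- function(pm, A, nb = NULL) {
  if (is.null(nb)) nb <- enumerate_neighborhood(pm, A)
  if (nrow(nb) == 0L) stop("empty move neighbourhood")
  k <- nb[sample.int(nrow(nb), 1L), ]
  move <- list(kind = .move_kinds[k[["kind"]]], i = k[["i"]], j = k[["j"]])
  A2 <- apply_move(A, move)
  n2 <- .neighborhood_count(pm, A2)
  list(A = A2, move = move, log_q_ratio = log(nrow(nb)) - log(n2),
       n_nbhd = nrow(nb))
}

#' Metropolis-Hastings acceptance for a structure move
#'
#' Accepts with probability
#' `min(1, exp(score_delta + prior_delta + log_q_ratio))`.
#'
#' @param log_score_delta log-likelihood-score difference (candidate - current).
#' @param log_prior_delta log structure-prior difference.
#' @param log_q_ratio log proposal ratio `Q(G_s|G_c) / Q(G_c|G_s)`.
#' @return logical: accept the candidate?
#' @export
accept_structure <- function(log_score_delta, log_prior_delta = 0,
                             log_q_ratio = 0) {
  la <- log_score_delta + log_prior_delta + log_q_ratio
  if (is.nan(la)) stop("acceptance log ratio is NaN")
  la >= 0 || log(stats::runif(1)) < la
}
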