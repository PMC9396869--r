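#' Local energy of a node's parent set under the prior-knowledge matrix
#'
#' The energy of node j with parent set Pa is
#' \deqn{\varepsilon(j, Pa) = \sum_{i \in Pa} (1 - B_{ij}) +
#'   \sum_{i \in C_j \setminus Pa} B_{ij},}
#' where the second sum runs over the admissible candidate parents of j only.
#' Zero energy means perfect agreement with the prior knowledge.
#'
#' @param pm a `bn_problem`.
#' @param j child node index.
#' @param parents integer vector of parent indices (must be admissible for j).
#' @param B prior matrix (defaults to `pm$B`; pass a merged matrix to use
#'   empirical knowledge).
#' @return non-negative energy.
#' @export
local_energy <- function(pm, j, parents = integer(), B = pm$B) {
  cand <- pm$cand[[j]]$all
  if (length(setdiff(parents, cand)))
    stop("parent set contains non-admissible candidates for node ", j)
  b <- B[, j]
  if (anyNA(b[cand])) stop("missing B entry for an admissible pair of node ", j)
  sum(1 - b[parents]) + sum(b[setdiff(cand, parents)])
}

#' Total energy of a structure
#'
#' Sum of [local_energy()] over all nodes. Equals
#' `sum(B over admissible pairs) + sum over edges of (1 - 2 B_ij)`, so adding
#' edge i -> j changes the energy by `1 - 2 B_ij`.
#'
#' @param pm a `bn_problem`.
#' @param A adjacency matrix.
#' @param B prior matrix (defaults to `pm$B`).
#' @return non-negative energy.
#' @export
graph_energy <- function(pm, A, B = pm$B) {
  e <- sum(B[pm$adm])
  idx <- which(A > 0)
  if (length(idx)) e <- e + sum(1 - 2 * B[idx])
  e
}

# log of sum_{r=0..k} e_r(w) for w = exp(logw), elementary symmetric
# polynomials via a stable dynamic programme (weights scaled by max(logw))
.log_sum_esp <- function(logw, k) {
  cn <- length(logw)
  if (cn == 0L || k <= 0) return(0)
  k <- min(k, cn)
  a <- max(logw)
  wp <- exp(logw - a)
  e <- c(1, numeric(k))
  for (w in wp) {
    for (r in seq.int(k, 1L)) e[r + 1L] <- e[r + 1L] + w * e[r]
  }
  terms <- log(e) + (0:k) * a
  mx <- max(terms)
  mx + log(sum(exp(terms - mx)))
}

#' Log upper bound of the structure-prior partition function
#'
#' Node-decomposable bound: \eqn{\log Z(\beta) = \sum_j \log \sum_{Pa_j}
#' e^{-\beta \varepsilon(j, Pa_j)}} where the inner sum ranges over all
#' admissible, cap-respecting parent sets of node j, ignoring global
#' acyclicity (which is what makes it an upper bound of the true acyclic
#' partition sum). Using \eqn{e^{-\beta\varepsilon} =
#' e^{-\beta \sum_{i \in C_j} B_{ij}} \prod_{i \in Pa} w_i} with
#' \eqn{w_i = e^{-\beta(1 - 2B_{ij})}}, the per-type cardinality caps are
#' handled by summing elementary symmetric polynomials of the weights.
#'
#' @param pm a `bn_problem`.
#' @param beta prior-strength parameter (>= 0).
#' @param B prior matrix (defaults to `pm$B`).
#' @return log of the partition-function upper bound.
#' @export
log_partition_upper <- function(pm, beta, B = pm$B) {
  if (beta < 0) stop("beta must be non-negative")
  cs <- pm$constraints
  total <- 0
  for (j in seq_len(pm$N)) {
    cand <- pm$cand[[j]]
    if (!length(cand$all)) next
    b <- B[, j]
    total <- total - beta * sum(b[cand$all])
    lw <- function(ii) beta * (2 * b[ii] - 1)
    if (length(cand$ge))
      total <- total + .log_sum_esp(lw(cand$ge), cs$max_ge_parents)
    if (length(cand$cnv))
      total <- total + .log_sum_esp(lw(cand$cnv), cs$max_cnv_parents)
    if (length(cand$meth)) {
      if (is.finite(cs$max_meth_parents)) {
        total <- total + .log_sum_esp(lw(cand$meth), cs$max_meth_parents)
      } else {
        lwm <- lw(cand$meth)
        total <- total + sum(ifelse(lwm > 30, lwm, log1p(exp(lwm))))
      }
    }
  }
  total
}

#' Log prior probability of a structure
#'
#' \eqn{\log P(G \mid \beta) = -\beta E(G) - \log Z(\beta)} with the
#' partition-function upper bound of [log_partition_upper()]. Differences of
#' log priors between structures at fixed beta are exactly
#' \eqn{-\beta \Delta E} (the normaliser cancels).
#'
#' @param pm a `bn_problem`.
#' @param A adjacency matrix.
#' @param beta prior strength.
#' @param B prior matrix.
#' @param logZ optionally, a precomputed [log_partition_upper()] value.
#' @return log prior.
#' @export
log_prior_structure <- function(pm, A, beta, B = pm$B, logZ = NULL) {
  if (is.null(logZ)) logZ <- log_partition_upper(pm, beta, B)
  -beta * graph_energy(pm, A, B) - logZ
}

#' Log acceptance ratio for a prior-strength move
#'
#' For a fixed structure G, the Metropolis ratio of moving the prior
#' strength from `beta_s` to `beta_c`:
#' \eqn{-(\beta_c - \beta_s) E(G) - [\log Z(\beta_c) - \log Z(\beta_s)]}.
#'
#' @param pm a `bn_problem`.
#' @param A adjacency matrix.
#' @param beta_c,beta_s candidate and current strengths (both >= beta_min).
#' @param B prior matrix.
#' @return log ratio (exponentiates to `P(G|beta_c) / P(G|beta_s)`).
#' @export
log_beta_ratio <- function(pm, A, beta_c, beta_s, B = pm$B) {
  -(beta_c - beta_s) * graph_energy(pm, A, B) -
    (log_partition_upper(pm, beta_c, B) - log_partition_upper(pm, beta_s, B))
}
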