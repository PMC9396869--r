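#' BGe scorer for Gaussian Bayesian networks
#'
#' Precomputes the posterior parametric matrix of the normal-Wishart model so
#' that node scores are cheap submatrix determinants. The marginal likelihood
#' of a variable set Y of size l under the score-equivalent (corrected)
#' normalisation is
#' \deqn{p(d^Y) = \pi^{-nl/2} \Big(\frac{\alpha_\mu}{n+\alpha_\mu}\Big)^{l/2}
#'   \prod_{i=1}^{l}\frac{\Gamma((a+n+1-i)/2)}{\Gamma((a+1-i)/2)}
#'   \; t^{al/2} \, |R_Y|^{-(a+n)/2}, \quad a = \alpha_w - N + l,}
#' with \eqn{R = T + S + \frac{n\alpha_\mu}{n+\alpha_\mu}\bar{x}\bar{x}^\top},
#' \eqn{T = t I}, S the centred scatter matrix and prior mean 0 on
#' column-standardised data. The node score is
#' \eqn{\log p(d^{Pa \cup \{j\}}) - \log p(d^{Pa})}, which makes score
#' equivalence of Markov-equivalent DAGs automatic.
#'
#' @param data numeric matrix, samples x nodes.
#' @param alpha_mu prior precision on the mean (default 1).
#' @param alpha_w Wishart degrees of freedom; must exceed N + 1
#'   (default N + 2).
#' @param t_scale scale of the prior parametric matrix `T = t I`; default
#'   `alpha_mu * (alpha_w - N - 1) / (alpha_mu + 1)`, the value that preserves
#'   score equivalence.
#' @param standardize standardise columns to zero mean / unit variance
#'   (default TRUE; the prior mean is taken as 0).
#' @return An environment of class `bge_scorer`.
#' @export
bge_scorer <- function(data, alpha_mu = 1, alpha_w = NULL, t_scale = NULL,
                       standardize = TRUE) {
  data <- as.matrix(data)
  n <- nrow(data); N <- ncol(data)
  if (n < 2L) stop("need at least 2 observations")
  if (standardize) {
    sds <- apply(data, 2, stats::sd)
    if (any(!is.finite(sds) | sds == 0))
      stop("zero-variance column(s): ",
           paste(colnames(data)[!is.finite(sds) | sds == 0], collapse = ", "))
    data <- scale(data)
  }
  if (is.null(alpha_w)) alpha_w <- N + 2
  if (alpha_w <= N + 1) stop("alpha_w must exceed N + 1")
  if (alpha_mu <= 0) stop("alpha_mu must be positive")
  t <- if (is.null(t_scale)) alpha_mu * (alpha_w - N - 1) / (alpha_mu + 1) else t_scale
  if (t <= 0) stop("t_scale must be positive")
  xbar <- colMeans(data)
  S <- crossprod(sweep(data, 2, xbar))
  R <- diag(t, N) + S + (n * alpha_mu / (n + alpha_mu)) * tcrossprod(xbar)
  sc <- new.env(parent = emptyenv())
  sc$n <- n; sc$N <- N; sc$am <- alpha_mu; sc$aw <- alpha_w; sc$t <- t
  sc$R <- R
  sc$set_cache <- new.env(parent = emptyenv(), hash = TRUE)
  sc$hits <- 0L; sc$misses <- 0L
  class(sc) <- "bge_scorer"
  sc
}

# log marginal likelihood of the variable subset Y (integer column indices)
.bge_set_logml <- function(sc, Y) {
  l <- length(Y)
  if (l == 0L) return(0)
  key <- paste(sort.int(Y), collapse = ",")
  got <- sc$set_cache[[key]]
  if (!is.null(got)) { sc$hits <- sc$hits + 1L; return(got) }
  sc$misses <- sc$misses + 1L
  n <- sc$n; a <- sc$aw - sc$N + l
  RY <- sc$R[Y, Y, drop = FALSE]
  ld <- determinant(RY, logarithm = TRUE)
  if (ld$sign <= 0 || !is.finite(ld$modulus))
    stop("singular posterior scatter matrix (collinear columns?); ",
         "consider a ridge term or checking the data")
  i <- seq_len(l)
  val <- -(l * n / 2) * log(pi) + (l / 2) * log(sc$am / (n + sc$am)) +
    sum(lgamma((a + n + 1 - i) / 2) - lgamma((a + 1 - i) / 2)) +
    (a * l / 2) * log(sc$t) - ((a + n) / 2) * as.numeric(ld$modulus)
  sc$set_cache[[key]] <- val
  val
}

#' Local BGe score of one node given a parent set
#'
#' Deterministic log marginal likelihood contribution of `node` with parents
#' `parents`. Degenerate (collinear) parent sets raise an error rather than
#' returning `NaN`.
#'
#' @param sc a [bge_scorer()].
#' @param node integer column index of the child.
#' @param parents integer vector of parent column indices (possibly empty).
#' @return log score (numeric scalar).
#' @export
bge_node_score <- function(sc, node, parents = integer()) {
  parents <- as.integer(parents)
  if (node %in% parents) stop("a node cannot be its own parent")
  .bge_set_logml(sc, c(parents, node)) - .bge_set_logml(sc, parents)
}

#' Total BGe score of a DAG
#'
#' Sum of [bge_node_score()] over all nodes; the score of the graph's
#' factorised Gaussian likelihood. Uses and fills the scorer's cache.
#'
#' @param sc a [bge_scorer()].
#' @param A adjacency matrix (`A[i, j] != 0` means edge i -> j); must be a DAG.
#' @return log score.
#' @export
bge_graph_score <- function(sc, A) {
  if (.has_cycle(A)) stop("graph is not acyclic")
  s <- 0
  for (j in seq_len(ncol(A))) s <- s + bge_node_score(sc, j, which(A[, j] > 0))
  s
}

#' Score change of a single-edge move
#'
#' Returns `log score(G') - log score(G)` touching only the affected nodes:
#' the child for add/delete, both endpoints for reverse.
#'
#' @param sc a [bge_scorer()].
#' @param A current adjacency matrix.
#' @param move list with `kind` in `"add"`, `"delete"`, `"reverse"` and
#'   integer endpoints `i`, `j` (edge i -> j).
#' @return log score delta.
#' @export
bge_delta <- function(sc, A, move) {
  i <- move$i; j <- move$j
  pa_j <- which(A[, j] > 0)
  switch(move$kind,
    add = {
      if (A[i, j] > 0) stop("edge already present")
      bge_node_score(sc, j, c(pa_j, i)) - bge_node_score(sc, j, pa_j)
    },
    delete = {
      if (A[i, j] == 0) stop("edge not present")
      bge_node_score(sc, j, setdiff(pa_j, i)) - bge_node_score(sc, j, pa_j)
    },
    reverse = {
      if (A[i, j] == 0) stop("edge not present")
      pa_i <- which(A[, i] > 0)
      (bge_node_score(sc, j, setdiff(pa_j, i)) - bge_node_score(sc, j, pa_j)) +
        (bge_node_score(sc, i, c(pa_i, j)) - bge_node_score(sc, i, pa_i))
    },
    stop("unknown move kind: ", move$kind))
}
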