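# Brute-force oracles and fixture builders shared across the suite.
# All oracles are independent of the package's implementation paths they
# check: enumeration, closed forms and equivalence-class definitions only.

# all DAG adjacency matrices over N nodes restricted to admissible pairs
all_dags <- function(N, adm = NULL) {
  if (is.null(adm)) { adm <- matrix(TRUE, N, N); diag(adm) <- FALSE }
  pairs <- which(adm, arr.ind = TRUE)
  np <- nrow(pairs)
  out <- list()
  for (mask in 0:(2^np - 1)) {
    A <- matrix(0, N, N)
    bits <- which(bitwAnd(mask, 2^(seq_len(np) - 1)) > 0)
    for (b in bits) A[pairs[b, 1], pairs[b, 2]] <- 1
    if (oracle_is_acyclic(A)) out[[length(out) + 1]] <- A
  }
  out
}

# Kahn's algorithm: repeatedly remove zero-in-degree nodes
oracle_is_acyclic <- function(A) {
  N <- ncol(A); alive <- rep(TRUE, N)
  for (step in seq_len(N)) {
    indeg <- colSums(A[alive, , drop = FALSE])
    cand <- which(alive & indeg == 0)
    if (!length(cand)) break
    alive[cand] <- FALSE
  }
  !any(alive)
}

# v-structure triple set of a DAG, as sorted strings "i<j>k" with i < k
v_structures <- function(A) {
  N <- ncol(A)
  out <- character(0)
  for (j in seq_len(N)) {
    pa <- which(A[, j] > 0)
    if (length(pa) < 2) next
    for (a in utils::combn(pa, 2, simplify = FALSE)) {
      i <- min(a); k <- max(a)
      if (A[i, k] == 0 && A[k, i] == 0)
        out <- c(out, paste(i, j, k, sep = "<"))
    }
  }
  sort(out)
}

skeleton_key <- function(A) paste(as.integer((A + t(A)) > 0), collapse = "")

# brute-force CPDAG: enumerate the whole equivalence class, mark an edge
# compelled iff it has the same orientation in every member
cpdag_oracle <- function(A, dag_pool) {
  key <- skeleton_key(A); vs <- v_structures(A)
  members <- Filter(function(G) skeleton_key(G) == key &&
                      identical(v_structures(G), vs), dag_pool)
  S <- Reduce(`+`, members)
  N <- ncol(A)
  C <- matrix(0L, N, N)
  idx <- which(A > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    if (S[i, j] == length(members) && S[j, i] == 0) C[i, j] <- 1L
    else { C[i, j] <- 2L; C[j, i] <- 2L }
  }
  C
}

# exact edge posterior over admissible DAGs by full enumeration
exact_edge_posterior <- function(pm, sc, beta, dags, B = pm$B) {
  lp <- vapply(dags, function(A)
    bge_graph_score(sc, A) - beta * graph_energy(pm, A, B), numeric(1))
  w <- exp(lp - max(lp)); w <- w / sum(w)
  Reduce(`+`, Map(function(A, wi) A * wi, dags, w))
}

# GE-only dataset from a raw matrix (adds sample/gene names if missing)
make_ge_dataset <- function(mat) {
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("G%02d", seq_len(ncol(mat)))
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("S%03d", seq_len(nrow(mat)))
  omics_dataset(mat)
}

make_ge_problem <- function(mat, ...) {
  assemble_network_problem(make_ge_dataset(mat), ...)
}

# small typed problem: n_g genes, a CNV on gene 1, strong chain
# cnv_G01 -> G01 -> G02 (coefs 0.9); extra independent genes
make_anchored_dataset <- function(m, n_extra = 1) {
  ge1 <- stats::rnorm(m)
  cnv <- stats::rnorm(m)
  g1 <- 0.9 * cnv + stats::rnorm(m)
  g2 <- 0.9 * g1 + stats::rnorm(m)
  ge <- cbind(G01 = g1, G02 = g2)
  if (n_extra > 0) {
    extra <- matrix(stats::rnorm(m * n_extra), m,
                    dimnames = list(NULL, sprintf("G%02d", 2 + seq_len(n_extra))))
    ge <- cbind(ge, extra)
  }
  rownames(ge) <- sprintf("S%03d", seq_len(m))
  omics_dataset(ge, cnv = matrix(cnv, m, 1, dimnames = list(rownames(ge), "cnv_G01")),
                cnv_map = c(cnv_G01 = "G01"))
}
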