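#' Parent-count constraints for typed network nodes
#'
#' Transcription of a gene is typically controlled by few regulators, so each
#' GE node may have at most `max_ge_parents` GE parents and at most one CNV
#' parent (its own gene's copy number). METH parents (probes of the own gene)
#' are unlimited by default. CNV and METH nodes never have parents.
#'
#' @param max_ge_parents maximum GE parents per GE node (default 3).
#' @param max_cnv_parents maximum CNV parents per GE node (default 1).
#' @param max_meth_parents maximum METH parents per GE node (default `Inf`).
#' @return A list of class `bn_constraints`.
#' @export
bn_constraints <- function(max_ge_parents = 3L, max_cnv_parents = 1L,
                           max_meth_parents = Inf) {
  stopifnot(max_ge_parents >= 0, max_cnv_parents >= 0, max_meth_parents >= 0)
  structure(list(max_ge_parents = max_ge_parents,
                 max_cnv_parents = max_cnv_parents,
                 max_meth_parents = max_meth_parents),
            class = "bn_constraints")
}

#' Read prior-knowledge edges from a TSV file
#'
#' Accepts either a three-column edge list (`source`, `target`, `value`) or a
#' square matrix with gene symbols as dimnames. Values must lie in `[0, 1]`;
#' the conventional encoding is 1 for a known direct interaction, 0.75 for a
#' transcription-factor/target pair, 0 for a known non-edge and 0.5 (or
#' absence) for "no knowledge".
#'
#' @param path TSV file path.
#' @return data.frame with columns `from`, `to`, `value`.
#' @export
read_prior_edges <- function(path) {
  if (!file.exists(path)) stop("prior file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) >= 3 && all(c("source", "target", "value") %in% names(df))) {
    out <- data.frame(from = df$source, to = df$target, value = as.numeric(df$value))
  } else {
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    idx <- which(!is.na(m), arr.ind = TRUE)
    out <- data.frame(from = rownames(m)[idx[, 1]], to = colnames(m)[idx[, 2]],
                      value = m[idx])
  }
  if (any(out$value < 0 | out$value > 1))
    stop("prior values must lie in [0, 1]")
  out
}

.prov_of <- function(v) {
  ifelse(v == 1, "database_edge",
         ifelse(v == 0.75, "tf_target",
                ifelse(v == 0, "forbidden",
                       ifelse(v == 0.5, "unknown", "user"))))
}

#' Assemble a typed Bayesian-network problem from an omics dataset
#'
#' Builds the node table (one GE node per gene, one CNV node per mapped CNV
#' feature, one METH node per probe passing [screen_meth_probes()]), the
#' column-standardised data matrix (METH probes are ordered-quantile
#' transformed first), the type-admissibility relation, and the
#' prior-knowledge matrix B. Admissible parent-child pairs are GE -> GE
#' (between distinct genes) and CNV/METH -> GE restricted to the own gene;
#' CNV and METH nodes have no parents. Pairs not covered by `prior` default to
#' B = 0.5 ("no knowledge"): for CNV/METH -> GE pairs no interaction database
#' exists, and these are exactly the entries the empirical-knowledge phase of
#' the sampler later fills in.
#'
#' @param ds an `omics_dataset`.
#' @param prior `NULL`, a data.frame (`from`, `to`, `value` in node ids /
#'   gene symbols) or a path readable by [read_prior_edges()].
#' @param constraints a [bn_constraints()] object.
#' @param screen logical; run the methylation probe screen (default TRUE).
#' @param meth_p_threshold,meth_r2_threshold thresholds passed to
#'   [screen_meth_probes()].
#' @return A list of class `bn_problem` with elements `data` (standardised
#'   m x N matrix), `nodes` (data.frame `id`, `type`, `gene`), `adm` (logical
#'   N x N admissibility), `B` (numeric N x N prior, `NA` off-support),
#'   `prov` (provenance), `constraints`, and candidate-parent bookkeeping.
#' @export
assemble_network_problem <- function(ds, prior = NULL,
                                     constraints = bn_constraints(),
                                     screen = TRUE,
                                     meth_p_threshold = 0.05,
                                     meth_r2_threshold = 0.3) {
  genes <- colnames(ds$ge)
  cnv_feats <- names(ds$cnv_map)
  meth_probes <- colnames(ds$meth)
  if (length(meth_probes) && screen) {
    sc <- screen_meth_probes(ds, meth_p_threshold, meth_r2_threshold)
    meth_probes <- sc$probe[sc$selected]
  }
  meth_probes <- meth_probes[meth_probes %in% names(ds$meth_map)]
  nodes <- rbind(
    data.frame(id = genes, type = "GE", gene = genes),
    if (length(cnv_feats)) data.frame(id = cnv_feats, type = "CNV",
                                      gene = unname(ds$cnv_map[cnv_feats])),
    if (length(meth_probes)) data.frame(id = meth_probes, type = "METH",
                                        gene = unname(ds$meth_map[meth_probes])))
  rownames(nodes) <- NULL
  N <- nrow(nodes)
  meth_cols <- if (length(meth_probes))
    apply(ds$meth[, meth_probes, drop = FALSE], 2, orq_transform) else NULL
  dat <- cbind(ds$ge,
               if (length(cnv_feats)) ds$cnv[, cnv_feats, drop = FALSE],
               meth_cols)
  dat <- dat[, nodes$id, drop = FALSE]
  sds <- apply(dat, 2, stats::sd)
  if (any(sds == 0)) stop("zero-variance node column(s): ",
                          paste(nodes$id[sds == 0], collapse = ", "))
  dat <- scale(dat)
  attr(dat, "scaled:center") <- NULL
  attr(dat, "scaled:scale") <- NULL

  type <- nodes$type
  adm <- matrix(FALSE, N, N, dimnames = list(nodes$id, nodes$id))
  is_ge <- type == "GE"
  adm[is_ge, is_ge] <- TRUE
  diag(adm) <- FALSE
  for (i in which(!is_ge)) {
    j <- match(nodes$gene[i], nodes$id)
    if (!is.na(j)) adm[i, j] <- TRUE
  }

  B <- matrix(NA_real_, N, N, dimnames = dimnames(adm))
  B[adm] <- 0.5
  prov <- matrix(NA_character_, N, N, dimnames = dimnames(adm))
  prov[adm] <- "unknown"
  if (!is.null(prior)) {
    if (is.character(prior)) prior <- read_prior_edges(prior)
    for (k in seq_len(nrow(prior))) {
      i <- match(prior$from[k], nodes$id); j <- match(prior$to[k], nodes$id)
      if (is.na(i) || is.na(j) || !adm[i, j]) {
        warning(sprintf("prior entry %s -> %s is not an admissible pair; ignored",
                        prior$from[k], prior$to[k]))
        next
      }
      B[i, j] <- prior$value[k]
      prov[i, j] <- .prov_of(prior$value[k])
    }
  }

  prob <- structure(list(
    data = dat, nodes = nodes, N = N, m = nrow(dat),
    ge_idx = which(type == "GE"), cnv_idx = which(type == "CNV"),
    meth_idx = which(type == "METH"),
    adm = adm, B = B, prov = prov, constraints = constraints,
    cache = new.env(parent = emptyenv())), class = "bn_problem")
  prob$cand <- .candidate_lists(prob)
  prob
}

# per-child lists of admissible candidate parents, split by parent type
.candidate_lists <- function(pm) {
  lapply(seq_len(pm$N), function(j) {
    cand <- which(pm$adm[, j])
    list(ge = intersect(cand, pm$ge_idx),
         cnv = intersect(cand, pm$cnv_idx),
         meth = intersect(cand, pm$meth_idx),
         all = cand)
  })
}

#' @export
print.bn_problem <- function(x, ...) {
  cat(sprintf("bn_problem: %d samples, %d nodes (%d GE, %d CNV, %d METH), %d admissible pairs\n",
              x$m, x$N, length(x$ge_idx), length(x$cnv_idx), length(x$meth_idx),
              sum(x$adm)))
  invisible(x)
}

# empty adjacency for a problem (numeric 0/1, parents in rows, children in columns)
empty_graph <- function(pm) {
  matrix(0, pm$N, pm$N, dimnames = list(pm$nodes$id, pm$nodes$id))
}

# per-type cap for a parent node index
.cap_for_parent <- function(pm, i) {
  switch(pm$nodes$type[i],
         GE = pm$constraints$max_ge_parents,
         CNV = pm$constraints$max_cnv_parents,
         METH = pm$constraints$max_meth_parents)
}

#' Validate a structure against acyclicity, admissibility and parent caps
#'
#' @param A adjacency matrix (`A[i, j] != 0` means edge i -> j).
#' @param pm a `bn_problem`.
#' @return logical: does `A` satisfy all structural constraints?
#' @export
graph_is_valid <- function(A, pm) {
  if (any(A > 0 & !pm$adm)) return(FALSE)
  for (j in seq_len(pm$N)) {
    pa <- which(A[, j] > 0)
    if (length(intersect(pa, pm$ge_idx)) > pm$constraints$max_ge_parents) return(FALSE)
    if (length(intersect(pa, pm$cnv_idx)) > pm$constraints$max_cnv_parents) return(FALSE)
    if (length(intersect(pa, pm$meth_idx)) > pm$constraints$max_meth_parents) return(FALSE)
  }
  !.has_cycle(A)
}
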