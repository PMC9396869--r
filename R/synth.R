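#' Random typed ground-truth model for multi-omics simulation
#'
#' Samples a GE-GE skeleton under a random topological order with at most
#' `max_ge_parents` GE parents per gene, then attaches a CNV parent to
#' `n_cnv` randomly chosen genes (positive gene-dosage coefficients) and a
#' METH probe parent to `n_meth` chosen genes (sign given by `meth_sign`,
#' promoter methylation typically down-regulating expression). Coefficients
#' are drawn from `+/- U[coef_range]`, bounded away from zero.
#'
#' @param n_genes number of genes.
#' @param edge_density probability that an admissible ancestor-ordered gene
#'   pair carries an edge (before the parent cap).
#' @param n_cnv number of genes with a CNV parent; a fraction in `[0, 1)` is
#'   converted via `round(n_genes * n_cnv)`.
#' @param n_meth number of genes with a METH probe parent (same convention).
#' @param coef_range absolute-coefficient range (default `c(0.3, 1)`).
#' @param meth_sign sign of methylation effects (default -1).
#' @param noise_sd Gaussian noise s.d. per GE node (default 1).
#' @param max_ge_parents GE-parent cap (default 3, matching the network
#'   constraints).
#' @return list of class `bn_truth`: node ids, typed edge list with
#'   coefficients, and simulation parameters.
#' @export
random_typed_dag <- function(n_genes, edge_density = 0.25,
                             n_cnv = 0, n_meth = 0,
                             coef_range = c(0.3, 1), meth_sign = -1,
                             noise_sd = 1, max_ge_parents = 3L) {
  stopifnot(n_genes >= 2, edge_density >= 0, edge_density < 1)
  if (n_cnv > 0 && n_cnv < 1) n_cnv <- round(n_genes * n_cnv)
  if (n_meth > 0 && n_meth < 1) n_meth <- round(n_genes * n_meth)
  stopifnot(n_cnv <= n_genes, n_meth <= n_genes)
  genes <- sprintf("G%02d", seq_len(n_genes))
  ord <- sample(n_genes)
  edges <- NULL
  rcoef <- function(k) stats::runif(k, coef_range[1], coef_range[2]) *
    sample(c(-1, 1), k, replace = TRUE)
  for (p in seq_len(n_genes)[-1]) {
    j <- ord[p]
    anc <- ord[seq_len(p - 1)]
    pa <- anc[stats::runif(p - 1) < edge_density]
    if (length(pa) > max_ge_parents) pa <- sample(pa, max_ge_parents)
    if (length(pa))
      edges <- rbind(edges, data.frame(from = genes[pa], to = genes[j],
                                       type = "GE", coef = rcoef(length(pa))))
  }
  cnv_genes <- if (n_cnv) sort(sample(n_genes, n_cnv)) else integer(0)
  meth_genes <- if (n_meth) sort(sample(n_genes, n_meth)) else integer(0)
  if (length(cnv_genes))
    edges <- rbind(edges, data.frame(
      from = paste0("cnv_", genes[cnv_genes]), to = genes[cnv_genes],
      type = "CNV",
      coef = stats::runif(length(cnv_genes), coef_range[1], coef_range[2])))
  if (length(meth_genes))
    edges <- rbind(edges, data.frame(
      from = paste0("meth_", genes[meth_genes]), to = genes[meth_genes],
      type = "METH",
      coef = meth_sign * stats::runif(length(meth_genes), coef_range[1], coef_range[2])))
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        type = character(), coef = numeric())
  structure(list(genes = genes, order = genes[ord],
                 cnv_genes = genes[cnv_genes], meth_genes = genes[meth_genes],
                 edges = edges, noise_sd = noise_sd, meth_sign = meth_sign),
            class = "bn_truth")
}

#' Simulate multi-omics data from a ground-truth model
#'
#' Ancestral sampling of the linear-Gaussian structural equations: CNV root
#' nodes are N(0, 1) (standing in for segment means), METH root nodes are
#' drawn in a latent Gaussian space and reported as beta-values through the
#' logistic function, and each GE node is the coefficient-weighted sum of its
#' parents (METH parents contribute their latent Gaussian value) plus
#' N(0, noise_sd^2) noise.
#'
#' @param model a [random_typed_dag()] ground truth.
#' @param m number of samples (>= 2).
#' @return an [omics_dataset()].
#' @export
simulate_multiomics <- function(model, m) {
  stopifnot(m >= 2)
  genes <- model$genes
  samples <- sprintf("S%03d", seq_len(m))
  typed_mat <- function(genes_of_type, prefix) {
    x <- matrix(stats::rnorm(m * length(genes_of_type)), nrow = m,
                ncol = length(genes_of_type))
    rownames(x) <- samples
    if (length(genes_of_type)) colnames(x) <- paste0(prefix, genes_of_type)
    x
  }
  cnv <- typed_mat(model$cnv_genes, "cnv_")
  meth_lat <- typed_mat(model$meth_genes, "meth_")
  ge <- matrix(0, m, length(genes), dimnames = list(samples, genes))
  for (g in model$order) {
    x <- stats::rnorm(m, 0, model$noise_sd)
    pe <- model$edges[model$edges$to == g, , drop = FALSE]
    if (nrow(pe)) for (k in seq_len(nrow(pe))) {
      pv <- switch(pe$type[k],
                   GE = ge[, pe$from[k]],
                   CNV = cnv[, pe$from[k]],
                   METH = meth_lat[, pe$from[k]])
      x <- x + pe$coef[k] * pv
    }
    ge[, g] <- x
  }
  meth <- meth_lat
  meth[] <- stats::plogis(meth_lat)   # keep dims even for zero columns
  cnv_map <- if (length(model$cnv_genes))
    stats::setNames(model$cnv_genes, paste0("cnv_", model$cnv_genes)) else character()
  meth_map <- if (length(model$meth_genes))
    stats::setNames(model$meth_genes, paste0("meth_", model$meth_genes)) else character()
  omics_dataset(ge, cnv, meth, cnv_map, meth_map)
}

#' Corrupted prior knowledge retaining a fraction of the true edges
#'
#' Emulates incomplete database knowledge: a uniformly random
#' `floor(keep_fraction * n_edges)` subset of the true GE-GE edges is encoded
#' with B = 1; every other admissible pair is left at the no-knowledge value
#' 0.5 (by omission).
#'
#' @param model a [random_typed_dag()] ground truth.
#' @param keep_fraction fraction of true GE-GE edges to reveal, in `[0, 1]`.
#' @return data.frame (`from`, `to`, `value`) usable as the `prior` argument
#'   of [assemble_network_problem()].
#' @export
corrupt_prior <- function(model, keep_fraction) {
  stopifnot(keep_fraction >= 0, keep_fraction <= 1)
  gg <- model$edges[model$edges$type == "GE", , drop = FALSE]
  k <- floor(keep_fraction * nrow(gg))
  if (k == 0)
    return(data.frame(from = character(), to = character(), value = numeric()))
  keep <- sample(nrow(gg), k)
  data.frame(from = gg$from[keep], to = gg$to[keep], value = 1)
}

#' Gold-standard edge set and evaluable pair universe of a ground truth
#'
#' @param model a [random_typed_dag()] ground truth.
#' @param ge_only restrict the universe to GE-GE pairs (used when comparing
#'   with expression-only methods).
#' @return list with `gold` (data.frame `from`, `to`) and `universe`
#'   (data.frame of ordered evaluable pairs).
#' @export
gold_standard <- function(model, ge_only = FALSE) {
  genes <- model$genes
  uni <- expand.grid(from = genes, to = genes, stringsAsFactors = FALSE)
  uni <- uni[uni$from != uni$to, ]
  if (!ge_only) {
    if (length(model$cnv_genes))
      uni <- rbind(uni, data.frame(from = paste0("cnv_", model$cnv_genes),
                                   to = model$cnv_genes))
    if (length(model$meth_genes))
      uni <- rbind(uni, data.frame(from = paste0("meth_", model$meth_genes),
                                   to = model$meth_genes))
  }
  gold <- model$edges[, c("from", "to")]
  if (ge_only) gold <- gold[model$edges$type == "GE", ]
  rownames(uni) <- rownames(gold) <- NULL
  list(gold = gold, universe = uni)
}
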