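#' Convert a DAG to its completed partially directed acyclic graph
#'
#' Identifies the compelled edges of the Markov equivalence class by the
#' order-based edge-labelling algorithm: edges are visited in an ordering
#' induced by a topological sort and labelled compelled or reversible, so
#' that an edge ends up directed in the CPDAG iff it has the same
#' orientation in every DAG of the equivalence class (v-structure edges and
#' their logical consequences).
#'
#' @param A adjacency matrix of a DAG.
#' @return integer matrix `C` with `C[i, j] == 1` for a compelled edge
#'   i -> j and `C[i, j] == C[j, i] == 2` for a reversible (undirected) edge;
#'   class `bn_cpdag`.
#' @export
dag_to_cpdag <- function(A) {
  N <- ncol(A)
  if (.has_cycle(A)) stop("input graph is not acyclic")
  # topological order
  ord <- integer(0)
  indeg <- colSums(A > 0)
  avail <- which(indeg == 0)
  Aw <- A
  while (length(avail)) {
    v <- avail[1]; avail <- avail[-1]
    ord <- c(ord, v)
    out <- which(Aw[v, ] > 0)
    Aw[v, ] <- 0
    indeg[out] <- indeg[out] - 1
    avail <- c(avail, out[indeg[out] == 0])
  }
  pos <- integer(N); pos[ord] <- seq_len(N)
  # order edges: by destination order ascending, source order descending
  ed <- which(A > 0, arr.ind = TRUE)
  lab <- matrix(0L, N, N)   # 0 unknown, 1 compelled, -1 reversible
  if (nrow(ed)) {
    o <- order(pos[ed[, 2]], -pos[ed[, 1]])
    ed <- ed[o, , drop = FALSE]
  }
  edge_lab <- rep(0L, nrow(ed))
  lab_of <- function(i, j) lab[i, j]
  set_lab <- function(i, j, v) lab[i, j] <<- v
  while (any(edge_lab == 0L)) {
    e <- which(edge_lab == 0L)[1]
    x <- ed[e, 1]; y <- ed[e, 2]
    done <- FALSE
    ws <- which(A[, x] > 0 & lab[, x] == 1L)
    for (w in ws) {
      if (A[w, y] == 0) {
        into_y <- which(A[, y] > 0)
        lab[into_y, y] <- 1L
        done <- TRUE
        break
      } else {
        lab[w, y] <- 1L
      }
    }
    if (!done) {
      zs <- which(A[, y] > 0)
      zs <- zs[zs != x & A[zs, x] == 0]
      into_y_unknown <- which(A[, y] > 0 & lab[, y] == 0L)
      if (length(zs)) {
        lab[x, y] <- 1L
        lab[into_y_unknown, y] <- 1L
      } else {
        lab[x, y] <- -1L
        lab[into_y_unknown, y] <- -1L
      }
    }
    for (k in seq_len(nrow(ed)))
      edge_lab[k] <- lab[ed[k, 1], ed[k, 2]]
  }
  C <- matrix(0L, N, N, dimnames = dimnames(A))
  if (nrow(ed)) for (k in seq_len(nrow(ed))) {
    i <- ed[k, 1]; j <- ed[k, 2]
    if (edge_lab[k] == 1L) C[i, j] <- 1L else { C[i, j] <- 2L; C[j, i] <- 2L }
  }
  class(C) <- c("bn_cpdag", class(C))
  C
}

.cpdag_key <- function(C) paste(as.integer(C), collapse = "")

#' Deduplicate a list of CPDAGs
#'
#' Exact-equality deduplication preserving the order of first appearance.
#' Idempotent.
#'
#' @param cpdags list of CPDAG matrices.
#' @return list of unique CPDAGs.
#' @export
dedup_cpdags <- function(cpdags) {
  keys <- vapply(cpdags, .cpdag_key, character(1))
  cpdags[!duplicated(keys)]
}

#' Edge weights as empirical frequencies over a pooled CPDAG sample
#'
#' For each ordered pair (i, j), the fraction of CPDAGs containing i -> j
#' compelled or i - j undirected; an undirected edge contributes to both
#' ordered pairs, so that reversible evidence is never discarded.
#'
#' @param cpdags non-empty list of CPDAG matrices (typically both chains'
#'   deduplicated post-burn-in samples pooled).
#' @return numeric matrix of weights in `[0, 1]` with attribute `n_samples`.
#' @export
edge_weights <- function(cpdags) {
  if (!length(cpdags)) stop("empty CPDAG sample")
  N <- ncol(cpdags[[1]])
  W <- matrix(0, N, N, dimnames = dimnames(cpdags[[1]]))
  for (C in cpdags) W <- W + (unclass(C) > 0)
  W <- W / length(cpdags)
  attr(W, "n_samples") <- length(cpdags)
  W
}

#' Threshold edge weights at a quantile of the positive weights
#'
#' An edge is reported when its weight is at least the `q` quantile
#' (type-7, linear interpolation) of all positive weights.
#'
#' @param W edge-weight matrix from [edge_weights()].
#' @param q quantile in `[0, 1]` (default 0.75).
#' @return data.frame of reported edges (`from`, `to`, `weight`) plus the
#'   threshold as attribute `threshold`.
#' @export
threshold_edges <- function(W, q = 0.75) {
  pos <- W[W > 0]
  if (!length(pos)) {
    out <- data.frame(from = character(), to = character(), weight = numeric())
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  thr <- stats::quantile(pos, q, names = FALSE, type = 7)
  idx <- which(W >= thr & W > 0, arr.ind = TRUE)
  out <- data.frame(from = rownames(W)[idx[, 1]], to = colnames(W)[idx[, 2]],
                    weight = W[idx])
  out <- out[order(-out$weight, out$from, out$to), ]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Export the inferred network to TSV, SIF and GraphML
#'
#' Writes `edge_weights.tsv` (source, target, weight, kept flag),
#' `network.sif` (interaction labelled by the node-type pair, e.g. `GE-GE`)
#' and `network.graphml` with `nodeType` and `gene` attributes.
#'
#' @param W edge-weight matrix.
#' @param kept data.frame of reported edges from [threshold_edges()].
#' @param nodes node table (`id`, `type`, `gene`).
#' @param dir output directory.
#' @return Invisibly, the written file paths.
#' @export
export_network <- function(W, kept, nodes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- which(W > 0, arr.ind = TRUE)
  tsv <- data.frame(source = rownames(W)[idx[, 1]], target = colnames(W)[idx[, 2]],
                    weight = W[idx])
  key <- paste(tsv$source, tsv$target)
  tsv$kept <- key %in% paste(kept$from, kept$to)
  tsv <- tsv[order(-tsv$weight, tsv$source, tsv$target), ]
  p1 <- file.path(dir, "edge_weights.tsv")
  utils::write.table(tsv, p1, sep = "\t", quote = FALSE, row.names = FALSE)

  ty <- stats::setNames(nodes$type, nodes$id)
  p2 <- file.path(dir, "network.sif")
  if (nrow(kept)) {
    sif <- data.frame(source = kept$from,
                      interaction = paste0(ty[kept$from], "-", ty[kept$to]),
                      target = kept$to)
    utils::write.table(sif, p2, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    file.create(p2)
  }

  g <- igraph::graph_from_data_frame(
    if (nrow(kept)) kept[, c("from", "to", "weight")] else
      data.frame(from = character(), to = character(), weight = numeric()),
    directed = TRUE, vertices = nodes$id)
  igraph::V(g)$nodeType <- as.character(ty[igraph::V(g)$name])
  igraph::V(g)$gene <- as.character(stats::setNames(nodes$gene, nodes$id)[igraph::V(g)$name])
  p3 <- file.path(dir, "network.graphml")
  igraph::write_graph(g, p3, format = "graphml")
  invisible(c(p1, p2, p3))
}
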