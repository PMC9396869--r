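.pair_key <- function(from, to) paste(from, to, sep = "\r")

# extract the weight of each universe pair from a weight matrix (0 if absent)
.universe_weights <- function(W, universe) {
  w <- numeric(nrow(universe))
  for (k in seq_len(nrow(universe))) {
    i <- match(universe$from[k], rownames(W))
    j <- match(universe$to[k], colnames(W))
    w[k] <- if (is.na(i) || is.na(j)) 0 else W[i, j]
  }
  w
}

#' ROC curve and AUC of edge weights against a gold standard
#'
#' Sweeps thresholds over the distinct weights of the evaluable pair
#' universe; the AUC uses the rank (Mann-Whitney) formulation, so ties are
#' handled by mid-ranks and a weight vector carrying no information gives
#' AUC 0.5.
#'
#' @param W edge-weight matrix (or a named numeric vector keyed
#'   `from\rto`).
#' @param gold data.frame (`from`, `to`) of reference edges.
#' @param universe data.frame (`from`, `to`) of evaluable ordered pairs;
#'   `gold` must be a subset.
#' @return list with `roc` (data.frame `threshold`, `tpr`, `fpr`), `auc`,
#'   `n_pos`, `n_neg`.
#' @export
roc_auc <- function(W, gold, universe) {
  if (!nrow(universe)) stop("empty pair universe")
  gk <- .pair_key(gold$from, gold$to)
  uk <- .pair_key(universe$from, universe$to)
  if (!all(gk %in% uk)) stop("gold edges must lie inside the universe")
  lab <- uk %in% gk
  w <- if (is.matrix(W)) .universe_weights(W, universe) else unname(W[uk])
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (n_pos == 0 || n_neg == 0) stop("need at least one positive and one negative pair")
  r <- rank(w)
  auc <- (sum(r[lab]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(w), decreasing = TRUE)
  roc <- data.frame(
    threshold = c(Inf, thr),
    tpr = c(0, vapply(thr, function(t) mean(w[lab] >= t), numeric(1))),
    fpr = c(0, vapply(thr, function(t) mean(w[!lab] >= t), numeric(1))))
  list(roc = roc, auc = auc, n_pos = n_pos, n_neg = n_neg)
}

#' 83 percent confidence interval for an AUC
#'
#' Normal approximation with the Hanley-McNeil variance; two AUCs are judged
#' different when their 83% intervals are disjoint (the interval level that
#' calibrates a pairwise overlap test to roughly the 5% level).
#'
#' @param auc the observed AUC.
#' @param n_pos,n_neg numbers of positive and negative pairs.
#' @param level confidence level (default 0.83).
#' @return numeric vector `c(low, high)`, truncated to `[0, 1]`.
#' @export
auc_ci83 <- function(auc, n_pos, n_neg, level = 0.83) {
  stopifnot(n_pos >= 1, n_neg >= 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- auc + c(-1, 1) * z * sqrt(max(v, 0))
  pmin(pmax(ci, 0), 1)
}

#' Bootstrap 83 percent confidence interval for an AUC
#'
#' Nonparametric alternative to [auc_ci83()]: resamples the universe pairs
#' with replacement and takes percentile limits of the recomputed AUCs.
#'
#' @inheritParams roc_auc
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param level confidence level (default 0.83).
#' @return numeric vector `c(low, high)`.
#' @export
auc_ci_boot <- function(W, gold, universe, n_boot = 1000L, level = 0.83) {
  gk <- .pair_key(gold$from, gold$to)
  uk <- .pair_key(universe$from, universe$to)
  lab <- uk %in% gk
  w <- if (is.matrix(W)) .universe_weights(W, universe) else unname(W[uk])
  aucs <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(length(w), replace = TRUE)
    lb <- lab[idx]
    if (!any(lb) || all(lb)) { aucs[b] <- NA; next }
    r <- rank(w[idx])
    aucs[b] <- (sum(r[lb]) - sum(lb) * (sum(lb) + 1) / 2) / (sum(lb) * sum(!lb))
  }
  stats::quantile(aucs, c((1 - level) / 2, 1 - (1 - level) / 2),
                  na.rm = TRUE, names = FALSE)
}

#' Cohen's kappa agreement between two edge sets
#'
#' Chance-corrected agreement of the binary presence/absence labels that two
#' methods assign to every ordered pair of the universe:
#' `kappa = (p_o - p_e) / (1 - p_e)`.
#'
#' @param edgesA,edgesB data.frames (`from`, `to`), subsets of the universe.
#' @param universe data.frame of evaluable ordered pairs.
#' @return kappa in `[-1, 1]` (1 for identical sets).
#' @export
cohens_kappa <- function(edgesA, edgesB, universe) {
  uk <- .pair_key(universe$from, universe$to)
  a <- uk %in% .pair_key(edgesA$from, edgesA$to)
  b <- uk %in% .pair_key(edgesB$from, edgesB$to)
  n <- length(uk)
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}
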