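#' Infer a regulatory network from a multi-omics dataset
#'
#' End-to-end convenience wrapper: assembles the typed network problem,
#' runs the adaptive MCMC pipeline ([run_network_mcmc()]), pools the two
#' chains' deduplicated post-burn-in CPDAG samples into edge weights, and
#' thresholds them at the `edge_quantile` quantile of the positive weights.
#'
#' @param ds an [omics_dataset()].
#' @param prior prior-knowledge edges (data.frame or file path), or `NULL`.
#' @param config a [bn_config()].
#' @param seed integer seed.
#' @param edge_quantile reporting threshold quantile (default 0.75).
#' @param ... passed to [assemble_network_problem()].
#' @return list of class `bn_fit`: `weights` (edge-weight matrix), `edges`
#'   (reported edges), `mcmc` (the full [run_network_mcmc()] result),
#'   `problem`.
#' @export
infer_network <- function(ds, prior = NULL, config = bn_config(), seed = 1L,
                          edge_quantile = 0.75, ...) {
  pm <- assemble_network_problem(ds, prior = prior, ...)
  fit <- run_network_mcmc(pm, config, seed)
  pooled <- unlist(lapply(fit$chains, function(ch)
    dedup_cpdags(ch$cpdags[!ch$burnin])), recursive = FALSE)
  W <- edge_weights(pooled)
  kept <- threshold_edges(W, edge_quantile)
  structure(list(weights = W, edges = kept, mcmc = fit, problem = pm),
            class = "bn_fit")
}

#' @export
print.bn_fit <- function(x, ...) {
  cat(sprintf("bn_fit: %d nodes, %d reported edges (threshold %.3f), beta = %.3f\n",
              x$problem$N, nrow(x$edges), attr(x$edges, "threshold"),
              x$mcmc$beta))
  invisible(x)
}
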