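#' Configuration for the adaptive MCMC simulation
#'
#' Defaults follow the method's standard operating settings: 200,000 sampling
#' iterations per chain with a 100,000-iteration burn-in and thinning of 500,
#' a greedy horizon of three 500-iteration paths, a Markov-blanket-resampling
#' probability of 1/15, prior-strength support `beta >= 0.5` with initial
#' `beta ~ U[0, 10]` (clamped up to 0.5) and initial proposal s.d. 5.
#'
#' @param adapt1_iters iterations of the rough sigma-tuning phase.
#' @param adapt2_iters iterations of the fine-tuning / empirical-knowledge
#'   phase.
#' @param beta_batch beta proposals per sigma-adaptation batch.
#' @param transient_window window length (iterations) for the stationarity
#'   check of the transient phase.
#' @param transient_max maximum transient iterations before proceeding with a
#'   warning.
#' @param sampling_iters sampling iterations per chain.
#' @param burn_in iterations flagged as burn-in per chain.
#' @param thin keep every `thin`-th structure.
#' @param horizon greedy-horizon segment length.
#' @param n_paths independent paths per horizon (the highest-posterior
#'   endpoint is kept).
#' @param p_mbr per-iteration probability of a Markov-blanket-resampling move.
#' @param beta_min lower support bound of the prior strength.
#' @param beta_max upper support bound of the prior strength. The
#'   conditional of beta given the structure is flat whenever the structure
#'   attains the per-node minimum energy (always the case under a
#'   no-knowledge prior), so an unbounded support lets beta random-walk to
#'   arbitrarily large values and freeze the sampling phase; the support is
#'   therefore truncated at the same upper bound the initial draw uses.
#' @param beta_init_max upper bound of the uniform beta initialisation.
#' @param sigma_init initial beta-proposal standard deviation.
#' @param accept_band target acceptance band for the beta proposals.
#' @param extension_block sampling iterations added per chain when the
#'   convergence check fails.
#' @param max_extensions maximum number of extension blocks.
#' @return list of class `bn_config`.
#' @export
bn_config <- function(adapt1_iters = 2000L, adapt2_iters = 10000L,
                      beta_batch = 100L, transient_window = 500L,
                      transient_max = 20000L,
                      sampling_iters = 200000L, burn_in = 100000L,
                      thin = 500L, horizon = 500L, n_paths = 3L,
                      p_mbr = 1 / 15, beta_min = 0.5, beta_max = 10,
                      beta_init_max = 10,
                      sigma_init = 5, accept_band = c(0.28, 0.60),
                      extension_block = 50000L, max_extensions = 3L) {
  structure(as.list(environment()), class = "bn_config")
}

# -- chain state --------------------------------------------------------------

.new_state <- function(pm, sc, A = NULL, beta = NULL, sigma = 5, B = pm$B,
                       cfg = bn_config()) {
  st <- new.env(parent = emptyenv())
  st$A <- if (is.null(A)) empty_graph(pm) else A
  st$beta <- if (is.null(beta))
    min(cfg$beta_max, max(cfg$beta_min, stats::runif(1, 0, cfg$beta_init_max)))
  else beta
  st$sigma <- sigma
  st$B <- B
  st$logscore <- bge_graph_score(sc, st$A)
  st$E <- graph_energy(pm, st$A, B)
  st$logZ <- log_partition_upper(pm, st$beta, B)
  st$iter <- 0L
  st$nb <- NULL
  st
}

.state_logpost <- function(st) st$logscore - st$beta * st$E - st$logZ

.clone_state <- function(st) {
  s2 <- new.env(parent = emptyenv())
  for (nm in ls(st)) assign(nm, get(nm, st), s2)
  s2
}

# one structure move (single edge or MBR); updates state in place.
# Returns the move record with an `accepted` flag.
.structure_step <- function(st, pm, sc, cfg, counts = NULL) {
  if (stats::runif(1) < cfg$p_mbr) {
    prop <- mbr_propose(pm, sc, st$A)
    if (!length(prop$move$targets)) return(invisible(prop$move))
    new_score <- st$logscore
    dE <- 0
    for (t in seq_along(prop$move$targets)) {
      nd <- prop$move$targets[t]
      oldp <- prop$move$old_sets[[t]]; newp <- prop$move$new_sets[[t]]
      new_score <- new_score + bge_node_score(sc, nd, newp) -
        bge_node_score(sc, nd, oldp)
      b <- st$B[, nd]
      dE <- dE + sum(1 - 2 * b[newp]) - sum(1 - 2 * b[oldp])
    }
    acc <- accept_structure(new_score - st$logscore, -st$beta * dE,
                            prop$log_q_ratio)
    if (acc) {
      st$A <- prop$A; st$logscore <- new_score; st$E <- st$E + dE
      st$nb <- NULL
    }
    prop$move$accepted <- acc
    return(invisible(prop$move))
  }
  if (is.null(st$nb)) st$nb <- enumerate_neighborhood(pm, st$A)
  prop <- propose_single_edge(pm, st$A, nb = st$nb)
  mv <- prop$move
  ds <- bge_delta(sc, st$A, mv)
  i <- mv$i; j <- mv$j
  dE <- switch(mv$kind,
               add = 1 - 2 * st$B[i, j],
               delete = -(1 - 2 * st$B[i, j]),
               reverse = -(1 - 2 * st$B[i, j]) + (1 - 2 * st$B[j, i]))
  acc <- accept_structure(ds, -st$beta * dE, prop$log_q_ratio)
  if (acc) {
    st$A <- prop$A; st$logscore <- st$logscore + ds; st$E <- st$E + dE
    st$nb <- NULL
  }
  mv$accepted <- acc
  if (!is.null(counts)) update_counts(counts, mv, acc)
  invisible(mv)
}

#' Propose a candidate prior strength
#'
#' Gaussian perturbation `beta_c ~ N(beta_s, sigma^2)`. Candidates below
#' `beta_min` are invalid (the chain support is truncated at `beta_min`) and
#' are rejected outright by the caller without evaluating the prior ratio.
#'
#' @param beta_s current value.
#' @param sigma proposal standard deviation.
#' @return candidate value (may lie below `beta_min`).
#' @export
propose_beta <- function(beta_s, sigma) stats::rnorm(1, beta_s, sigma)

# one beta move; returns TRUE if accepted
.beta_step <- function(st, pm, cfg) {
  bc <- propose_beta(st$beta, st$sigma)
  if (bc < cfg$beta_min || bc > cfg$beta_max) return(FALSE)
  logZ_c <- log_partition_upper(pm, bc, st$B)
  la <- -(bc - st$beta) * st$E - (logZ_c - st$logZ)
  if (la >= 0 || log(stats::runif(1)) < la) {
    st$beta <- bc; st$logZ <- logZ_c
    return(TRUE)
  }
  FALSE
}

#' Table-style bookkeeping of proposal and acceptance counts
#'
#' Updates per-ordered-pair proposal frequencies `f` and acceptance-evidence
#' counts `a` after a single-edge move (Markov-blanket moves are not
#' counted). The accounting encodes evidence *for the edge being present*:
#' an accepted addition and a rejected deletion both support i -> j; a
#' reversal is treated as deleting i -> j and adding j -> i, so it increments
#' `f_ij` and `f_ji`, with `a_ji` on acceptance and `a_ij` on rejection.
#'
#' @param counts environment with numeric matrices `f` and `a`.
#' @param move single-edge move (list with `kind`, `i`, `j`).
#' @param accepted logical.
#' @return the counts environment, invisibly (updated in place).
#' @export
update_counts <- function(counts, move, accepted) {
  i <- move$i; j <- move$j
  switch(move$kind,
    add = {
      counts$f[i, j] <- counts$f[i, j] + 1
      if (accepted) counts$a[i, j] <- counts$a[i, j] + 1
    },
    delete = {
      counts$f[i, j] <- counts$f[i, j] + 1
      if (!accepted) counts$a[i, j] <- counts$a[i, j] + 1
    },
    reverse = {
      counts$f[i, j] <- counts$f[i, j] + 1
      counts$f[j, i] <- counts$f[j, i] + 1
      if (accepted) counts$a[j, i] <- counts$a[j, i] + 1
      else counts$a[i, j] <- counts$a[i, j] + 1
    },
    stop("update_counts expects a single-edge move"))
  invisible(counts)
}

#' Create an empty proposal/acceptance count accumulator
#'
#' @param pm a `bn_problem`.
#' @return environment with zero matrices `f` and `a`.
#' @export
new_counts <- function(pm) {
  cn <- new.env(parent = emptyenv())
  cn$f <- matrix(0, pm$N, pm$N, dimnames = dimnames(pm$adm))
  cn$a <- matrix(0, pm$N, pm$N, dimnames = dimnames(pm$adm))
  cn
}

#' Empirical knowledge matrix from accumulated counts
#'
#' `Bhat_ij = a_ij / f_ij` for admissible pairs proposed at least once;
#' never-proposed pairs keep the no-knowledge value 0.5.
#'
#' @param counts a [new_counts()] accumulator after [update_counts()] calls.
#' @param pm a `bn_problem`.
#' @return numeric matrix over admissible pairs (`NA` off-support).
#' @export
empirical_knowledge <- function(counts, pm) {
  Bh <- matrix(NA_real_, pm$N, pm$N, dimnames = dimnames(pm$adm))
  Bh[pm$adm] <- 0.5
  seen <- pm$adm & counts$f > 0
  Bh[seen] <- counts$a[seen] / counts$f[seen]
  Bh
}

#' Merge empirical knowledge into the prior-knowledge matrix
#'
#' Entries whose provenance is "unknown" (B = 0.5 with no database or
#' transcription-factor evidence) are replaced by the empirical estimate;
#' database, TF-target, forbidden and user-specified entries are kept
#' verbatim.
#'
#' @param pm a `bn_problem`.
#' @param B_hat matrix from [empirical_knowledge()].
#' @return merged prior matrix.
#' @export
merge_prior <- function(pm, B_hat) {
  B <- pm$B
  repl <- pm$adm & pm$prov == "unknown" & !is.na(B_hat)
  B[repl] <- B_hat[repl]
  B
}

#' Stationarity check on a log-posterior trace
#'
#' Geweke-style diagnostic: standardised difference of means between the two
#' most recent non-overlapping windows; the chain is considered past its
#' transient when `|z| < 1.96`. A constant trace passes.
#'
#' @param trace numeric vector of log-posterior values.
#' @param window window length; the last `2 * window` values are used.
#' @return logical.
#' @export
transient_check <- function(trace, window) {
  if (length(trace) < 2 * window) return(FALSE)
  x1 <- trace[seq(length(trace) - 2 * window + 1, length(trace) - window)]
  x2 <- trace[seq(length(trace) - window + 1, length(trace))]
  d <- mean(x2) - mean(x1)
  if (d == 0) return(TRUE)
  se <- sqrt(stats::var(x1) / window + stats::var(x2) / window)
  if (se == 0) return(FALSE)
  abs(d / se) < 1.96
}

# -- phases -------------------------------------------------------------------

# rough (phase 1) or fine (phase 2) sigma tuning step size
.tune_sigma <- function(st, acc_rate, cfg, delta) {
  if (acc_rate < cfg$accept_band[1]) st$sigma <- st$sigma * exp(-delta)
  else if (acc_rate > cfg$accept_band[2]) st$sigma <- st$sigma * exp(delta)
  invisible(st)
}

.run_adaptive <- function(st, pm, sc, cfg, n_iter, delta, counts = NULL,
                          collect_beta = FALSE) {
  betas <- if (collect_beta) numeric(n_iter) else NULL
  acc_in_batch <- 0L; batch_n <- 0L
  last_rate <- NA_real_
  in_band <- FALSE
  for (it in seq_len(n_iter)) {
    .structure_step(st, pm, sc, cfg, counts)
    acc_in_batch <- acc_in_batch + .beta_step(st, pm, cfg)
    batch_n <- batch_n + 1L
    if (batch_n == cfg$beta_batch) {
      last_rate <- acc_in_batch / batch_n
      in_band <- last_rate >= cfg$accept_band[1] && last_rate <= cfg$accept_band[2]
      .tune_sigma(st, last_rate, cfg, delta)
      acc_in_batch <- 0L; batch_n <- 0L
    }
    if (collect_beta) betas[it] <- st$beta
  }
  list(betas = betas, last_rate = last_rate, in_band = in_band)
}

#' Rough adaptation phase: tune the beta-proposal variance
#'
#' Interleaves structure moves with prior-strength moves and rescales the
#' proposal s.d. by `exp(+/- 0.5)` after every batch until the acceptance
#' rate enters the target band. Warns (and proceeds) if the band is not
#' reached within the configured iterations.
#'
#' @param st chain state (modified in place).
#' @param pm a `bn_problem`.
#' @param sc a [bge_scorer()].
#' @param cfg a [bn_config()].
#' @return list with the final batch acceptance rate and band membership.
#' @export
phase1_adapt <- function(st, pm, sc, cfg) {
  res <- .run_adaptive(st, pm, sc, cfg, cfg$adapt1_iters, delta = 0.5)
  if (!isTRUE(res$in_band))
    warning("beta acceptance rate did not reach the target band during phase 1")
  res
}

#' Transient phase: run until the log-posterior trace stabilises
#'
#' Advances the chain in windows and applies [transient_check()] after each;
#' returns once the chain appears to have reached the mode of the target (or
#' warns when the iteration cap is hit first).
#'
#' @inheritParams phase1_adapt
#' @return the accumulated log-posterior trace.
#' @export
phase_transient <- function(st, pm, sc, cfg) {
  trace <- numeric(0)
  repeat {
    for (it in seq_len(cfg$transient_window)) {
      .structure_step(st, pm, sc, cfg)
      .beta_step(st, pm, cfg)
      trace <- c(trace, .state_logpost(st))
    }
    if (transient_check(trace, cfg$transient_window)) break
    if (length(trace) >= cfg$transient_max) {
      warning("transient phase hit its iteration cap before stabilising")
      break
    }
  }
  trace
}

#' Fine adaptation phase: sigma fine-tuning and empirical-knowledge counts
#'
#' Continues the adaptive schedule with smaller (`exp(+/- 0.1)`) sigma
#' steps, updates the per-pair proposal/acceptance counts after every
#' single-edge proposal, and on exit reports the empirical knowledge matrix
#' `a/f` together with the phase-mean beta estimate.
#'
#' @inheritParams phase1_adapt
#' @return list with `counts`, `B_hat`, `beta_hat`, the beta trace and the
#'   final beta acceptance rate.
#' @export
phase2_estimate <- function(st, pm, sc, cfg) {
  counts <- new_counts(pm)
  res <- .run_adaptive(st, pm, sc, cfg, cfg$adapt2_iters, delta = 0.1,
                       counts = counts, collect_beta = TRUE)
  list(counts = counts, B_hat = empirical_knowledge(counts, pm),
       beta_hat = mean(res$betas), betas = res$betas,
       beta_acc_rate = res$last_rate)
}

# -- sampling phase -----------------------------------------------------------

#' Sample structures at fixed prior strength (greedy-horizon kernel)
#'
#' The sampling-phase kernel: the prior strength is held fixed; from the
#' current state, `n_paths` independent `horizon`-iteration paths of the full
#' Metropolis-Hastings kernel (single-edge moves plus Markov-blanket
#' resampling with probability `p_mbr`) are spawned and the endpoint with the
#' highest log posterior is kept. Structures are recorded every `thin`
#' iterations along the kept path. With `n_paths = 1` this reduces to plain
#' structure MCMC.
#'
#' @param pm a `bn_problem`.
#' @param sc a [bge_scorer()].
#' @param st chain state (modified in place).
#' @param cfg a [bn_config()].
#' @param n_iter total sampling iterations.
#' @param iter_offset global iteration count already performed (for thinning
#'   alignment when extending a chain).
#' @return list with `dags` (thinned adjacency snapshots), `iters`
#'   (iteration indices), `logpost` trace at snapshots.
#' @export
sample_structures <- function(pm, sc, st, cfg, n_iter, iter_offset = 0L) {
  dags <- list(); iters <- integer(0); lps <- numeric(0)
  done <- 0L
  while (done < n_iter) {
    seg <- min(cfg$horizon, n_iter - done)
    best <- NULL
    for (p in seq_len(cfg$n_paths)) {
      stp <- .clone_state(st)
      rec_d <- list(); rec_i <- integer(0); rec_l <- numeric(0)
      for (it in seq_len(seg)) {
        .structure_step(stp, pm, sc, cfg)
        gi <- iter_offset + done + it
        if (gi %% cfg$thin == 0L) {
          rec_d[[length(rec_d) + 1L]] <- stp$A
          rec_i <- c(rec_i, gi)
          rec_l <- c(rec_l, .state_logpost(stp))
        }
      }
      lp <- .state_logpost(stp)
      if (is.null(best) || lp > best$lp)
        best <- list(st = stp, lp = lp, d = rec_d, i = rec_i, l = rec_l)
      if (cfg$n_paths == 1L) break
    }
    st$A <- best$st$A; st$logscore <- best$st$logscore; st$E <- best$st$E
    st$nb <- best$st$nb
    dags <- c(dags, best$d); iters <- c(iters, best$i); lps <- c(lps, best$l)
    done <- done + seg
  }
  list(dags = dags, iters = iters, logpost = lps)
}

# -- convergence --------------------------------------------------------------

#' Between-chain cumulative RMS discrepancy of edge frequencies
#'
#' At each thinned index k, the root-mean-square difference, over all
#' admissible ordered pairs, between the two chains' running relative edge
#' frequencies computed from their first k post-burn-in CPDAG snapshots
#' (an undirected CPDAG edge counts towards both ordered pairs).
#'
#' @param cpdagsA,cpdagsB lists of CPDAG matrices (post-burn-in, thinned,
#'   not deduplicated), one per chain.
#' @param adm logical admissibility matrix defining the pair universe.
#' @return numeric vector of length `min(length(cpdagsA), length(cpdagsB))`.
#' @export
c_rms_series <- function(cpdagsA, cpdagsB, adm) {
  K <- min(length(cpdagsA), length(cpdagsB))
  if (K == 0L) return(numeric(0))
  SA <- matrix(0, nrow(adm), ncol(adm)); SB <- SA
  out <- numeric(K)
  for (k in seq_len(K)) {
    SA <- SA + (unclass(cpdagsA[[k]]) > 0)
    SB <- SB + (unclass(cpdagsB[[k]]) > 0)
    d <- (SA - SB)[adm] / k
    out[k] <- sqrt(mean(d^2))
  }
  out
}

#' Convergence stopping rule on a c_rms series
#'
#' The threshold is the third quartile of the successive absolute differences
#' `|c_rms_k - c_rms_(k-1)|`; the simulation may stop when each of the last
#' 100 thinned values lies strictly below the threshold. A constant series
#' has threshold 0 and therefore never satisfies the strict inequality
#' (degenerate case; callers should treat identical chains separately).
#'
#' @param crms numeric vector from [c_rms_series()] (length >= 101).
#' @param last number of trailing values that must be below threshold
#'   (default 100).
#' @return logical.
#' @export
convergence_stop <- function(crms, last = 100L) {
  if (length(crms) < last + 1L) return(FALSE)
  thr <- stats::quantile(abs(diff(crms)), 0.75, names = FALSE, type = 7)
  all(utils::tail(crms, last) < thr)
}

# -- full pipeline ------------------------------------------------------------

#' Run the full adaptive MCMC network-inference pipeline
#'
#' Executes the four phases once on one adaptive chain -- rough
#' proposal-variance tuning, transient detection, fine tuning with
#' empirical-knowledge accumulation -- merges the empirical knowledge into
#' the prior, then runs two independent greedy-horizon sampling chains at the
#' estimated fixed prior strength. Chains are extended in blocks until the
#' c_rms stopping rule is met or `max_extensions` is reached.
#'
#' @param pm a `bn_problem` from [assemble_network_problem()].
#' @param cfg a [bn_config()].
#' @param seed integer seed controlling all randomness.
#' @return list of class `bn_mcmc` with the two chain traces (thinned DAG and
#'   CPDAG snapshots with burn-in flags), merged prior, estimated beta, the
#'   c_rms series, and a provenance log.
#' @export
run_network_mcmc <- function(pm, cfg = bn_config(), seed = 1L) {
  set.seed(seed)
  sc <- bge_scorer(pm$data, standardize = FALSE)
  st <- .new_state(pm, sc, cfg = cfg)
  beta_init <- st$beta
  p1 <- phase1_adapt(st, pm, sc, cfg)
  tr <- phase_transient(st, pm, sc, cfg)
  p2 <- phase2_estimate(st, pm, sc, cfg)
  B_merged <- merge_prior(pm, p2$B_hat)
  beta_hat <- max(cfg$beta_min, p2$beta_hat)

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    stc <- .new_state(pm, sc, A = st$A, beta = beta_hat, sigma = st$sigma,
                      B = B_merged, cfg = cfg)
    res <- sample_structures(pm, sc, stc, cfg, cfg$sampling_iters)
    list(state = stc, dags = res$dags, iters = res$iters, logpost = res$logpost)
  }
  chains <- list(run_chain(seed + 1L), run_chain(seed + 2L))
  extensions <- 0L
  crms <- numeric(0)
  repeat {
    cpd <- lapply(chains, function(ch) {
      post <- ch$iters > cfg$burn_in
      lapply(ch$dags[post], dag_to_cpdag)
    })
    crms <- c_rms_series(cpd[[1]], cpd[[2]], pm$adm)
    if (convergence_stop(crms) || extensions >= cfg$max_extensions) break
    extensions <- extensions + 1L
    for (k in 1:2) {
      set.seed(seed + 2L + extensions * 2L + k)
      off <- max(chains[[k]]$iters)
      res <- sample_structures(pm, sc, chains[[k]]$state, cfg,
                               cfg$extension_block, iter_offset = off)
      chains[[k]]$dags <- c(chains[[k]]$dags, res$dags)
      chains[[k]]$iters <- c(chains[[k]]$iters, res$iters)
      chains[[k]]$logpost <- c(chains[[k]]$logpost, res$logpost)
    }
  }
  traces <- lapply(chains, function(ch) {
    post <- ch$iters > cfg$burn_in
    list(dags = ch$dags, iters = ch$iters, logpost = ch$logpost,
         burnin = !post, cpdags = lapply(ch$dags, dag_to_cpdag))
  })
  structure(list(
    chains = traces, B_merged = B_merged, B_hat = p2$B_hat,
    counts = list(f = p2$counts$f, a = p2$counts$a),
    beta = beta_hat, crms = crms,
    log = list(seed = seed, beta_init = beta_init, beta_final = beta_hat,
               sigma_final = st$sigma, beta_acc_rate = p2$beta_acc_rate,
               transient_iters = length(tr), extensions = extensions,
               phase_iters = c(adapt1 = cfg$adapt1_iters,
                               adapt2 = cfg$adapt2_iters,
                               sampling = cfg$sampling_iters))),
    class = "bn_mcmc")
}

#' @export
print.bn_mcmc <- function(x, ...) {
  cat(sprintf("bn_mcmc: 2 chains, %d + %d thinned snapshots, beta = %.3f, final c_rms = %s\n",
              length(x$chains[[1]]$dags), length(x$chains[[2]]$dags), x$beta,
              if (length(x$crms)) sprintf("%.4f", utils::tail(x$crms, 1)) else "NA"))
  invisible(x)
}
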