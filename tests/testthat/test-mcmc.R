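test_that("beta proposals are Gaussian and the support is truncated", {
  set.seed(601)
  draws <- replicate(10000, propose_beta(2, 0.7))
  expect_lt(abs(mean(draws) - 2), 3 * 0.7 / sqrt(10000))
  expect_lt(abs(sd(draws) - 0.7), 3 * 0.7 / sqrt(2 * 10000))

  # a candidate below beta_min is rejected without touching the state
  pm <- make_ge_problem(matrix(rnorm(36), 12, 3))
  sc <- bge_scorer(pm$data, standardize = FALSE)
  cfg <- bn_config()
  st <- bnomics:::.new_state(pm, sc, beta = 0.5, sigma = 5, cfg = cfg)
  set.seed(2)   # first rnorm(1, 0.5, 5) draw is negative under this seed
  stopifnot(rnorm(1, 0.5, 5) < cfg$beta_min)
  set.seed(2)
  expect_false(bnomics:::.beta_step(st, pm, cfg))
  expect_equal(st$beta, 0.5)
})

test_that("proposal/acceptance bookkeeping matches the counting table", {
  pm <- make_ge_problem(matrix(rnorm(36), 12, 3))
  cases <- list(
    list(kind = "add", acc = TRUE,  df_ij = 1, da_ij = 1, df_ji = 0, da_ji = 0),
    list(kind = "add", acc = FALSE, df_ij = 1, da_ij = 0, df_ji = 0, da_ji = 0),
    list(kind = "delete", acc = TRUE,  df_ij = 1, da_ij = 0, df_ji = 0, da_ji = 0),
    list(kind = "delete", acc = FALSE, df_ij = 1, da_ij = 1, df_ji = 0, da_ji = 0),
    list(kind = "reverse", acc = TRUE,  df_ij = 1, da_ij = 0, df_ji = 1, da_ji = 1),
    list(kind = "reverse", acc = FALSE, df_ij = 1, da_ij = 1, df_ji = 1, da_ji = 0))
  for (cs in cases) {
    counts <- new_counts(pm)
    update_counts(counts, list(kind = cs$kind, i = 1L, j = 2L), cs$acc)
    expect_equal(counts$f[1, 2], cs$df_ij, label = cs$kind)
    expect_equal(counts$a[1, 2], cs$da_ij, label = cs$kind)
    expect_equal(counts$f[2, 1], cs$df_ji, label = cs$kind)
    expect_equal(counts$a[2, 1], cs$da_ji, label = cs$kind)
  }
  # acceptance evidence can never exceed proposal frequency
  set.seed(602)
  counts <- new_counts(pm)
  kinds <- c("add", "delete", "reverse")
  for (r in 1:500) {
    update_counts(counts, list(kind = sample(kinds, 1),
                               i = sample(3, 1), j = sample(3, 1)),
                  runif(1) < 0.5)
    expect_true(all(counts$a <= counts$f))
  }
})

test_that("empirical knowledge is the acceptance/frequency ratio", {
  pm <- make_ge_problem(matrix(rnorm(36), 12, 3))
  counts <- new_counts(pm)
  for (r in 1:4) update_counts(counts, list(kind = "add", i = 1L, j = 2L), r <= 3)
  Bh <- empirical_knowledge(counts, pm)
  expect_equal(Bh[1, 2], 0.75)     # a = 3, f = 4
  expect_equal(Bh[2, 1], 0.5)      # never proposed
  expect_true(is.na(Bh[1, 1]))     # inadmissible

  # merging: only unknown-provenance entries are replaced
  pm2 <- make_ge_problem(matrix(rnorm(36), 12, 3),
                         prior = data.frame(from = c("G01", "G02"),
                                            to = c("G02", "G03"),
                                            value = c(1, 0)))
  Bh2 <- matrix(NA_real_, 3, 3, dimnames = dimnames(pm2$adm))
  Bh2[pm2$adm] <- 0.8
  merged <- merge_prior(pm2, Bh2)
  expect_equal(merged[1, 2], 1)    # database edge kept
  expect_equal(merged[2, 3], 0)    # forbidden kept
  expect_equal(merged[3, 1], 0.8)  # unknown replaced
  # all-unknown prior: merged is the empirical matrix everywhere
  merged_u <- merge_prior(pm, Bh)
  expect_equal(merged_u[pm$adm], Bh[pm$adm])
})

test_that("transient diagnostics flag climbing traces and pass stationary ones", {
  expect_false(transient_check(seq_len(200), 100))        # still climbing
  expect_true(transient_check(rep(3.2, 200), 100))        # constant
  set.seed(603)
  hits <- mean(replicate(400, transient_check(rnorm(200), 100)))
  expect_gt(hits, 0.90)                                   # ~95% for iid noise
  expect_lt(hits, 0.99)
})

test_that("sigma adaptation steers toward the acceptance band", {
  cfg <- bn_config()
  st <- new.env(); st$sigma <- 2
  bnomics:::.tune_sigma(st, 0.1, cfg, 0.5)
  expect_lt(st$sigma, 2)                                  # below band: shrink
  st$sigma <- 2
  bnomics:::.tune_sigma(st, 0.9, cfg, 0.5)
  expect_gt(st$sigma, 2)                                  # above band: grow
  st$sigma <- 2
  bnomics:::.tune_sigma(st, 0.44, cfg, 0.5)
  expect_equal(st$sigma, 2)                               # in band: keep
})

test_that("phase 1 brings the beta acceptance rate into the band", {
  ok <- 0L
  for (s in 1:3) {
    set.seed(610 + s)
    mod <- random_typed_dag(5, edge_density = 0.4, n_cnv = 1, n_meth = 0)
    ds <- simulate_multiomics(mod, 60)
    pm <- assemble_network_problem(ds, prior = corrupt_prior(mod, 1))
    sc <- bge_scorer(pm$data, standardize = FALSE)
    cfg <- bn_config(adapt1_iters = 2000L)
    st <- bnomics:::.new_state(pm, sc, cfg = cfg)
    res <- suppressWarnings(phase1_adapt(st, pm, sc, cfg))
    ok <- ok + isTRUE(res$in_band)
  }
  expect_gte(ok, 2L)
})

test_that("c_rms measures the running between-chain edge-frequency gap", {
  A1 <- matrix(0, 3, 3); A1[1, 3] <- 1; A1[2, 3] <- 1
  A2 <- matrix(0, 3, 3)
  C1 <- dag_to_cpdag(A1); C0 <- dag_to_cpdag(A2)
  adm <- matrix(TRUE, 3, 3); diag(adm) <- FALSE
  # identical chains: all zeros
  expect_equal(c_rms_series(list(C1, C0, C1), list(C1, C0, C1), adm),
               rep(0, 3))
  # chains differing in 2 of 6 admissible frequencies by exactly 1 at k = 1
  s <- c_rms_series(list(C1), list(C0), adm)
  expect_equal(s, sqrt(2 / 6))
  # symmetry
  a <- list(C1, C1, C0, C1); b <- list(C0, C1, C1, C1)
  expect_equal(c_rms_series(a, b, adm), c_rms_series(b, a, adm))
})

test_that("the stopping rule needs a long quiet tail", {
  # plateau after decay: threshold from the noisy decay dominates the tail
  set.seed(604)
  decay <- exp(-seq(0, 5, length.out = 60)) + rnorm(60, 0, 0.01)
  plateau <- rep(0.005, 120)
  expect_true(convergence_stop(c(decay, plateau)))
  # large oscillation never settles
  osc <- rep(c(0.1, 0.9), 100)
  expect_false(convergence_stop(osc))
  # constant series: threshold 0, strict inequality fails by design
  expect_false(convergence_stop(rep(0.2, 200)))
  # too short
  expect_false(convergence_stop(rep(0.1, 50)))
})

test_that("thinning arithmetic yields the documented snapshot counts", {
  # sampling/thin snapshots per chain, (sampling - burn_in)/thin post burn-in
  set.seed(605)
  pm <- make_ge_problem(matrix(rnorm(45), 15, 3))
  sc <- bge_scorer(pm$data, standardize = FALSE)
  cfg <- bn_config(sampling_iters = 2000L, burn_in = 1000L, thin = 50L,
                   horizon = 100L, n_paths = 3L)
  st <- bnomics:::.new_state(pm, sc, beta = 1, cfg = cfg)
  res <- sample_structures(pm, sc, st, cfg, cfg$sampling_iters)
  expect_length(res$dags, 2000 / 50)
  expect_equal(sum(res$iters > cfg$burn_in), (2000 - 1000) / 50)
  expect_equal(res$iters, seq(50, 2000, by = 50))
})

test_that("identical seeds reproduce the full pipeline bit for bit", {
  set.seed(606)
  mod <- random_typed_dag(4, edge_density = 0.4, n_cnv = 1, n_meth = 0)
  ds <- simulate_multiomics(mod, 40)
  cfg <- bn_config(adapt1_iters = 200L, adapt2_iters = 400L,
                   transient_window = 100L, transient_max = 600L,
                   sampling_iters = 1000L, burn_in = 500L, thin = 100L,
                   horizon = 100L, n_paths = 2L, max_extensions = 0L)
  pm <- assemble_network_problem(ds)
  r1 <- suppressWarnings(run_network_mcmc(pm, cfg, seed = 9))
  r2 <- suppressWarnings(run_network_mcmc(pm, cfg, seed = 9))
  expect_identical(r1$chains[[1]]$dags, r2$chains[[1]]$dags)
  expect_identical(r1$chains[[2]]$dags, r2$chains[[2]]$dags)
  expect_identical(r1$beta, r2$beta)
  expect_identical(r1$B_hat, r2$B_hat)
  expect_identical(r1$crms, r2$crms)
})

test_that("the inferred prior strength rewards knowledge that matches the data", {
  # beta weighs the prior by its agreement with the data: a B = 1 skeleton
  # equal to the generating DAG should earn a larger strength estimate than
  # the same skeleton with permuted sources
  wins <- 0L
  for (s in 1:10) {
    set.seed(900 + s)
    mod <- random_typed_dag(10, edge_density = 0.3)
    ds <- simulate_multiomics(mod, 100)
    gg <- mod$edges[mod$edges$type == "GE", ]
    true_prior <- data.frame(from = gg$from, to = gg$to, value = 1)
    perm <- setNames(sample(mod$genes), mod$genes)
    perm_prior <- data.frame(from = unname(perm[gg$from]), to = gg$to, value = 1)
    perm_prior <- perm_prior[perm_prior$from != perm_prior$to, ]
    run_beta <- function(prior, seed) {
      pm <- assemble_network_problem(ds, prior = prior)
      sc <- bge_scorer(pm$data, standardize = FALSE)
      cfg <- bn_config(adapt1_iters = 300L, adapt2_iters = 1500L,
                       transient_window = 200L, transient_max = 1200L)
      set.seed(seed)
      st <- bnomics:::.new_state(pm, sc, cfg = cfg)
      suppressWarnings({
        phase1_adapt(st, pm, sc, cfg)
        phase_transient(st, pm, sc, cfg)
        phase2_estimate(st, pm, sc, cfg)$beta_hat
      })
    }
    wins <- wins + (run_beta(true_prior, 7000 + s) > run_beta(perm_prior, 7000 + s))
  }
  expect_gte(wins, 9L)
})

test_that("a hard all-forbidden prior pins the chain to the empty graph", {
  set.seed(607)
  # weak data signal: independent genes
  pm <- make_ge_problem(matrix(rnorm(25 * 4), 25, 4))
  pm$B[pm$adm] <- 0                      # every edge actively forbidden
  sc <- bge_scorer(pm$data, standardize = FALSE)
  cfg <- bn_config(thin = 10L, n_paths = 1L)
  st <- bnomics:::.new_state(pm, sc, beta = 10, cfg = cfg)
  res <- sample_structures(pm, sc, st, cfg, 2000L)
  n_edges <- vapply(res$dags, sum, numeric(1))
  # the modal sampled structure is empty
  expect_equal(as.integer(names(which.max(table(n_edges)))), 0L)
  expect_lt(mean(n_edges), 0.5)
})
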