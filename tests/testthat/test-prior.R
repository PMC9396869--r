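# small typed problem builder: 3 GE genes, optional prior edges
prior_problem <- function(prior = NULL, m = 12, seed = 301) {
  set.seed(seed)
  make_ge_problem(matrix(rnorm(m * 3), m, 3,
                         dimnames = list(NULL, c("A", "B", "C"))), prior = prior)
}

test_that("local energy evaluates agreement with the B matrix", {
  # candidates of C are {A (B=1), B (B=0)}
  pm2 <- prior_problem(prior = data.frame(from = c("A", "B"), to = c("C", "C"),
                                          value = c(1, 0)))
  jC <- match("C", pm2$nodes$id)
  iA <- match("A", pm2$nodes$id); iB <- match("B", pm2$nodes$id)
  cand <- which(pm2$adm[, jC])
  expect_setequal(pm2$nodes$id[cand], c("A", "B"))
  expect_equal(local_energy(pm2, jC, iA), 0)        # perfect agreement
  expect_equal(local_energy(pm2, jC, iB), (1 - 0) + 1)  # worst choice: eps = 2
  expect_error(local_energy(pm2, jC, match("C", pm2$nodes$id)), "non-admissible")
})

test_that("all-0.5 knowledge gives constant energy over parent sets", {
  set.seed(302)
  pm <- make_ge_problem(matrix(rnorm(60), 12, 5))
  j <- 5L
  cand <- which(pm$adm[, j])
  vals <- unlist(lapply(0:length(cand), function(r) {
    if (r == 0) return(local_energy(pm, j, integer()))
    sets <- utils::combn(cand, r, simplify = FALSE)
    vapply(sets[seq_len(min(6, length(sets)))],
           function(s) local_energy(pm, j, s), numeric(1))
  }))
  expect_equal(vals, rep(0.5 * length(cand), length(vals)), tolerance = 1e-12)
})

test_that("graph energy sums local energies and changes by 1 - 2 B_ij per edge", {
  pm <- prior_problem(prior = data.frame(from = "A", to = "B", value = 0.9),
                      seed = 303)
  A0 <- matrix(0, pm$N, pm$N)
  e0 <- graph_energy(pm, A0)
  expect_equal(e0, sum(vapply(seq_len(pm$N), function(j)
    local_energy(pm, j, integer()), numeric(1))), tolerance = 1e-12)
  # empty graph under uniform B: 0.5 * (number of admissible pairs)
  pmu <- prior_problem(seed = 304)
  expect_equal(graph_energy(pmu, A0), 0.5 * sum(pmu$adm), tolerance = 1e-12)
  # finite difference on random admissible edges
  set.seed(305)
  for (rep in 1:20) {
    A <- matrix(0, pm$N, pm$N)
    free <- which(pm$adm & A == 0, arr.ind = TRUE)
    k <- free[sample.int(nrow(free), 1), ]
    A2 <- A; A2[k[1], k[2]] <- 1
    expect_equal(graph_energy(pm, A2) - graph_energy(pm, A),
                 1 - 2 * pm$B[k[1], k[2]], tolerance = 1e-12)
  }
})

test_that("partition bound matches brute-force parent-set enumeration", {
  # typed toy: 6 GE candidates would overflow a hand count, so enumerate
  set.seed(306)
  mod <- random_typed_dag(6, edge_density = 0.4, n_cnv = 1, n_meth = 0)
  ds <- simulate_multiomics(mod, 30)
  pm <- assemble_network_problem(ds)
  set.seed(307)
  pm$B[pm$adm] <- runif(sum(pm$adm))          # random knowledge values
  beta <- 1.3
  lz <- log_partition_upper(pm, beta)
  oracle <- 0
  for (j in seq_len(pm$N)) {
    cand <- which(pm$adm[, j])
    tot <- 0
    for (mask in 0:(2^length(cand) - 1)) {
      S <- cand[which(bitwAnd(mask, 2^(seq_along(cand) - 1)) > 0)]
      if (length(intersect(S, pm$ge_idx)) > pm$constraints$max_ge_parents) next
      if (length(intersect(S, pm$cnv_idx)) > pm$constraints$max_cnv_parents) next
      tot <- tot + exp(-beta * local_energy(pm, j, S))
    }
    oracle <- oracle + log(tot)
  }
  expect_equal(lz, oracle, tolerance = 1e-10)
})

test_that("partition bound closed forms hold at beta = 0 and one candidate", {
  pm <- prior_problem(seed = 308)
  # beta = 0, no caps binding (3 nodes, cap 3): every node factor is 2^c
  expect_equal(log_partition_upper(pm, 0), sum(log(2^colSums(pm$adm))),
               tolerance = 1e-12)
  # single-candidate node at B = 0.5: factor 2 * exp(-0.5 beta)
  set.seed(309)
  ds <- make_anchored_dataset(20, n_extra = 0)
  pm2 <- assemble_network_problem(ds)
  jG1 <- match("G01", pm2$nodes$id)
  jcnv <- match("cnv_G01", pm2$nodes$id)
  beta <- 2.7
  # isolate the cnv candidate's node factor: candidates of G01 are G02 + cnv
  # instead compute the full bound minus the same problem with beta = 0 ...
  # simpler: direct check on a 1-gene + 1-cnv problem
  ge <- matrix(rnorm(20), 20, 1, dimnames = list(sprintf("S%02d", 1:20), "G01"))
  cnv <- matrix(rnorm(20), 20, 1, dimnames = list(rownames(ge), "cnv_G01"))
  pm3 <- assemble_network_problem(omics_dataset(ge, cnv = cnv,
                                                cnv_map = c(cnv_G01 = "G01")))
  expect_equal(log_partition_upper(pm3, beta), log(2) - 0.5 * beta +
                 0,                               # cnv node itself has no candidates
               tolerance = 1e-12)
})

test_that("the bound dominates the true acyclic partition sum (<= 4 nodes)", {
  for (N in 3:4) {
    set.seed(310 + N)
    pm <- make_ge_problem(matrix(rnorm(15 * N), 15, N))
    set.seed(320 + N)
    pm$B[pm$adm] <- runif(sum(pm$adm))
    dags <- all_dags(N, pm$adm)
    for (beta in c(0.5, 1, 2)) {
      truth <- sum(vapply(dags, function(A) exp(-beta * graph_energy(pm, A)),
                          numeric(1)))
      expect_gte(exp(log_partition_upper(pm, beta)), truth)
    }
  }
})

test_that("log prior is uniform at beta = 0 and Z-free in differences", {
  pm <- prior_problem(prior = data.frame(from = "A", to = "B", value = 1),
                      seed = 330)
  A0 <- matrix(0, pm$N, pm$N)
  A1 <- A0; A1[match("A", pm$nodes$id), match("B", pm$nodes$id)] <- 1
  expect_equal(log_prior_structure(pm, A0, 0), log_prior_structure(pm, A1, 0),
               tolerance = 1e-12)
  for (beta in c(0.5, 1, 2, 4)) {
    dlp <- log_prior_structure(pm, A1, beta) - log_prior_structure(pm, A0, beta)
    dE <- graph_energy(pm, A1) - graph_energy(pm, A0)
    expect_equal(dlp, -beta * dE, tolerance = 1e-12)
  }
})

test_that("raising beta monotonically favours the minimum-energy structure", {
  pm <- prior_problem(prior = data.frame(from = c("A", "A"), to = c("B", "C"),
                                         value = c(1, 1)), seed = 331)
  dags <- all_dags(3, pm$adm)
  energies <- vapply(dags, function(A) graph_energy(pm, A), numeric(1))
  best <- dags[[which.min(energies)]]
  other <- dags[[which.max(energies)]]
  gaps <- vapply(c(0.5, 1, 2, 4), function(beta)
    log_prior_structure(pm, best, beta) - log_prior_structure(pm, other, beta),
    numeric(1))
  expect_true(all(diff(gaps) > 0))
})

test_that("beta-move ratio matches direct prior evaluation", {
  pm <- prior_problem(prior = data.frame(from = "B", to = "A", value = 0.75),
                      seed = 332)
  A <- matrix(0, pm$N, pm$N)
  A[match("B", pm$nodes$id), match("A", pm$nodes$id)] <- 1
  expect_equal(log_beta_ratio(pm, A, 1.7, 1.7), 0, tolerance = 1e-12)
  direct <- log_prior_structure(pm, A, 2.4) - log_prior_structure(pm, A, 0.8)
  expect_equal(log_beta_ratio(pm, A, 2.4, 0.8), direct, tolerance = 1e-12)
})

test_that("candidate-label permutation leaves local energy unchanged", {
  set.seed(333)
  pm <- make_ge_problem(matrix(rnorm(48), 12, 4))
  set.seed(334)
  pm$B[pm$adm] <- runif(sum(pm$adm))
  j <- 4L
  cand <- which(pm$adm[, j])
  pa <- cand[1:2]
  # permuting which candidates are in the parent set only changes energy
  # through their B values, not through labels: compare two relabelings
  e1 <- local_energy(pm, j, pa)
  manual <- sum(1 - pm$B[pa, j]) + sum(pm$B[setdiff(cand, pa), j])
  expect_equal(e1, manual, tolerance = 1e-12)
})
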