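test_that("simulator matches coalescent closed forms on the benchmark quartet", {
  # no gene flow: each discordant rooted triplet has probability e^-2/3
  # (the (A,B) ancestral population spans 2 coalescent units)
  set.seed(301)
  m <- simulate_mc_summary(quartet_null(0.01), samples1, 3e4)
  p_dis <- exp(-2) / 3
  se <- sqrt(p_dis * (1 - p_dis) / 3e4)
  expect_lt(abs(mean(m$topology == 2) - p_dis), 3 * se)
  expect_lt(abs(mean(m$topology == 3) - p_dis), 3 * se)

  # certain introgression (phi = 1, inflow): P((B,C) cherry) = 1 - (2/3)e^-3
  net1 <- quartet_network(0.01, "inflow", "msci", phi = 1)
  m1 <- simulate_mc_summary(net1, samples1, 3e4)
  p_bc <- 1 - (2 / 3) * exp(-3)
  se1 <- sqrt(p_bc * (1 - p_bc) / 3e4)
  expect_lt(abs(mean(m1$topology == 3) - p_bc), 3 * se1)

  # mixture at phi = 0.2
  net2 <- quartet_network(0.01, "inflow", "msci", phi = 0.2)
  m2 <- simulate_mc_summary(net2, samples1, 3e4)
  p_mix <- 0.2 * p_bc + 0.8 * p_dis
  se2 <- sqrt(p_mix * (1 - p_mix) / 3e4)
  expect_lt(abs(mean(m2$topology == 3) - p_mix), 3 * se2)
})

test_that("single-lineage migration probability equals the band formula", {
  set.seed(302)
  netm <- quartet_network(0.01, "inflow", "mscm", M = 0.1)
  mm <- simulate_mc_summary(netm, c(B = 1), 3e4, mode = "mscm")
  p <- expected_cumulative_introgression(0.1, 0.01, 0.01)
  se <- sqrt(p * (1 - p) / 3e4)
  expect_lt(abs(mean(mm$n_jumps > 0) - p), 3 * se)
})

test_that("within-species pairwise coalescent time has mean theta/2", {
  set.seed(303)
  ms <- simulate_mc_summary(quartet_null(0.01), c(A = 2), 2e4)
  expect_lt(abs(mean(ms$root_age) - 0.005), 3 * 0.005 / sqrt(2e4))
})

test_that("migration simulator matches an independent pure-R oracle", {
  # inflow-migration quartet, M = 0.1: triplet-class frequencies against a
  # from-scratch structured-coalescent simulation written in R
  theta <- 0.01; M <- 0.1; n <- 2e4
  set.seed(304)
  netm <- quartet_network(theta, "inflow", "mscm", M = M)
  sim <- simulate_mc_summary(netm, samples1, n, mode = "mscm")
  set.seed(305)
  orc <- replicate(n, oracle_mscm_quartet_topology(theta, M))
  tab <- rbind(tabulate(sim$topology, 3), tabulate(orc, 3))
  pval <- suppressWarnings(chisq.test(tab)$p.value)
  expect_gt(pval, 0.001)
})

test_that("JC sequence evolution matches the pairwise closed form", {
  set.seed(306)
  gt <- list(parent = c(2L, 2L, -1L), age = c(0, 0, 0.05),
             tip_species = c("X", "X"), tip_labels = c("x1", "x2"),
             tip_individual = c(1, 2))
  aln <- simulate_jc_alignment(gt, 5e4)
  s <- strsplit(aln$seq, "")
  p_exp <- 0.75 * (1 - exp(-4 * 0.1 / 3))
  expect_lt(abs(mean(s[[1]] != s[[2]]) - p_exp),
            3 * sqrt(p_exp * (1 - p_exp) / 5e4))

  # zero-length tree: identical sequences
  gt0 <- list(parent = c(2L, 2L, -1L), age = c(0, 0, 0),
              tip_species = c("X", "X"), tip_labels = c("x1", "x2"),
              tip_individual = c(1, 2))
  a0 <- simulate_jc_alignment(gt0, 100)
  expect_equal(a0$seq[1], a0$seq[2])

  # zero sites: a valid empty alignment
  az <- simulate_jc_alignment(gt, 0)
  expect_equal(az$n, 0L)
  expect_error(simulate_jc_alignment(gt, -1), "nonnegative")
})

test_that("datasets are reproducible and per-locus substreams are isolated", {
  net <- quartet_null(0.01)
  set.seed(99)
  d1 <- simulate_dataset(net, samples1, L = 3, n_sites = 30, mode = "msci")
  set.seed(99)
  d2 <- simulate_dataset(net, samples1, L = 3, n_sites = 30, mode = "msci")
  expect_identical(lapply(d1$alignments, `[[`, "seq"),
                   lapply(d2$alignments, `[[`, "seq"))
  # locus 2 regenerated in isolation from its own seed
  set.seed(d1$locus_seeds[2])
  gt <- simulate_gene_tree(net, samples1, "msci")
  a <- simulate_jc_alignment(gt, 30, id = 2)
  expect_identical(a$seq, d1$alignments[[2]]$seq)
})

test_that("mode/network combinations are validated", {
  neti <- quartet_network(0.01, "inflow", "msci")
  netm <- quartet_network(0.01, "inflow", "mscm")
  expect_error(simulate_gene_tree(netm, samples1, "msci"), "without migration")
  expect_error(simulate_gene_tree(neti, samples1, "mscm"), "without an introgression")
  expect_error(simulate_gene_tree(neti, c(Z = 1), "msci"), "unknown species")
  expect_error(simulate_gene_tree(neti, c(A = 0), "msci"), "at least one")
})

test_that("gene trees carry a consistent event log", {
  set.seed(307)
  neti <- quartet_network(0.01, "inflow", "msci", phi = 1)
  gt <- simulate_gene_tree(neti, samples1, "msci")
  # with phi = 1 every lineage crossing the introgression time took the donor
  # path; the B tip must have crossed
  b_tip <- which(gt$tip_species == "B")
  expect_equal(gt$crossed[b_tip], 1L)
  expect_equal(gt$bits[b_tip], 1L)
  # ultrametric: all tips at age 0, root the oldest node
  expect_true(all(gt$age[seq_along(gt$tip_labels)] == 0))
  expect_equal(which.max(gt$age), length(gt$parent))
})
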