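test_that("jc_distance implements the correction and its domain", {
  expect_equal(jc_distance(0), 0)
  expect_equal(jc_distance(3 / 16), -0.75 * log(0.75))
  expect_error(jc_distance(0.75), "saturates")
  expect_error(jc_distance(0.9), "saturates")
})

test_that("quartet ML is an argmax with flagged ties", {
  dat <- make_tiny_dataset(seed = 41, n = 400)
  a <- dat$alignments[[1]]
  fit <- quartet_ml_jc(a, a$labels)
  # best topology's log-likelihood is the maximum by construction
  expect_equal(which.max(fit$loglik), fit$topology)
  expect_length(fit$branch_lengths, 5)
  expect_true(all(fit$branch_lengths >= 1e-9))

  # invariant alignment: three equal log-likelihoods, tie flagged
  a0 <- locus_alignment(1, setNames(rep(strrep("A", 60), 4),
                                    c("a", "b", "c", "o")), rep("X", 4))
  f0 <- quartet_ml_jc(a0, c("a", "b", "c", "o"))
  expect_true(f0$tie)
  expect_lt(max(f0$loglik) - min(f0$loglik), 1e-6)
})

test_that("two-taxon branch-length optimum equals the JC distance", {
  # the pruning likelihood of a two-tip tree is maximised at the analytic
  # JC distance of the observed mismatch fraction
  set.seed(52)
  gt <- list(parent = c(2L, 2L, -1L), age = c(0, 0, 0.04),
             tip_species = c("X", "X"), tip_labels = c("x1", "x2"),
             tip_individual = c(1, 2))
  aln <- simulate_jc_alignment(gt, 2000)
  s <- strsplit(aln$seq, "")
  p <- mean(s[[1]] != s[[2]])
  pat <- mscflow:::aln_patterns(aln)
  f <- function(d) -cpp_jc_loglik(pat$mask, pat$wt, c(2L, 2L, -1L), c(0, 0, d / 2))
  opt <- optimize(f, c(1e-6, 1))
  expect_equal(opt$minimum, jc_distance(p), tolerance = 1e-4)
})

test_that("quartet ML is consistent: recovery improves with sites", {
  set.seed(53)
  net <- quartet_network(0.02, "inflow", "none")
  recovery <- function(n_sites, total) {
    hits <- 0
    for (r in 1:total) {
      gt <- simulate_gene_tree(net, samples1, "msci")
      a <- simulate_jc_alignment(gt, n_sites)
      f <- quartet_ml_jc(a, c("A^1", "B^1", "C^1", "O^1"))
      cl <- classify_triplet(gt$phylo, c("A^1", "B^1"), "O^1",
                             flow_pair = c("B^1", "C^1"))
      est <- switch(f$topology, "con", "dis1", "dis2")
      if (!f$tie && est == cl$class) hits <- hits + 1
    }
    hits / total
  }
  r2000 <- recovery(2000, 30)
  expect_gte(r2000, 0.9) # near-certain recovery at n = 2000
  r250 <- recovery(250, 30)
  expect_gte(r2000, r250 - 0.1) # and no worse than at n = 250
})

test_that("classify_triplet follows the rooted-triplet definitions", {
  tr <- parse_newick("(((A:1,B:1):1,C:2):1,O:3);")
  r <- classify_triplet(tr, c("A", "B"), "O", flow_pair = c("B", "C"))
  expect_equal(r$class, "con")
  expect_equal(r$internal_length, 1)

  tr2 <- parse_newick("(((B:1,C:1):0.5,A:1.5):1.5,O:3);")
  r2 <- classify_triplet(tr2, c("A", "B"), "O", flow_pair = c("B", "C"))
  expect_equal(r2$class, "dis2")
  expect_equal(r2$internal_length, 0.5)

  tr3 <- parse_newick("(((A:1,C:1):0.5,B:1.5):1.5,O:3);")
  r3 <- classify_triplet(tr3, c("A", "B"), "O", flow_pair = c("B", "C"))
  expect_equal(r3$class, "dis1")

  expect_error(classify_triplet(tr, c("A", "Z"), "O"), "missing")
})

test_that("under pure ILS the two discordant classes are symmetric", {
  set.seed(54)
  m <- simulate_mc_summary(quartet_null(0.01), samples1, 2e4)
  d1 <- sum(m$topology == 2); d2 <- sum(m$topology == 3)
  expect_gt(binom.test(d2, d1 + d2, 0.5)$p.value, 0.001)
})

test_that("triplet classification pipeline excludes tied loci", {
  set.seed(55)
  net <- quartet_network(0.01, "inflow", "none")
  dat <- simulate_dataset(net, samples2, L = 6, n_sites = 120, mode = "msci")
  cls <- infer_triplet_classes(dat$alignments, c("A", "B", "C", "O"))
  expect_equal(nrow(cls), 6)
  expect_true(all(is.na(cls$class) == cls$tie | !cls$tie))
  cc <- triplet_counts(cls)
  expect_equal(cc$c_con + cc$c_dis1 + cc$c_dis2 + cc$n_excluded, 6)
})
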