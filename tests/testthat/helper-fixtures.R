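# Shared fixtures and independent oracles for the test suite.

# the benchmark quartet (((A,B)T, C)S, O)R with tau = (3,2,1) x theta
quartet_null <- function(theta = 0.01) quartet_network(theta, "inflow", "none")

samples1 <- c(A = 1, B = 1, C = 1, O = 1)
samples2 <- c(A = 2, B = 2, C = 2, O = 2)

# a tiny 3-locus dataset reused across io / summary tests
make_tiny_dataset <- function(seed = 101, L = 3, n = 40, theta = 0.01) {
  set.seed(seed)
  net <- quartet_null(theta)
  simulate_dataset(net, samples1, L = L, n_sites = n, mode = "msci")
}

# ---------------------------------------------------------------------------
# Independent structured-coalescent oracle (pure R, written separately from
# the C++ engine) for the inflow-migration quartet of the benchmark design:
# species (((A,B)T, C)S, O)R, tau = (3,2,1)*theta, band C->B with rate M
# active over (0, tauT); one sampled lineage per species.  Returns the
# rooted-triplet topology of (A,B,C): 1 = (A,B), 2 = (A,C), 3 = (B,C).
# ---------------------------------------------------------------------------
oracle_mscm_quartet_topology <- function(theta, M) {
  tauT <- theta; tauS <- 2 * theta; tauR <- 3 * theta
  rate_mig <- 4 * M / theta        # backward jump rate of the B lineage
  t <- 0
  # phase 1: (0, tauT): lineages A, B, C in own branches; B may jump to C's
  # population (pop C spans (0, tauS)); after a jump B and C can coalesce.
  pos_b <- "B"
  first <- NULL                     # first coalescing pair
  t_bc <- Inf
  while (t < tauT) {
    rates <- c(jump = if (pos_b == "B") rate_mig else 0,
               coalBC = if (pos_b == "C") 2 / theta else 0)
    tot <- sum(rates)
    if (tot == 0) { t <- tauT; break }
    dt <- stats::rexp(1, tot)
    if (t + dt > tauT) { t <- tauT; break }
    t <- t + dt
    if (stats::runif(1) < rates["jump"] / tot) pos_b <- "C"
    else return(3L)                 # B-C coalesced first
  }
  # phase 2: (tauT, tauS): A enters T; if B still in its own branch it joins
  # T as well, otherwise B's ancestor stays in C's population with C.
  t <- tauT
  inT <- c("A", if (pos_b == "B") "B")
  inC <- c("C", if (pos_b == "C") "B")
  while (t < tauS) {
    rates <- c(coalT = if (length(inT) == 2) 2 / theta else 0,
               coalC = if (length(inC) == 2) 2 / theta else 0)
    tot <- sum(rates)
    if (tot == 0) { t <- tauS; break }
    dt <- stats::rexp(1, tot)
    if (t + dt > tauS) { t <- tauS; break }
    t <- t + dt
    if (stats::runif(1) < rates["coalT"] / tot) return(1L) else return(3L)
  }
  # phase 3: >= tauS: the three remaining lineages are exchangeable
  switch(sample(c("AB", "AC", "BC"), 1), AB = 1L, AC = 2L, BC = 3L)
}
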