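#' Prior specification for the Bayesian introgression model
#'
#' Gamma priors (shape, rate) on the species-tree root age and on every
#' branch population size, and a beta prior on the introgression probability.
#' Non-root divergence times (and the introgression time) are uniform over
#' the order-compatible region given the root age.
#'
#' @param tau_shape,tau_rate gamma prior on the root age (substitutions/site).
#' @param theta_shape,theta_rate gamma prior on each branch theta.
#' @param phi_a,phi_b beta prior on phi (default uniform, beta(1,1)).
#' @return a `prior_spec` list.
#' @export
prior_spec <- function(tau_shape = 2, tau_rate = 266,
                       theta_shape = 2, theta_rate = 800,
                       phi_a = 1, phi_b = 1) {
  stopifnot(tau_shape > 0, tau_rate > 0, theta_shape > 0, theta_rate > 0,
            phi_a > 0, phi_b > 0)
  structure(list(tau_shape = tau_shape, tau_rate = tau_rate,
                 theta_shape = theta_shape, theta_rate = theta_rate,
                 phi_a = phi_a, phi_b = phi_b), class = "prior_spec")
}

#' Priors matched to a simulation setting
#'
#' Shape-2 gamma priors whose means equal the generating values: mean theta
#' for the population sizes and the true root age for tau (e.g. theta =
#' 0.0025 with root age 3 theta gives theta ~ G(2, 800), tau ~ G(2, 266.7)).
#'
#' @param theta generating population size.
#' @param root_age generating root age (defaults to `3 * theta`).
#' @return a `prior_spec`.
#' @export
matched_priors <- function(theta, root_age = 3 * theta) {
  prior_spec(tau_shape = 2, tau_rate = 2 / root_age,
             theta_shape = 2, theta_rate = 2 / theta)
}

#' Log coalescent density of a gene tree under the introgression model
#'
#' The product over populations of standard coalescent factors -- `2/theta`
#' per coalescence and `exp(-k(k-1) dt / theta)` per inter-event interval
#' with `k` lineages -- times `phi^a (1-phi)^b` over the `a` lineages taking
#' the donor path and `b` taking the main path at the introgression time.
#'
#' @param gene_tree a `gene_tree` (from [simulate_gene_tree()]), or a list
#'   with `parent` (0-based), `age`, `bits` and `tip_species` fields.
#' @param net a [species_network] with (at most) one introgression edge.
#' @return log density (may be `-Inf` when `phi` is 0/1 and the parent
#'   choices have zero probability); an incompatible gene tree is an error.
#' @export
msci_gene_tree_log_density <- function(gene_tree, net) {
  tip_sp <- match(gene_tree$tip_species, net$labels) - 1L
  if (anyNA(tip_sp)) stop("gene tree tips do not match network species")
  bits <- gene_tree$bits
  if (is.null(bits)) bits <- integer(length(gene_tree$parent))
  phi <- if (!is.null(net$introgression)) net$introgression$phi else 0
  res <- cpp_coal_logdensity(as_cpp_net(net), as.integer(gene_tree$parent),
                             as.numeric(gene_tree$age), as.integer(bits),
                             as.integer(tip_sp), phi)
  res$logdens
}

#' Jukes-Cantor log-likelihood of an alignment on a gene tree
#'
#' Felsenstein pruning with JC transition probabilities and site-pattern
#' compression; ambiguity codes and gaps contribute partial likelihood 1 for
#' every compatible base. An empty alignment has log-likelihood 0.
#'
#' @param aln a [locus_alignment] whose labels match the gene-tree tips.
#' @param gene_tree a `gene_tree`.
#' @return log-likelihood.
#' @export
jc_log_likelihood <- function(aln, gene_tree) {
  if (aln$n == 0) return(0)
  pat <- aln_patterns(aln, labels = gene_tree$tip_labels)
  cpp_jc_loglik(pat$mask, pat$wt, as.integer(gene_tree$parent),
                as.numeric(gene_tree$age))
}

#' Bayesian MCMC under the quartet introgression model
#'
#' Metropolis-within-Gibbs sampler for the full-likelihood MSC-I model:
#' latent per-locus gene trees (node-age sliding windows, NNI topology moves,
#' hybrid parent-choice flips), per-branch population sizes (log-scale
#' windows against cached coalescent sufficient statistics), divergence and
#' introgression times (rubber-band moves that rescale gene-tree node ages
#' inside the affected populations, with Jacobian), and an exact Gibbs update
#' of `phi` from its conditional beta distribution. Proposal windows are
#' tuned towards 30% acceptance during burn-in and frozen afterwards.
#' Population sizes are per-branch, with the recipient branch sharing one
#' theta across the introgression time point. Gene trees are initialised by
#' simulating from the model at the template's parameter values (with
#' `phi = 1/2`), giving a deterministic-seed, always-compatible warm start.
#'
#' @param alignments list of [locus_alignment] objects (zero loci samples
#'   the prior).
#' @param net a [species_network] giving the model topology and the initial
#'   parameter values (typically prior means); must carry the introgression
#'   edge unless a pure MSC fit is wanted.
#' @param priors a [prior_spec].
#' @param samples_per_species named vector used when `alignments` is empty
#'   (prior sampling) to size the latent trees; otherwise inferred.
#' @param burnin,n_samples,thin MCMC schedule; the trace has `n_samples` rows
#'   recorded every `thin` iterations after `burnin`.
#' @param tau_every run the divergence-time sweep every this many iterations.
#' @param age_moves node-age proposals per locus per iteration.
#' @param mix_every run the joint time/size rescaling move every this many
#'   iterations.
#' @param resim_every run the per-locus gene-tree resimulation (independence)
#'   proposal every this many iterations.
#' @return a `posterior_trace`: tibble with one row per sample (divergence
#'   times, `tau_h`, per-branch thetas, `phi`, `lnL`), with attributes
#'   `acceptance`, `settings` and `priors`.
#' @export
run_mcmc <- function(alignments, net, priors,
                     samples_per_species = NULL,
                     burnin = 1000, n_samples = 3000, thin = 1,
                     tau_every = 2, age_moves = 2, mix_every = 1,
                     resim_every = 1) {
  stopifnot(inherits(net, "species_network"), inherits(priors, "prior_spec"))
  if (!is.null(net$migration))
    stop("inference is implemented for the introgression (MSC-I) model only")
  nloci <- length(alignments)
  tips <- tip_ids(net)
  if (nloci > 0) {
    spp <- table(alignments[[1]]$species)
    samples_per_species <- setNames(as.integer(spp), names(spp))
  } else if (is.null(samples_per_species)) {
    samples_per_species <- setNames(rep(1L, length(tips)), net$labels[tips])
  }

  init_net <- net
  if (!is.null(init_net$introgression)) init_net$introgression$phi <- 0.5

  loci <- vector("list", max(nloci, 0))
  init <- vector("list", max(nloci, 0))
  if (nloci > 0) {
    for (l in seq_len(nloci)) {
      a <- alignments[[l]]
      gt <- simulate_gene_tree(init_net, samples_per_species,
                               mode = "msci")
      # tie alignment rows to simulated tips by species/individual
      key_a <- paste(a$species, a$individual)
      key_t <- paste(gt$tip_species, gt$tip_individual)
      idx <- match(key_t, key_a)
      if (anyNA(idx))
        stop("locus ", l, ": sequences do not match the sampling layout")
      pat <- aln_patterns(a, labels = a$labels[idx])
      tip_sp <- match(gt$tip_species, net$labels) - 1L
      loci[[l]] <- list(mask = pat$mask, wt = pat$wt,
                        tip_sp = as.integer(tip_sp))
      init[[l]] <- list(parent = as.integer(gt$parent),
                        age = as.numeric(gt$age),
                        bits = as.integer(gt$bits))
    }
  }
  pri <- list(theta_shape = priors$theta_shape, theta_rate = priors$theta_rate,
              tau_shape = priors$tau_shape, tau_rate = priors$tau_rate,
              phi_a = priors$phi_a, phi_b = priors$phi_b)
  sett <- list(burnin = as.integer(burnin), nsamples = as.integer(n_samples),
               thin = as.integer(thin), tau_every = as.integer(tau_every),
               age_moves = as.integer(age_moves),
               mix_every = as.integer(mix_every),
               resim_every = as.integer(resim_every))
  res <- cpp_mcmc_msci(as_cpp_net(init_net), loci, init, pri, sett)
  tr <- tibble::as_tibble(as.data.frame(res$trace))
  names(tr) <- rename_trace_cols(names(tr), net)
  attr(tr, "acceptance") <- res$acceptance
  attr(tr, "settings") <- sett
  attr(tr, "priors") <- priors
  class(tr) <- c("posterior_trace", class(tr))
  tr
}

# map tau_<idx>/theta_<idx> columns to species labels
rename_trace_cols <- function(cn, net) {
  relab <- function(prefix, nm) {
    idx <- as.integer(sub(paste0(prefix, "_"), "", nm)) + 1L
    paste0(prefix, "_", net$labels[idx])
  }
  out <- cn
  tau_cols <- grepl("^tau_[0-9]+$", cn)
  theta_cols <- grepl("^theta_[0-9]+$", cn)
  out[tau_cols] <- relab("tau", cn[tau_cols])
  out[theta_cols] <- relab("theta", cn[theta_cols])
  out
}

#' Highest-posterior-density interval
#'
#' Shortest contiguous window of sorted samples containing just over `mass`
#' of the sample (window size `floor(mass * N) + 1`, capped at `N`); the
#' leftmost shortest window is returned.
#'
#' @param samples numeric vector (>= 2 values).
#' @param mass credibility mass (default 0.95).
#' @return numeric `c(low, high)`.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  n <- length(samples)
  if (n < 2) stop("at least two samples required")
  stopifnot(mass > 0, mass <= 1)
  x <- sort(samples)
  m <- min(n, floor(mass * n) + 1L)
  widths <- x[m:n] - x[1:(n - m + 1)]
  i <- which.min(widths)
  c(x[i], x[i + m - 1L])
}

#' Savage-Dickey Bayes factor for the test of gene flow
#'
#' Approximates the Bayes factor in favour of gene flow by the ratio of prior
#' to posterior mass in the near-null region:
#' `B10 = P(phi < eps) / P(phi < eps | X)`, with the posterior probability
#' estimated as the fraction of sampled `phi` values below `eps`. When no
#' samples fall below `eps`, the posterior mass is floored at `1/N` (a trace
#' of `N` samples cannot resolve smaller probabilities) and the result is
#' flagged as capped. Values of `B10 > 100` are interpreted as strong support
#' for gene flow, `B10 < 0.01` as strong support for its absence.
#'
#' @param trace a `posterior_trace` (or numeric vector of phi samples).
#' @param priors a [prior_spec] giving the beta prior on phi.
#' @param epsilon null-region width (default 0.01; the conclusion should be
#'   insensitive to e.g. 0.001).
#' @return list with `B10`, `prior_mass`, `posterior_mass`, `capped`.
#' @export
savage_dickey_bf <- function(trace, priors, epsilon = 0.01) {
  if (epsilon <= 0 || epsilon >= 1) stop("epsilon must be in (0, 1)")
  phi <- if (is.numeric(trace)) trace else trace$phi
  if (is.null(phi) || !length(phi)) stop("trace contains no phi samples")
  n <- length(phi)
  prior_mass <- pbeta(epsilon, priors$phi_a, priors$phi_b)
  k <- sum(phi < epsilon)
  capped <- k == 0
  post <- max(k, 1) / n
  list(B10 = prior_mass / post, prior_mass = prior_mass,
       posterior_mass = k / n, capped = capped)
}
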