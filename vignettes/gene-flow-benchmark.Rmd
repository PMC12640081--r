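---
title: "Benchmarking full-likelihood and summary tests of cross-species gene flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking full-likelihood and summary tests of cross-species gene flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscflow)
```

## The problem

Gene flow between diverging species leaves a signature in multilocus
sequence data: gene trees whose topologies and coalescent times depart from
what ancestral polymorphism (incomplete lineage sorting, ILS) alone would
produce. Two model families formalise this under the multispecies
coalescent (MSC): a pulse of introgression at a single time point with
probability $\varphi$ (MSC-I), and continuous migration at a rate of $M$
migrants per generation over a time interval (MSC-M). Practitioners detect
gene flow either with full-likelihood Bayesian inference, which treats the
per-locus gene trees as latent variables and averages over them, or with
summary statistics computed from reconstructed gene trees or pooled site
patterns. This package implements both sides at quartet scale so their
power, bias, and interval calibration can be compared on simulated data
under known truth.

All times and population sizes are measured in expected substitutions per
site: $\theta = 4N\mu$, so a population of size $\theta$ coalesces lineage
pairs at rate $2/\theta$, and a migration band at rate $M$ moves a lineage
of the recipient population (backwards in time) into the donor at rate
$4M/\theta_\text{recipient}$. With that parameterisation the cumulative
introgression probability implied by a band of duration $\Delta\tau$ is
exactly

$$\varphi_0 \;=\; 1 - e^{-4M\Delta\tau/\theta},$$

implemented as `expected_cumulative_introgression()`. This is the value a
pulse model is expected to recover (at most) when the true history is
continuous migration.

## The benchmark design

`quartet_network()` builds the study system: species tree
$(((A,B)T, C)S, O)R$ with divergence times $\tau_R = 3\theta$,
$\tau_S = 2\theta$, $\tau_T = \theta$, one $\theta$ for every branch at
simulation time, and gene flow between the nonsister species B and C —
either *inflow* (C into B) or *outflow* (B into C), as a pulse at
$\tau_h = \theta/2$ with $\varphi = 0.2$ or as a band with $M = 0.1$.
Two regimes of information are used: $\theta \in \{0.0025, 0.01\}$, loci of
$n \in \{250, 1000\}$ sites, $L \in \{250, 1000, 4000\}$ loci and
$S \in \{2, 8\}$ sequences per species. These defaults are the package's
study conditions, not tuning knobs.

```{r design}
net <- quartet_network(theta = 0.0025, direction = "inflow", mode = "msci",
                       phi = 0.2)
net
```

## The simulator

`simulate_gene_tree()` runs the structured coalescent backwards in time by
competing exponentials within epochs delimited by species divergences, the
introgression time, and migration-band endpoints. At the introgression time
every lineage in the recipient branch independently reparents into the
donor branch with probability $\varphi$ (logged); under migration, lineages
jump at the backward rate above (jumps logged). Sequences evolve by
Jukes-Cantor: uniform root state, change probability
$\tfrac34(1 - e^{-4d/3})$ along a branch of length $d$.

The simulator is validated in the test suite against closed forms rather
than against itself: the ILS discordance probability $e^{-2}/3$ per
discordant class; the certain-introgression probability
$P[((B,C),A)] = 1 - \tfrac23 e^{-3}$ at $\varphi = 1$; their
$\varphi$-mixture; the single-lineage band-crossing probability
$1 - e^{-4M\Delta\tau/\theta}$; the JC mismatch fraction; and an
equality-in-distribution check against an independent pure-R
structured-coalescent simulation of the migration quartet. What these
checks do *not* establish is realism of the generating model itself: loci
are unlinked and recombination-free, rates are constant across sites and
loci, and the JC model is correct by construction. Conclusions about real
data inherit those assumptions.

## Gene-tree estimation and the summary tests

Summary methods consume per-locus gene trees. `quartet_ml_jc()` replaces a
general tree-search program at quartet scale: for each of the three
unrooted topologies it maximises the JC pruning likelihood over the five
branch lengths (L-BFGS-B, bounds $[10^{-9}, 5]$, two deterministic starts,
ties within $10^{-9}$ log-units excluded from counts). With one random
sequence per species (the convention when multiple are available), rooting
at the outgroup classifies each locus as concordant (`con`), or one of the
two discordant classes; `dis2` is defined as the class grouping the
hypothesised gene-flow pair, so an excess of `dis2` is evidence for gene
flow in that pair.

* **DCT** (`dct_test()`): $\hat\varphi = (c_{dis2} - c_{dis1})/(c_{con} +
  c_{dis1} + c_{dis2})$, truncated to 0 when $c_{dis1} > c_{dis2}$;
  significance by an exact two-sided binomial test of $c_{dis2}$ against
  $c_{dis1}$ at $p = 1/2$ (under ILS alone the discordant classes are
  exchangeable). The binomial choice is this package's; the original count
  test's statistic is not printed in the literature we benchmark against.
* **BLT** (`blt_test()`): two-sided Mann-Whitney U contrast of the internal
  branch lengths of the two discordant classes, chosen over a t-test
  because the lengths are exponential-like and heavily tied at zero.
* **Mixture test** (`quibl_fit()`, `quibl_test()`): internal branch lengths
  of a discordant class as $\pi_1\,\lambda e^{-\lambda t} + \pi_2\,\lambda
  e^{-\lambda(t - C)}\mathbf 1[t \ge C]$ with shared rate $\lambda$, the
  shift $C$ profiled on a 50-point grid over $[0, \max t]$ and
  $(\lambda, \pi_2)$ fitted by EM at each grid point; a class is called
  significant when the two-component BIC wins by at least 10 *and*
  $\pi_2 \ge 0.1$. Fidelity to any particular published implementation is
  not claimed; the model is a concrete, testable variant.
* **D-statistic** (`d_statistic()`): ABBA-BABA counts pooled over loci with
  outgroup polarisation; $D = (n_{ABBA} - n_{BABA})/(n_{ABBA} + n_{BABA})$.

Two numerical choices here deserve emphasis, because both were forced by
calibration failures that a naive implementation exhibits at exactly the
settings this benchmark cares about (short, low-divergence loci):

1. *Measurement resolution in the mixture test.* ML branch lengths from an
   $n$-site locus are quantised: most are exactly zero and the rest sit
   near multiples of $1/n$. A continuous mixture component will chase that
   discreteness and win enormous BIC margins on null data. `quibl_fit()`
   therefore integrates each component over a bin of width `resolution`
   around the observed value (use `resolution = 1/n_sites` for ML lengths;
   0 keeps the continuous model for exactly observed lengths). Shifts below
   the measurement resolution are then undetectable — which is the correct
   behaviour, and reproduces the known near-zero power of branch-length
   mixture tests under outflow gene flow while retaining their power on
   informative inflow data.
2. *Jackknife on the count difference.* The delete-one block jackknife
   applied to the ratio $D$ is anti-conservative when per-locus
   informative-site counts are sparse (empirical size ~4% at nominal 1%).
   `d_statistic()` therefore jackknifes the numerator
   $n_{ABBA} - n_{BABA}$ over loci (testing $D = 0$ is equivalent since the
   denominator is positive); empirical size is then 0.2-0.8% across the
   benchmark settings.

## The Bayesian engine

`run_mcmc()` implements full-likelihood inference under the quartet MSC-I
model: per-branch $\theta$ (the recipient branch shares one $\theta$ across
the introgression time point), divergence times, the introgression time
$\tau_h$, and $\varphi$, with the per-locus gene trees as latent variables
and the JC pruning likelihood (site patterns compressed; ambiguity codes
contribute partial likelihood 1 for compatible bases).

Priors: gamma on each $\theta$ and on the root age (`matched_priors()`
builds the shape-2 priors whose means equal the generating values, the
convention of the benchmark), flat on the non-root times over the
order-compatible region given the root (density $\propto \tau_R^{-k}$ for
$k$ free non-root times — a simplification of a uniform-Dirichlet prior
that is exact in its root-age marginal), and beta(1, 1) on $\varphi$.

The kernel is Metropolis-within-Gibbs with one deliberate structural
choice: **the discrete introgression parent-choices are marginalised
analytically**. The $k$ lineages present in the recipient branch at
$\tau_h$ admit $2^k$ donor/main assignments; the coalescent density of each
is computed by a population sweep and cached with its sufficient statistics
(per-population coalescent counts and exposures, donor counts). Latent-flag
samplers mix poorly here because a flag flip usually contradicts the
current gene tree; marginalisation removes that bottleneck entirely, at a
cost exponential in $k$ (trivial at the benchmark's 2 sequences per
species; the engine refuses $k > 16$).

Moves, per iteration:

* per-locus node-age sliding windows (reflected) and NNI topology changes,
  accepted against the marginalised coalescent density times the pruning
  likelihood (conditional likelihoods are cached and recomputed only along
  the dirty path to the root);
* a per-locus *resimulation* independence proposal: a fresh gene tree drawn
  from the coalescent prior at the current parameters, accepted with the
  sequence-likelihood ratio (the prior densities cancel). At the weakest
  benchmark setting this accepts ~20% of the time and dominates mixing;
* $\varphi$ by partially collapsed Gibbs: one assignment is drawn per locus
  from its exact conditional, then $\varphi \sim$ beta posterior of the
  drawn donor/main counts;
* each $\theta$ by a log-scale window against the cached sufficient
  statistics;
* each divergence time by a rubber-band move (gene-tree node ages inside
  the populations adjacent to the moving boundary are rescaled linearly,
  with Jacobian), conditioned on a drawn assignment;
* a joint rescaling ("mixing") move multiplying every time and every
  $\theta$ by a common factor — the coalescent core transforms
  analytically, so only the pruning likelihood is recomputed;
* a coupled $(\tau_h, \varphi)$ move along their posterior ridge: moving
  the introgression time rescales $\varphi$ to hold constant the expected
  number of *completed* introgressions,
  $\varphi\,[1 - e^{-2(\tau_{\text{top}} - \tau_h)/\theta_d}]$, with the
  exact Jacobian. This ridge is what makes $\varphi$ genuinely harder to
  pin down under outflow than under inflow, and a sampler that fails to
  travel it understates the outflow credible intervals.

Proposal windows adapt towards 30% acceptance during burn-in and are frozen
afterwards. Gene trees are initialised by simulating from the model at the
template's parameter values with $\varphi = 1/2$ — a warm start that is
always population-compatible and deterministic under the caller's seed.

Correctness is established by independent oracles in the test suite: the
two-lineage density and its normalisation by quadrature; the marginalised
density against brute-force enumeration of explicit assignments; the JC
pruning likelihood against the pairwise closed form and under rerooting
(reversibility); an end-to-end single-population posterior against 2-D
numerical integration; and prior recovery — the full kernel run with zero
loci reproduces the prior moments of $\varphi$, the root age, the
$\theta$s, and the conditional uniformity of $\tau_h$.

Hypothesis testing uses the Savage-Dickey ratio
(`savage_dickey_bf()`): $B_{10} = P(\varphi < \epsilon)/P(\varphi <
\epsilon \mid X)$ with $\epsilon = 0.01$ by default (conclusions should be
checked at 0.001), the posterior mass estimated from the trace, floored at
$1/N$ (flagged `capped`) when no samples fall below $\epsilon$ — a trace of
$N$ samples cannot resolve smaller probabilities, so reported Bayes factors
are bounded by $0.01N$ and traces must be long enough for the intended
cutoff ($B_{10} > 100$ needs $N > 10^4$). Credible intervals are
highest-posterior-density (`hpd_interval()`): the shortest window of
$\lfloor 0.95 N \rfloor + 1$ sorted samples, which always contains just
over the nominal mass.

## The benchmark harness

`experiment_config()` + `run_grid()` loop generating models (inflow/outflow
x pulse/migration x the size grid), simulate each replicate, run the
requested arms, and record estimates, decisions (Bayes factor > 100;
p < 0.01 for the summary arms, the 1% convention of the benchmark), and
HPD intervals; `power_table()` and `estimation_table()` reduce to power,
bias, mean interval width and empirical coverage, with failed replicates
excluded from denominators and counted. For migration-generated data
analysed under the pulse model, the reference truth is $\varphi_0$ above
(the misspecified-mode expectation); full-likelihood migration inference is
out of scope, so the pulse engine is the single Bayesian arm.

## Problem sizes and numerical choices

The package's own test and acceptance runs use deliberately scaled-down
study sizes chosen once: MCMC chains of 200-1,000 burn-in plus
1,200-10,100 kept iterations (the longest where the Savage-Dickey cap must
exceed the decision threshold 100), 10-30 replicates per Monte Carlo
condition for stochastic checks, $10^4$-$10^5$ draws for closed-form
simulator checks, and 1,000 replicates for size calibration of the summary
tests (run on true gene trees and bulk-simulated site-pattern counts, which
share the scoring code with the user-facing paths). Degenerate inputs are
defined rather than crashed on: empty alignments have log-likelihood 0,
all-zero length vectors give a flagged degenerate mixture fit, empty
discordant classes are "insufficient" (not significant) in the mixture
test, and zero-width HPD intervals arise from constant traces.

## Known limitations

* Inference supports one introgression edge and quartet-scale trees;
  migration-model (MSC-M) likelihood inference is not implemented.
* JC only; no rate variation among sites or loci; no recombination within
  loci.
* The marginalisation of parent choices is exponential in the number of
  lineages crossing the introgression time, so many sequences per species
  from the recipient clade make the engine slow (and it refuses $k > 16$).
* Summary-test implementations are concrete variants chosen for
  testability and calibration; they are not line-for-line ports of any
  published tool, and power comparisons transfer to those tools only at
  the level of the statistics they share.
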