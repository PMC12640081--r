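#' Simulate a gene tree under the multispecies coalescent with gene flow
#'
#' Backward-in-time structured-coalescent simulation on a species network.
#' Within a population of size `theta` each lineage pair coalesces at rate
#' `2/theta` per unit of mutational time. Under `mode = "msci"`, every
#' lineage present in the recipient branch at the introgression time
#' independently reparents into the donor branch with probability `phi`
#' (choices are logged). Under `mode = "mscm"`, each lineage in the recipient
#' branch of a band jumps (backward in time) into the donor branch at rate
#' `4 M / theta_recipient`; jumps are logged. Randomness comes from R's RNG,
#' so results are reproducible under [set.seed()].
#'
#' @param net a [species_network]. `"msci"` requires no migration bands;
#'   `"mscm"` requires no introgression edge.
#' @param samples_per_species named integer vector (species label -> number
#'   of sampled sequences); species omitted get 0.
#' @param mode `"msci"`, `"mscm"` or `"none"` (plain MSC; the network must
#'   then carry no gene flow, or its gene-flow parameters are ignored at
#'   `phi = 0` / `M = 0` only if so specified -- see Details).
#' @return a `gene_tree`: a list with `phylo` (ultrametric [ape::phylo] with
#'   node ages in substitutions/site), `age`, `parent` (internal arrays),
#'   `tip_species`, `tip_individual`, `bits`/`crossed` (hybrid parent
#'   choices) and `n_jumps` plus a jump log for migration.
#' @export
simulate_gene_tree <- function(net, samples_per_species, mode = c("msci", "mscm")) {
  mode <- match.arg(mode)
  if (mode == "msci" && !is.null(net$migration))
    stop("msci simulation requires a network without migration bands")
  if (mode == "mscm" && !is.null(net$introgression))
    stop("mscm simulation requires a network without an introgression edge")
  tips <- tip_ids(net)
  sps <- net$labels[tips]
  cnt <- setNames(rep(0L, length(sps)), sps)
  if (is.null(names(samples_per_species)))
    stop("samples_per_species must be named by species label")
  if (!all(names(samples_per_species) %in% sps))
    stop("unknown species in samples_per_species")
  cnt[names(samples_per_species)] <- as.integer(samples_per_species)
  if (any(cnt < 0) || sum(cnt) < 1) stop("need at least one sampled lineage")
  tip_sp <- rep(tips[match(names(cnt), sps)], cnt)
  tip_ind <- unlist(lapply(cnt, seq_len), use.names = FALSE)
  sim <- cpp_sim_gene_tree(as_cpp_net(net), as.integer(tip_sp - 1L))
  labels <- paste0(net$labels[tip_sp], "^", tip_ind)
  gt <- list(parent = sim$parent, age = sim$age,
             tip_species = net$labels[tip_sp], tip_individual = tip_ind,
             tip_labels = labels, bits = sim$bits, crossed = sim$crossed,
             n_jumps = sim$n_jumps,
             jumps = data.frame(node = sim$jump_node + 1L,
                                time = sim$jump_time),
             phylo = build_phylo(sim$parent, sim$age, labels))
  class(gt) <- "gene_tree"
  gt
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("gene_tree:", length(x$tip_labels), "tips, root age",
      format(max(x$age)), "\n")
  invisible(x)
}

# build an ape phylo from 0-based parent pointers and node ages
build_phylo <- function(parent, age, tip_labels) {
  nn <- length(parent)
  nt <- (nn + 1L) / 2L
  if (nt == 1L) {
    return(structure(list(edge = matrix(integer(0), 0, 2),
                          tip.label = tip_labels, Nnode = 0L),
                     class = "phylo"))
  }
  # ape numbering: tips 1..nt, internals nt+1..nn with root first
  ints <- (nt + 1):nn                       # 0-based internal ids are nt..nn-1
  ord <- order(-age[ints])                  # root (max age) first
  newid <- integer(nn)
  newid[1:nt] <- 1:nt
  newid[ints[ord]] <- nt + seq_along(ints)
  p1 <- parent + 1L
  edge <- cbind(newid[p1[p1 > 0]], newid[which(p1 > 0)])
  len <- age[p1[p1 > 0]] - age[which(p1 > 0)]
  o <- order(edge[, 1], edge[, 2])
  structure(list(edge = edge[o, , drop = FALSE],
                 edge.length = len[o],
                 tip.label = tip_labels, Nnode = nt - 1L),
            class = "phylo")
}

#' Evolve a Jukes-Cantor alignment along a gene tree
#'
#' The root state is uniform on \{A,C,G,T\}; along a branch of length `d`
#' (substitutions/site) the probability of ending in each of the three other
#' states is `(1/4)(1 - exp(-4d/3))`.
#'
#' @param gene_tree a `gene_tree` from [simulate_gene_tree()].
#' @param n_sites number of sites (>= 0).
#' @param id locus id for the returned alignment.
#' @return a [locus_alignment].
#' @export
simulate_jc_alignment <- function(gene_tree, n_sites, id = 1L) {
  if (n_sites < 0) stop("n_sites must be nonnegative")
  m <- cpp_sim_jc(gene_tree$parent, gene_tree$age, as.integer(n_sites))
  bases <- c("A", "C", "G", "T")
  seqs <- apply(m, 1, function(r)
    paste(bases[r + 1L], collapse = ""))
  if (n_sites == 0) seqs <- rep("", nrow(m))
  names(seqs) <- gene_tree$tip_labels
  locus_alignment(id, seqs, gene_tree$tip_species, gene_tree$tip_individual)
}

#' Bulk Monte-Carlo gene-tree summaries
#'
#' Simulates many independent gene trees and returns, per replicate, the
#' rooted-triplet topology of the first three sampled lineages (1 = first
#' pair coalesces first, 2 = first/third, 3 = second/third), the gene-tree
#' root age and the number of migration jumps. Used for distribution-level
#' checks of the simulator against closed-form coalescent probabilities.
#'
#' @inheritParams simulate_gene_tree
#' @param reps number of independent gene trees.
#' @return a [tibble::tibble] with columns `topology`, `root_age`, `n_jumps`.
#' @export
simulate_mc_summary <- function(net, samples_per_species, reps,
                                mode = c("msci", "mscm")) {
  mode <- match.arg(mode)
  if (mode == "msci" && !is.null(net$migration))
    stop("msci simulation requires a network without migration bands")
  if (mode == "mscm" && !is.null(net$introgression))
    stop("mscm simulation requires a network without an introgression edge")
  tips <- tip_ids(net)
  sps <- net$labels[tips]
  cnt <- setNames(rep(0L, length(sps)), sps)
  cnt[names(samples_per_species)] <- as.integer(samples_per_species)
  tip_sp <- rep(tips[match(names(cnt), sps)], cnt)
  m <- cpp_sim_quartet_mc(as_cpp_net(net), as.integer(tip_sp - 1L),
                          as.integer(reps))
  tibble::as_tibble(as.data.frame(m))
}

#' Bulk site-pattern simulation for D-statistic calibration
#'
#' Simulates `reps` datasets of `L` loci (gene tree plus JC sites, one
#' sequence per listed species) and returns per-locus ABBA/BABA counts for
#' the ordered taxa (P1, P2, P3, O), for feeding [d_statistic_from_counts()]
#' at calibration scale.
#'
#' @inheritParams simulate_gene_tree
#' @param taxa character(4) species labels in (P1, P2, P3, O) order.
#' @param L loci per replicate dataset.
#' @param n_sites sites per locus.
#' @param reps number of replicate datasets.
#' @return integer matrix with `reps * L` rows (replicate-major) and columns
#'   `abba`, `baba`.
#' @export
simulate_dstat_counts <- function(net, taxa, L, n_sites, reps,
                                  mode = c("msci", "mscm")) {
  mode <- match.arg(mode)
  if (mode == "msci" && !is.null(net$migration))
    stop("msci simulation requires a network without migration bands")
  if (mode == "mscm" && !is.null(net$introgression))
    stop("mscm simulation requires a network without an introgression edge")
  tips <- tip_ids(net)
  tip_sp <- tips[match(taxa, net$labels[tips])]
  if (anyNA(tip_sp)) stop("unknown species label")
  cpp_sim_dstat_mc(as_cpp_net(net), as.integer(tip_sp - 1L), as.integer(L),
                   as.integer(n_sites), as.integer(reps))
}

#' Simulate a multilocus dataset
#'
#' `L` independent loci: a gene tree from the network under the given mode,
#' then a JC alignment of `n_sites` sites. Per-locus RNG substreams are
#' derived from the current RNG state by drawing one seed per locus up
#' front, so locus `i` is reproducible in isolation from its seed and the
#' whole dataset is reproducible under [set.seed()].
#'
#' @inheritParams simulate_gene_tree
#' @param L number of loci (>= 1).
#' @param n_sites sites per locus.
#' @return list with elements `trees` (list of `gene_tree`), `alignments`
#'   (list of [locus_alignment]) and `locus_seeds`.
#' @export
simulate_dataset <- function(net, samples_per_species, L, n_sites,
                             mode = c("msci", "mscm")) {
  mode <- match.arg(mode)
  if (L < 1) stop("L must be >= 1")
  locus_seeds <- sample.int(.Machine$integer.max - 1L, L)
  trees <- vector("list", L)
  alns <- vector("list", L)
  for (i in seq_len(L)) {
    set.seed(locus_seeds[i])
    trees[[i]] <- simulate_gene_tree(net, samples_per_species, mode)
    alns[[i]] <- simulate_jc_alignment(trees[[i]], n_sites, id = i)
  }
  list(trees = trees, alignments = alns, locus_seeds = locus_seeds)
}
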