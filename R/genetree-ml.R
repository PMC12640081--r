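#' Jukes-Cantor distance from a mismatch proportion
#'
#' @param p_mismatch observed proportion of mismatching sites, `0 <= p < 3/4`.
#' @return distance in expected substitutions/site,
#'   `-(3/4) log(1 - 4p/3)`.
#' @export
jc_distance <- function(p_mismatch) {
  if (any(p_mismatch < 0)) stop("mismatch proportion must be nonnegative")
  if (any(p_mismatch >= 0.75))
    stop("JC distance saturates at mismatch proportion >= 3/4")
  -0.75 * log(1 - 4 * p_mismatch / 3)
}

# pairwise mismatch proportion between two sequences over unambiguous sites
mismatch_p <- function(s1, s2) {
  a <- strsplit(s1, "", fixed = TRUE)[[1]]
  b <- strsplit(s2, "", fixed = TRUE)[[1]]
  use <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(use)) return(0)
  mean(a[use] != b[use])
}

#' Exhaustive maximum-likelihood quartet estimation under JC
#'
#' For each of the three unrooted quartet topologies, the five branch lengths
#' are optimised (bounded L-BFGS-B, multi-start from JC-distance-based and
#' flat initial lengths) against the Jukes-Cantor pruning likelihood; the
#' best topology and all three maximised log-likelihoods are returned.
#' Topologies whose maximised log-likelihoods are within `1e-9` of the best
#' are flagged as ties (invariant alignments give a three-way tie).
#'
#' @param aln a [locus_alignment] containing the four sequences.
#' @param taxa four sequence labels, order defining the topology encoding
#'   `12|34`, `13|24`, `14|23`.
#' @return list with `topology` (1, 2 or 3), `split` (e.g. `"A,B|C,O"`),
#'   `branch_lengths` (terminal 1-4 then internal), `loglik` (length 3),
#'   `tie` (logical).
#' @export
quartet_ml_jc <- function(aln, taxa) {
  if (length(taxa) != 4) stop("exactly four taxa required")
  pat <- aln_patterns(aln, labels = taxa)
  if (ncol(pat$mask) == 0) stop("alignment has no sites")
  seqs <- setNames(aln$seq, aln$labels)[taxa]
  d <- matrix(0, 4, 4)
  for (i in 1:3) for (j in (i + 1):4) {
    p <- min(mismatch_p(seqs[i], seqs[j]), 0.70)
    d[i, j] <- d[j, i] <- jc_distance(p)
  }
  fit_topo <- function(topo) {
    pr <- switch(topo, list(c(1, 2), c(3, 4)), list(c(1, 3), c(2, 4)),
                 list(c(1, 4), c(2, 3)))
    i <- pr[[1]][1]; j <- pr[[1]][2]; k <- pr[[2]][1]; l <- pr[[2]][2]
    internal0 <- max((d[i, k] + d[j, l] + d[i, l] + d[j, k]) / 4 -
                       (d[i, j] + d[k, l]) / 2, 1e-6)
    term <- numeric(4)
    term[c(i, j)] <- d[i, j] / 2
    term[c(k, l)] <- d[k, l] / 2
    start1 <- pmax(c(term, internal0), 1e-6)
    starts <- list(start1, rep(0.01, 5))
    best <- NULL
    for (s in starts) {
      o <- optim(s, function(b) -cpp_quartet_loglik(pat$mask, pat$wt, topo, b),
                 method = "L-BFGS-B", lower = 1e-9, upper = 5,
                 control = list(factr = 1e6))
      if (is.null(best) || o$value < best$value) best <- o
    }
    best
  }
  fits <- lapply(1:3, fit_topo)
  ll <- -vapply(fits, `[[`, numeric(1), "value")
  topo <- which.max(ll)
  tie <- sum(ll >= max(ll) - 1e-9) > 1
  splits <- c(paste0(taxa[1], ",", taxa[2], "|", taxa[3], ",", taxa[4]),
              paste0(taxa[1], ",", taxa[3], "|", taxa[2], ",", taxa[4]),
              paste0(taxa[1], ",", taxa[4], "|", taxa[2], ",", taxa[3]))
  list(topology = topo, split = splits[topo],
       branch_lengths = fits[[topo]]$par, loglik = ll, tie = tie)
}

#' Classify a rooted triplet from a gene tree
#'
#' Restricts the tree to the three focal tips plus the outgroup, roots at the
#' outgroup, and classifies the rooted triplet: `con` if the declared sister
#' pair is monophyletic, `dis2` if the hypothesised gene-flow pair groups
#' together (so an excess of `dis2` indicates gene flow in that pair), `dis1`
#' for the remaining alternative. The internal branch length is the length of
#' the branch separating the triplet's cherry from the third tip
#' (substitutions/site).
#'
#' @param tree an [ape::phylo] containing the focal tips and outgroup.
#' @param sister_pair character(2), the species-tree sister pair.
#' @param outgroup outgroup tip label used for rooting.
#' @param flow_pair character(2), the hypothesised gene-flow pair defining
#'   class `dis2`; defaults to the second sister with the third tip.
#' @return list with `class` (`"con"`, `"dis1"`, `"dis2"` or `NA` for an
#'   unresolved triplet), `internal_length`, `tie` (zero or unresolved
#'   internal branch).
#' @export
classify_triplet <- function(tree, sister_pair, outgroup, flow_pair = NULL) {
  tips <- tree$tip.label
  if (!all(c(sister_pair, outgroup) %in% tips))
    stop("tree is missing focal or outgroup tips")
  ingroup3 <- setdiff(tips, outgroup)
  if (length(ingroup3) != 3) {
    # general tree: caller must pass a tree restricted to 3 ingroup tips + outgroup
    stop("tree must contain exactly three ingroup tips plus the outgroup")
  }
  third <- setdiff(ingroup3, sister_pair)
  if (length(third) != 1) stop("sister pair not found among ingroup tips")
  if (is.null(flow_pair)) flow_pair <- c(sister_pair[2], third)
  tr <- ape::unroot(tree)
  # quartet split: the two non-outgroup tips attached to the same internal node
  adj <- tr$edge[match(seq_along(tr$tip.label), tr$edge[, 2]), 1]
  names(adj) <- tr$tip.label
  if (tr$Nnode < 2 || length(unique(adj)) < 2) {
    return(list(class = NA_character_, internal_length = 0, tie = TRUE))
  }
  onode <- adj[[outgroup]]
  cherry <- names(adj)[adj != onode & names(adj) != outgroup]
  if (length(cherry) != 2) { # outgroup shares a node with one ingroup tip
    cherry <- names(adj)[adj != onode]
  }
  if (length(cherry) != 2)
    return(list(class = NA_character_, internal_length = 0, tie = TRUE))
  internal_edges <- which(tr$edge[, 2] > length(tr$tip.label))
  ilen <- sum(tr$edge.length[internal_edges])
  cls <- if (setequal(cherry, sister_pair)) "con"
         else if (setequal(cherry, flow_pair)) "dis2"
         else "dis1"
  list(class = cls, internal_length = ilen, tie = ilen <= 0)
}

#' Per-locus triplet classes for a multilocus dataset
#'
#' For each locus, one sequence per species is chosen at random (seeded by
#' the caller's RNG state), the quartet gene tree is estimated by exhaustive
#' ML under JC ([quartet_ml_jc()]), and the rooted triplet of the three
#' ingroup species is classified. Loci whose best topology is tied are
#' excluded from the counts (class `NA`).
#'
#' @param alignments list of [locus_alignment] objects.
#' @param taxa character(4): sister pair, third ingroup species, outgroup,
#'   in the order `c(sister1, sister2, third, outgroup)`.
#' @param flow_pair hypothesised gene-flow pair (default: second sister and
#'   third species).
#' @param use_trees optional list of true gene trees (`gene_tree` or
#'   [ape::phylo]); if supplied, classification uses these instead of ML
#'   estimation (one random individual per species).
#' @return a [tibble::tibble] with columns `locus`, `class`,
#'   `internal_length`, `tie`.
#' @export
infer_triplet_classes <- function(alignments, taxa, flow_pair = NULL,
                                  use_trees = NULL) {
  stopifnot(length(taxa) == 4)
  sister <- taxa[1:2]; third <- taxa[3]; outg <- taxa[4]
  if (is.null(flow_pair)) flow_pair <- c(taxa[2], taxa[3])
  n <- if (is.null(use_trees)) length(alignments) else length(use_trees)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (is.null(use_trees)) {
      a <- alignments[[i]]
      sel <- vapply(taxa, function(s) {
        cand <- which(a$species == s)
        if (!length(cand)) stop("species ", s, " missing from locus ", i)
        a$labels[cand[sample.int(length(cand), 1)]]
      }, character(1))
      fit <- quartet_ml_jc(a, unname(sel))
      if (fit$tie) {
        rows[[i]] <- list(class = NA_character_, internal_length = NA_real_,
                          tie = TRUE)
      } else {
        # topology 1: sisters together (con); 2: cherry = (sister1, third);
        # 3: sister1 with outgroup, so cherry = (sister2, third)
        cls <- switch(fit$topology,
                      "con",
                      if (setequal(c(taxa[1], taxa[3]), flow_pair)) "dis2" else "dis1",
                      if (setequal(c(taxa[2], taxa[3]), flow_pair)) "dis2" else "dis1")
        rows[[i]] <- list(class = cls,
                          internal_length = fit$branch_lengths[5],
                          tie = FALSE)
      }
    } else {
      tr <- use_trees[[i]]
      if (inherits(tr, "gene_tree")) {
        sel <- vapply(taxa, function(s) {
          cand <- which(tr$tip_species == s)
          if (!length(cand)) stop("species ", s, " missing from tree ", i)
          tr$tip_labels[cand[sample.int(length(cand), 1)]]
        }, character(1))
        ph <- ape::keep.tip(tr$phylo, unname(sel))
        # relabel to species names for classification
        ph$tip.label <- taxa[match(ph$tip.label, sel)]
      } else {
        ph <- ape::keep.tip(tr, taxa)
      }
      cl <- classify_triplet(ph, sister, outg, flow_pair)
      rows[[i]] <- list(class = cl$class, internal_length = cl$internal_length,
                        tie = cl$tie)
    }
  }
  tibble::tibble(
    locus = seq_len(n),
    class = vapply(rows, `[[`, character(1), "class"),
    internal_length = vapply(rows, `[[`, numeric(1), "internal_length"),
    tie = vapply(rows, `[[`, logical(1), "tie"))
}
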