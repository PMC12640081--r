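#' Triplet topology counts with per-class internal branch lengths
#'
#' @param classes tibble from [infer_triplet_classes()] (columns `class`,
#'   `internal_length`); loci with class `NA` (ties) are dropped.
#' @return object of class `triplet_counts` with counts `c_con`, `c_dis1`,
#'   `c_dis2` and length vectors `len_con`, `len_dis1`, `len_dis2`.
#' @export
triplet_counts <- function(classes) {
  keep <- !is.na(classes$class)
  cl <- classes$class[keep]
  len <- classes$internal_length[keep]
  out <- list(c_con = sum(cl == "con"),
              c_dis1 = sum(cl == "dis1"),
              c_dis2 = sum(cl == "dis2"),
              len_con = len[cl == "con"],
              len_dis1 = len[cl == "dis1"],
              len_dis2 = len[cl == "dis2"],
              n_excluded = sum(!keep))
  class(out) <- "triplet_counts"
  out
}

#' @export
print.triplet_counts <- function(x, ...) {
  cat("triplet_counts: con =", x$c_con, ", dis1 =", x$c_dis1,
      ", dis2 =", x$c_dis2,
      if (x$n_excluded) paste0(" (", x$n_excluded, " ties excluded)"), "\n")
  invisible(x)
}

#' Discordant-count test (DCT) of gene flow
#'
#' Estimates the introgression probability from gene-tree topology counts as
#' `phi_hat = (c_dis2 - c_dis1) / (c_con + c_dis1 + c_dis2)`, truncated to 0
#' when `c_dis1 > c_dis2` (under incomplete lineage sorting alone the two
#' discordant classes are equiprobable, so only an excess of the
#' gene-flow-concordant class counts as signal). Significance is an exact
#' two-sided binomial test of `c_dis2` against `c_dis1` with success
#' probability 1/2.
#'
#' @param counts a [triplet_counts] object.
#' @return list with `phi_hat`, `p_value`, and the counts used.
#' @export
dct_test <- function(counts) {
  tot <- counts$c_con + counts$c_dis1 + counts$c_dis2
  if (tot < 1) stop("dct_test requires at least one classified gene tree")
  phi_hat <- (counts$c_dis2 - counts$c_dis1) / tot
  if (counts$c_dis1 > counts$c_dis2) phi_hat <- 0
  nd <- counts$c_dis1 + counts$c_dis2
  p <- if (nd == 0) 1 else
    binom.test(counts$c_dis2, nd, p = 0.5, alternative = "two.sided")$p.value
  list(phi_hat = phi_hat, p_value = p,
       c_con = counts$c_con, c_dis1 = counts$c_dis1, c_dis2 = counts$c_dis2)
}

#' Branch-length test (BLT) of gene flow
#'
#' Two-sample Mann-Whitney U test contrasting the internal branch lengths of
#' the two discordant triplet classes. Under incomplete lineage sorting alone
#' the two classes are exchangeable, so any location difference between them
#' indicates gene flow. The reported direction is the class with the smaller
#' mean (gene flow predicts more recent coalescence in the introgressed
#' class).
#'
#' @param lengths_dis1,lengths_dis2 numeric vectors of internal branch
#'   lengths (substitutions/site) for the two discordant classes.
#' @return list with `p_value`, `direction` (`"dis1"`, `"dis2"` or `NA`),
#'   and the two class means.
#' @export
blt_test <- function(lengths_dis1, lengths_dis2) {
  if (!length(lengths_dis1) || !length(lengths_dis2))
    stop("both discordant classes must be nonempty")
  m1 <- mean(lengths_dis1); m2 <- mean(lengths_dis2)
  p <- suppressWarnings(
    wilcox.test(lengths_dis1, lengths_dis2, exact = FALSE)$p.value)
  if (is.na(p)) p <- 1
  direction <- if (m1 == m2) NA_character_ else if (m2 < m1) "dis2" else "dis1"
  list(p_value = p, direction = direction, mean_dis1 = m1, mean_dis2 = m2)
}

#' ABBA-BABA D-statistic with block jackknife
#'
#' Counts ABBA and BABA site patterns over all loci for one sequence from
#' each of the ordered taxa (P1, P2, P3, O), using the outgroup allele as
#' ancestral; sites with more than two states, missing data, or a
#' non-polarisable pattern are skipped. `D = (nABBA - nBABA)/(nABBA + nBABA)`;
#' significance comes from a delete-one block jackknife with loci as blocks
#' applied to the numerator `nABBA - nBABA` (the denominator is positive, so
#' testing `D = 0` is equivalent, and the count-difference jackknife stays
#' calibrated when per-locus informative-site counts are sparse), giving a
#' `z` score and a two-sided normal p-value.
#'
#' @param alignments list of [locus_alignment] objects.
#' @param taxa character(4) of species labels in order (P1, P2, P3, O).
#' @param labels optional character(4): the sequence label to use for each
#'   taxon; defaults to one random sequence per species (caller's RNG).
#' @return list with `D`, `z`, `p_value`, `n_abba`, `n_baba`, `n_blocks`.
#' @export
d_statistic <- function(alignments, taxa, labels = NULL) {
  stopifnot(length(taxa) == 4)
  counts <- vapply(seq_along(alignments), function(i) {
    a <- alignments[[i]]
    lab <- if (!is.null(labels)) labels else
      vapply(taxa, function(s) {
        cand <- which(a$species == s)
        if (!length(cand)) stop("species ", s, " missing from locus ", i)
        a$labels[cand[sample.int(length(cand), 1)]]
      }, character(1))
    m <- do.call(rbind, strsplit(setNames(a$seq, a$labels)[lab], "", fixed = TRUE))
    ok <- colSums(matrix(m %in% c("A", "C", "G", "T"), nrow = 4)) == 4
    m <- m[, ok, drop = FALSE]
    abba <- sum(m[1, ] == m[4, ] & m[2, ] == m[3, ] & m[1, ] != m[2, ])
    baba <- sum(m[2, ] == m[4, ] & m[1, ] == m[3, ] & m[1, ] != m[2, ])
    c(abba, baba)
  }, numeric(2))
  d_statistic_from_counts(counts[1, ], counts[2, ])
}

#' @param abba,baba per-block (per-locus) ABBA and BABA counts.
#' @rdname d_statistic
#' @export
d_statistic_from_counts <- function(abba, baba) {
  A <- sum(abba); B <- sum(baba)
  if (A + B == 0) stop("no informative (ABBA/BABA) sites")
  D <- (A - B) / (A + B)
  d <- abba - baba
  nb <- length(d)
  v <- (nb - 1) / nb * sum((d - mean(d))^2)
  z <- if (v > 0) (A - B) / sqrt(v) else if (D == 0) 0 else sign(D) * Inf
  list(D = D, z = z, p_value = 2 * pnorm(-abs(z)),
       n_abba = A, n_baba = B, n_blocks = nb)
}
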