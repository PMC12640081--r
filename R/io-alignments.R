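#' Construct a single-locus alignment
#'
#' @param id locus identifier.
#' @param seqs named character vector of nucleotide strings (names are the
#'   sequence labels), all of equal length; IUPAC ambiguity codes and gaps
#'   are accepted and treated as missing data under the JC likelihood.
#' @param species character vector, species of each sequence.
#' @param individual character vector, individual of each sequence
#'   (defaults to the label).
#' @return an object of class `locus_alignment` with fields `id`, `labels`,
#'   `species`, `individual`, `seq` and `n` (sites).
#' @export
locus_alignment <- function(id, seqs, species, individual = names(seqs)) {
  labels <- names(seqs)
  if (is.null(labels) || any(!nzchar(labels))) stop("sequences must be named")
  if (anyDuplicated(labels)) stop("labels must be unique within a locus")
  n <- unique(nchar(seqs))
  if (length(n) > 1)
    stop(sprintf("locus %s: ragged alignment", as.character(id)))
  if (length(n) == 0) n <- 0L
  stopifnot(length(species) == length(seqs))
  structure(list(id = id, labels = unname(labels),
                 species = as.character(species),
                 individual = as.character(individual),
                 seq = toupper(unname(seqs)), n = as.integer(n)),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("locus_alignment", x$id, ":", length(x$seq), "sequences x", x$n,
      "sites\n")
  invisible(x)
}

#' Read a species-individual map (Imap)
#'
#' Two whitespace-delimited columns: individual label, species.
#' @param path file path.
#' @return named character vector mapping individual to species.
#' @export
read_imap <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("individual", "species"))
  setNames(tab$species, tab$individual)
}

#' @param imap named character vector (individual -> species).
#' @rdname read_imap
#' @export
write_imap <- function(imap, path) {
  writeLines(paste(names(imap), unname(imap)), path)
  invisible(path)
}

# resolve a sequence label to (species, individual) via imap, honouring the
# "individual^..." / "...^individual" conventions used by multilocus tools
resolve_species <- function(labels, imap) {
  ind <- labels
  # a full label present in the imap wins; otherwise try the caret fields
  for (i in which(!(labels %in% names(imap)) &
                    grepl("^", labels, fixed = TRUE))) {
    parts <- strsplit(labels[i], "^", fixed = TRUE)[[1]]
    hit <- parts[parts %in% names(imap)]
    ind[i] <- if (length(hit)) hit[1] else parts[length(parts)]
  }
  sp <- unname(imap[ind])
  if (anyNA(sp))
    stop("unknown species for label(s): ",
         paste(labels[is.na(sp)], collapse = ", "))
  list(species = sp, individual = ind)
}

#' Read a multilocus sequence file
#'
#' Supports the multilocus sequential PHYLIP dialect (locus blocks headed by
#' `"<nseq> <nsites>"`, blank-line separated) and per-locus FASTA files.
#' Labels are resolved to species via the Imap, honouring the
#' `label^individual` convention. The reader accepts LF or CRLF line endings
#' and leading whitespace.
#'
#' @param path a single PHYLIP file, or a character vector of FASTA files
#'   (one per locus).
#' @param format `"phylip-bpp"` or `"fasta-per-locus"`.
#' @param imap named character vector mapping individuals to species.
#' @return list of [locus_alignment] objects in file order.
#' @export
read_multilocus <- function(path, format = c("phylip-bpp", "fasta-per-locus"),
                            imap) {
  format <- match.arg(format)
  if (format == "fasta-per-locus") {
    out <- lapply(seq_along(path), function(k) {
      dna <- ape::read.FASTA(path[k])
      seqs <- vapply(as.character(dna), function(s)
        paste(toupper(s), collapse = ""), character(1))
      r <- resolve_species(names(seqs), imap)
      locus_alignment(k, seqs, r$species, r$individual)
    })
    return(out)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- sub("^[ \t]+", "", lines)
  out <- list()
  i <- 1L; locus <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    hdr <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(hdr) < 2 || anyNA(suppressWarnings(as.integer(hdr[1:2]))))
      stop(sprintf("locus %d: malformed block header '%s'", locus + 1L, lines[i]))
    ns <- as.integer(hdr[1]); ls <- as.integer(hdr[2])
    i <- i + 1L; locus <- locus + 1L
    seqs <- character(0)
    for (s in seq_len(ns)) {
      while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
      if (i > length(lines))
        stop(sprintf("locus %d: truncated block", locus))
      toks <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
      lab <- toks[1]
      sq <- paste(toks[-1], collapse = "")
      i <- i + 1L
      # continuation lines: bare sequence until the declared length is met
      while (nchar(sq) < ls && i <= length(lines) && nzchar(trimws(lines[i]))) {
        sq <- paste0(sq, gsub("[ \t]", "", lines[i]))
        i <- i + 1L
      }
      if (nchar(sq) != ls)
        stop(sprintf("locus %d: ragged (sequence %s has %d sites, expected %d)",
                     locus, lab, nchar(sq), ls))
      seqs[lab] <- sq
    }
    r <- resolve_species(names(seqs), imap)
    out[[locus]] <- locus_alignment(locus, seqs, r$species, r$individual)
  }
  out
}

#' Write alignments as multilocus sequential PHYLIP (bpp dialect)
#'
#' @param alns list of [locus_alignment] objects.
#' @param path output file.
#' @export
write_multilocus_phylip <- function(alns, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (a in alns) {
    writeLines(paste(length(a$seq), a$n), con)
    writeLines(paste0(format(a$labels, width = max(nchar(a$labels)) + 2),
                      a$seq), con)
    writeLines("", con)
  }
  invisible(path)
}

# --- internal: pattern compression ------------------------------------------

# IUPAC nucleotide -> 4-bit mask (A=1, C=2, G=4, T=8); gaps/unknown = 15
iupac_mask <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L, R = 5L, Y = 10L,
                S = 6L, W = 9L, K = 12L, M = 3L, B = 14L, D = 13L, H = 11L,
                V = 7L, N = 15L, `-` = 15L, `?` = 15L, X = 15L)

# compress a locus alignment into site-pattern masks and weights, rows in
# the order of `labels`
aln_patterns <- function(aln, labels = aln$labels) {
  idx <- match(labels, aln$labels)
  if (anyNA(idx)) stop("alignment is missing sequences: ",
                       paste(labels[is.na(idx)], collapse = ", "))
  if (aln$n == 0)
    return(list(mask = matrix(integer(0), nrow = length(labels), ncol = 0),
                wt = numeric(0)))
  m <- do.call(rbind, strsplit(aln$seq[idx], "", fixed = TRUE))
  key <- apply(m, 2, paste, collapse = "")
  tab <- table(key)
  pats <- names(tab)
  chmat <- do.call(cbind, strsplit(pats, "", fixed = TRUE))
  msk <- iupac_mask[chmat]
  if (anyNA(msk)) stop("unknown nucleotide code in alignment")
  mask <- matrix(as.integer(msk), nrow = length(labels))
  list(mask = mask, wt = as.numeric(tab))
}
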