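#' Parse a Newick tree string
#'
#' Thin wrapper around [ape::read.tree()] preceded by a validation pass that
#' reports the character offset of structural problems (unbalanced
#' parentheses, missing terminating semicolon), which the underlying parser
#' does not.
#'
#' @param text a single Newick statement ending in `";"`.
#' @return an [ape::phylo] tree.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("newick parse error: unmatched ')' at offset %d", i))
    }
  }
  if (depth > 0L)
    stop(sprintf("newick parse error: missing ')' at offset %d",
                 length(chars) + 1L))
  if (length(chars) == 0L || chars[length(chars)] != ";")
    stop(sprintf("newick parse error: missing ';' at offset %d",
                 length(chars) + 1L))
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr))
    stop("newick parse error: malformed tree statement")
  tr
}

#' Write a tree as Newick with fixed-precision branch lengths
#'
#' Deterministic writer preserving child order; branch lengths are printed
#' with exactly `precision` digits after the decimal point (zero-length
#' branches are emitted, not elided; `precision = 0` gives integers).
#'
#' @param tree an [ape::phylo] tree.
#' @param precision number of decimal digits for branch lengths.
#' @return a single Newick string ending in `";"`.
#' @export
write_newick <- function(tree, precision = 6L) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt <- function(x) sprintf(paste0("%.", precision, "f"), x)
  rec <- function(node) {
    es <- kids[[as.character(node)]]
    if (is.null(es)) return(tree$tip.label[node])
    parts <- vapply(es, function(e) {
      child <- tree$edge[e, 2]
      s <- rec(child)
      if (!is.null(tree$edge.length))
        s <- paste0(s, ":", fmt(tree$edge.length[e]))
      s
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(root), ";")
}

#' Read gene trees from a file, one Newick statement per line
#' @param path file path.
#' @return a list of [ape::phylo] trees.
#' @export
read_gene_trees <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lapply(lines[nzchar(lines)], parse_newick)
}

#' Write gene trees to a file, one Newick statement per line
#' @param trees list of [ape::phylo] trees.
#' @param path file path.
#' @param precision decimal digits for branch lengths.
#' @export
write_gene_trees <- function(trees, path, precision = 6L) {
  writeLines(vapply(trees, write_newick, character(1),
                    precision = precision), path)
  invisible(path)
}
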