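#' Construct a species network
#'
#' A species network is a rooted species tree with node ages `tau`, one
#' population-size parameter `theta` per branch (the root node's `theta` is
#' the size of the ancestral population above the root), at most one pulse
#' introgression edge (MSC-I) and zero or more directed migration bands
#' (MSC-M). All times and sizes are in expected substitutions per site.
#'
#' @param parent integer vector over network nodes giving each node's parent
#'   index (`NA` for the root). Tips must come first and have age 0.
#' @param age numeric node ages; strictly decreasing from root to tips.
#' @param labels character node labels; tip labels are the species names.
#' @param theta per-node population size of the branch above the node
#'   (root entry = root population), all positive.
#' @param introgression `NULL`, or `list(donor=, recipient=, tau=, phi=)`
#'   naming the species-tree nodes whose parent branches exchange migrants in
#'   a single pulse at time `tau` (backward in time a lineage in the
#'   recipient branch reparents into the donor branch with probability `phi`).
#' @param migration `NULL`, or a data.frame with columns `donor`, `recipient`,
#'   `M` and optional `t_lo`, `t_hi`; each row is a band with rate `M`
#'   migrants per generation active over the temporal overlap of the two
#'   branches (optionally narrowed to `[t_lo, t_hi]`).
#' @return an object of class `species_network`.
#' @export
species_network <- function(parent, age, labels, theta,
                            introgression = NULL, migration = NULL) {
  n <- length(parent)
  stopifnot(length(age) == n, length(labels) == n, length(theta) == n)
  if (sum(is.na(parent)) != 1L) stop("network must have exactly one root")
  is_tip <- !(seq_len(n) %in% parent[!is.na(parent)])
  if (any(duplicated(labels[is_tip]))) stop("tip labels must be unique")
  if (any(theta <= 0)) stop("theta must be positive")
  if (any(age < 0)) stop("ages must be nonnegative")
  for (v in seq_len(n)) {
    if (!is.na(parent[v]) && age[parent[v]] <= age[v])
      stop("node ages must strictly decrease from root to tips")
  }
  net <- structure(list(parent = parent, age = age, labels = labels,
                        theta = theta, introgression = NULL, migration = NULL),
                   class = "species_network")
  if (!is.null(introgression)) {
    don <- match(introgression$donor, labels)
    rec <- match(introgression$recipient, labels)
    if (is.na(don) || is.na(rec)) stop("unknown donor/recipient label")
    th <- introgression$tau
    for (v in c(don, rec)) {
      hi <- if (is.na(parent[v])) Inf else age[parent[v]]
      if (!(th > age[v] && th < hi))
        stop("introgression time must lie within both donor and recipient branch intervals")
    }
    phi <- introgression$phi
    if (phi < 0 || phi > 1) stop("phi must be in [0, 1]")
    net$introgression <- list(donor = don, recipient = rec,
                              tau = th, phi = phi)
  }
  if (!is.null(migration)) {
    migration <- as.data.frame(migration)
    if (!is.null(net$introgression))
      stop("a network carries either an introgression edge or migration bands, not both")
    di <- match(migration$donor, labels); ri <- match(migration$recipient, labels)
    if (anyNA(di) || anyNA(ri)) stop("unknown band label")
    if (any(migration$M < 0)) stop("migration rates must be nonnegative")
    for (k in seq_len(nrow(migration))) {
      lo_d <- age[di[k]]; hi_d <- if (is.na(parent[di[k]])) Inf else age[parent[di[k]]]
      lo_r <- age[ri[k]]; hi_r <- if (is.na(parent[ri[k]])) Inf else age[parent[ri[k]]]
      if (max(lo_d, lo_r) >= min(hi_d, hi_r))
        stop("migration band connects branches whose time intervals do not overlap")
    }
    net$migration <- data.frame(
      donor = di, recipient = ri, M = migration$M,
      t_lo = if ("t_lo" %in% names(migration)) migration$t_lo else NA_real_,
      t_hi = if ("t_hi" %in% names(migration)) migration$t_hi else NA_real_)
  }
  net
}

#' Quartet gene-flow models
#'
#' Builds the four-species network (((A,B)T, C)S, O)R with divergence times
#' `tauR = 3 theta`, `tauS = 2 theta`, `tauT = theta` and gene flow between
#' the nonsister lineages B and C: inflow (C to B) or outflow (B to C), as a
#' pulse at `tau = theta/2` with probability `phi` (MSC-I) or as a continuous
#' band at rate `M` migrants/generation (MSC-M).
#'
#' @param theta population size parameter shared by all branches.
#' @param direction `"inflow"` (C to B) or `"outflow"` (B to C).
#' @param mode `"msci"` (pulse) or `"mscm"` (continuous band), or `"none"`
#'   for the no-gene-flow null quartet.
#' @param phi introgression probability (MSC-I).
#' @param M migration rate in migrants/generation (MSC-M).
#' @return a `species_network`.
#' @export
quartet_network <- function(theta = 0.01,
                            direction = c("inflow", "outflow"),
                            mode = c("msci", "mscm", "none"),
                            phi = 0.2, M = 0.1) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  # nodes: 1 A, 2 B, 3 C, 4 O, 5 T=(A,B), 6 S=(T,C), 7 R=(S,O)
  parent <- c(5L, 5L, 6L, 7L, 6L, 7L, NA)
  age <- c(0, 0, 0, 0, theta, 2 * theta, 3 * theta)
  labels <- c("A", "B", "C", "O", "T", "S", "R")
  th <- rep(theta, 7)
  donor <- if (direction == "inflow") "C" else "B"
  recip <- if (direction == "inflow") "B" else "C"
  intro <- if (mode == "msci")
    list(donor = donor, recipient = recip, tau = theta / 2, phi = phi) else NULL
  mig <- if (mode == "mscm")
    data.frame(donor = donor, recipient = recip, M = M) else NULL
  species_network(parent, age, labels, th, introgression = intro,
                  migration = mig)
}

#' @export
print.species_network <- function(x, ...) {
  ntip <- sum(!(seq_along(x$parent) %in% x$parent))
  cat("species_network:", ntip, "species, root age",
      format(max(x$age)), "\n")
  if (!is.null(x$introgression))
    cat("  introgression:", x$labels[x$introgression$donor], "->",
        x$labels[x$introgression$recipient], "at tau =",
        format(x$introgression$tau), ", phi =", x$introgression$phi, "\n")
  if (!is.null(x$migration))
    for (k in seq_len(nrow(x$migration)))
      cat("  migration:", x$labels[x$migration$donor[k]], "->",
          x$labels[x$migration$recipient[k]], "M =", x$migration$M[k], "\n")
  invisible(x)
}

# convert to the 0-based list the C++ engines consume
as_cpp_net <- function(net) {
  p <- net$parent; p[is.na(p)] <- 0L
  out <- list(parent = as.integer(p - 1L),
              age = as.numeric(net$age),
              theta = as.numeric(net$theta),
              has_hybrid = !is.null(net$introgression))
  if (out$has_hybrid) {
    out$recipient <- as.integer(net$introgression$recipient - 1L)
    out$donor <- as.integer(net$introgression$donor - 1L)
    out$tau_h <- net$introgression$tau
    out$phi <- net$introgression$phi
  }
  if (!is.null(net$migration)) {
    m <- net$migration
    out$bands <- cbind(m$donor - 1L, m$recipient - 1L, m$M,
                       ifelse(is.na(m$t_lo), -Inf, m$t_lo),
                       ifelse(is.na(m$t_hi), Inf, m$t_hi))
  }
  out
}

tip_ids <- function(net) which(!(seq_along(net$parent) %in% net$parent))

#' Expected cumulative introgression probability of a migration band
#'
#' The total probability that a lineage in the recipient population traces
#' its ancestry through the donor during a migration episode of duration
#' `delta_tau` at rate `M` migrants per generation:
#' `1 - exp(-4 M delta_tau / theta)`, with `theta` the recipient population
#' size. This is the introgression probability a pulse (MSC-I) model is
#' expected to recover when the true history is continuous migration.
#'
#' @param M migration rate, expected migrants per generation (>= 0).
#' @param delta_tau duration of the band, substitutions/site (>= 0).
#' @param theta recipient population size, substitutions/site (> 0).
#' @return probability in [0, 1).
#' @examples
#' expected_cumulative_introgression(0.1, 0.01, 0.01) # 1 - exp(-0.4)
#' @export
expected_cumulative_introgression <- function(M, delta_tau, theta) {
  if (any(theta <= 0)) stop("theta must be positive")
  if (any(M < 0) || any(delta_tau < 0)) stop("M and delta_tau must be nonnegative")
  -expm1(-4 * M * delta_tau / theta)
}

#' Read or write a species network as a YAML config
#'
#' The config mirrors [species_network()]: `labels`, `parent` (1-based, 0 for
#' the root), `age`, `theta`, and optional `introgression` / `migration`
#' blocks.
#'
#' @param path file path.
#' @return `read_network_config()` returns a `species_network`.
#' @export
read_network_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  parent <- as.integer(cfg$parent); parent[parent == 0L] <- NA_integer_
  mig <- if (!is.null(cfg$migration)) do.call(rbind.data.frame, cfg$migration)
  species_network(parent, as.numeric(cfg$age), as.character(cfg$labels),
                  as.numeric(cfg$theta),
                  introgression = cfg$introgression, migration = mig)
}

#' @param net a `species_network`.
#' @rdname read_network_config
#' @export
write_network_config <- function(net, path) {
  p <- net$parent; p[is.na(p)] <- 0L
  cfg <- list(labels = net$labels, parent = as.integer(p),
              age = net$age, theta = net$theta)
  if (!is.null(net$introgression)) {
    i <- net$introgression
    cfg$introgression <- list(donor = net$labels[i$donor],
                              recipient = net$labels[i$recipient],
                              tau = i$tau, phi = i$phi)
  }
  if (!is.null(net$migration)) {
    m <- net$migration
    cfg$migration <- lapply(seq_len(nrow(m)), function(k)
      list(donor = net$labels[m$donor[k]], recipient = net$labels[m$recipient[k]],
           M = m$M[k]))
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}
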