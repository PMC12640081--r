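#' Configure a simulation-analysis benchmark
#'
#' @param model generating model: `"inflow-I"`, `"outflow-I"` (pulse
#'   introgression), `"inflow-M"`, `"outflow-M"` (continuous migration), or
#'   `"null"` (no gene flow).
#' @param arms analysis arms, subset of
#'   `c("bayes", "dct", "blt", "quibl", "dstat")`.
#' @param L,S,n_sites,theta data-size grid vectors: loci, sequences per
#'   species, sites per locus, population size.
#' @param phi,M generating pulse probability / migration rate.
#' @param replicates replicate datasets per grid cell.
#' @param alpha significance level for the summary tests (default 0.01, the
#'   level at which power is tabulated).
#' @param bf_cutoff Bayes-factor threshold for the Bayesian test (default 100).
#' @param mcmc list of [run_mcmc()] schedule overrides for the Bayesian arm.
#' @param use_true_trees classify triplets from the true simulated gene trees
#'   instead of re-estimating them by quartet ML (fast; default FALSE).
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(model = "inflow-I",
                              arms = c("dct", "blt", "quibl", "dstat"),
                              L = 250, S = 2, n_sites = 250, theta = 0.01,
                              phi = 0.2, M = 0.1,
                              replicates = 10, alpha = 0.01, bf_cutoff = 100,
                              mcmc = list(), use_true_trees = FALSE) {
  stopifnot(replicates >= 1, length(L) >= 1,
            all(arms %in% c("bayes", "dct", "blt", "quibl", "dstat")),
            model %in% c("inflow-I", "outflow-I", "inflow-M", "outflow-M", "null"))
  structure(list(model = model, arms = arms, L = L, S = S, n_sites = n_sites,
                 theta = theta, phi = phi, M = M, replicates = replicates,
                 alpha = alpha, bf_cutoff = bf_cutoff, mcmc = mcmc,
                 use_true_trees = use_true_trees),
            class = "experiment_config")
}

config_network <- function(model, theta, phi, M) {
  switch(model,
         "inflow-I"  = quartet_network(theta, "inflow", "msci", phi = phi),
         "outflow-I" = quartet_network(theta, "outflow", "msci", phi = phi),
         "inflow-M"  = quartet_network(theta, "inflow", "mscm", M = M),
         "outflow-M" = quartet_network(theta, "outflow", "mscm", M = M),
         "null"      = quartet_network(theta, "inflow", "none"))
}

# true gene-flow rate on the introgression-probability scale: phi for the
# pulse models, the expected cumulative introgression probability (eq. of
# the band overlap) for the migration models, 0 for the null
config_truth <- function(model, theta, phi, M) {
  switch(model,
         "inflow-I" = phi, "outflow-I" = phi,
         "inflow-M" = expected_cumulative_introgression(M, theta, theta),
         "outflow-M" = expected_cumulative_introgression(M, theta, theta),
         "null" = 0)
}

#' Run a benchmark grid
#'
#' For every grid cell and replicate: simulate a dataset from the generating
#' model, run each analysis arm, and record its estimate and test decision
#' (Bayes factor > `bf_cutoff` for the Bayesian arm, p-value < `alpha` or the
#' mixture criterion for the summary arms). Deterministic given the seed;
#' failed replicates are recorded with `failed = TRUE` and excluded from the
#' table denominators.
#'
#' @param config an [experiment_config].
#' @param seed base RNG seed; per-replicate substreams are derived from it.
#' @return a `metrics_table`: tibble with one row per (cell, replicate, arm).
#' @export
run_grid <- function(config, seed = 1L) {
  stopifnot(inherits(config, "experiment_config"))
  grid <- expand.grid(L = config$L, S = config$S, n_sites = config$n_sites,
                      theta = config$theta, KEEP.OUT.ATTRS = FALSE)
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 nrow(grid) * config$replicates),
                      nrow = nrow(grid))
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    L <- grid$L[g]; S <- grid$S[g]; n <- grid$n_sites[g]; th <- grid$theta[g]
    net <- config_network(config$model, th, config$phi, config$M)
    mode <- if (!is.null(net$migration)) "mscm"
            else if (!is.null(net$introgression)) "msci" else "msci"
    sps <- setNames(rep(S, 4), c("A", "B", "C", "O"))
    for (r in seq_len(config$replicates)) {
      set.seed(rep_seeds[g, r])
      dat <- simulate_dataset(net, sps, L, n, mode = mode)
      res <- analyse_replicate(dat, net, config)
      for (arm in names(res)) {
        x <- res[[arm]]
        rows[[length(rows) + 1]] <- tibble::tibble(
          model = config$model, L = L, S = S, n_sites = n, theta = th,
          replicate = r, arm = arm,
          estimate = x$estimate, stat = x$stat, p_or_bf = x$p_or_bf,
          reject = x$reject, ci_low = x$ci_low, ci_high = x$ci_high,
          failed = x$failed)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- config
  class(out) <- c("metrics_table", class(out))
  out
}

arm_row <- function(estimate = NA_real_, stat = NA_real_, p_or_bf = NA_real_,
                    reject = NA, ci_low = NA_real_, ci_high = NA_real_,
                    failed = FALSE) {
  list(estimate = estimate, stat = stat, p_or_bf = p_or_bf, reject = reject,
       ci_low = ci_low, ci_high = ci_high, failed = failed)
}

analyse_replicate <- function(dat, net, config) {
  taxa <- c("A", "B", "C", "O")  # sisters (A,B); gene-flow pair (B,C)
  out <- list()
  need_triplets <- any(c("dct", "blt", "quibl") %in% config$arms)
  counts <- NULL
  if (need_triplets) {
    cls <- tryCatch({
      if (config$use_true_trees)
        infer_triplet_classes(NULL, taxa, use_trees = dat$trees)
      else infer_triplet_classes(dat$alignments, taxa)
    }, error = function(e) NULL)
    counts <- if (!is.null(cls)) triplet_counts(cls)
  }
  if ("dct" %in% config$arms) {
    out$dct <- tryCatch({
      r <- dct_test(counts)
      arm_row(estimate = r$phi_hat, p_or_bf = r$p_value,
              reject = r$p_value < config$alpha)
    }, error = function(e) arm_row(failed = TRUE))
  }
  if ("blt" %in% config$arms) {
    out$blt <- tryCatch({
      r <- blt_test(counts$len_dis1, counts$len_dis2)
      arm_row(p_or_bf = r$p_value, reject = r$p_value < config$alpha)
    }, error = function(e) arm_row(failed = TRUE))
  }
  if ("quibl" %in% config$arms) {
    out$quibl <- tryCatch({
      res <- if (config$use_true_trees) 0 else 1 / dat$alignments[[1]]$n
      r <- quibl_test(counts, resolution = res)
      arm_row(estimate = quibl_phi_estimate(counts, resolution = res),
              stat = r$dis2$delta_bic, reject = r$significant)
    }, error = function(e) arm_row(failed = TRUE))
  }
  if ("dstat" %in% config$arms) {
    out$dstat <- tryCatch({
      r <- d_statistic(dat$alignments, taxa)
      arm_row(estimate = r$D, stat = r$z, p_or_bf = r$p_value,
              reject = r$p_value < config$alpha)
    }, error = function(e) arm_row(failed = TRUE))
  }
  if ("bayes" %in% config$arms) {
    out$bayes <- tryCatch({
      th <- net$theta[1]
      # analysis assumes the correct donor/recipient of the generating model
      gen_dir <- if (!is.null(net$introgression)) {
        if (net$labels[net$introgression$recipient] == "B") "inflow" else "outflow"
      } else if (!is.null(net$migration)) {
        if (net$labels[net$migration$recipient[1]] == "B") "inflow" else "outflow"
      } else "inflow"
      model_net <- quartet_network(th, direction = gen_dir, mode = "msci",
                                   phi = 0.5)
      priors <- matched_priors(th)
      ms <- utils::modifyList(list(burnin = 1000, n_samples = 3000, thin = 1,
                                   tau_every = 2, age_moves = 2), config$mcmc)
      tr <- run_mcmc(dat$alignments, model_net, priors,
                     burnin = ms$burnin, n_samples = ms$n_samples,
                     thin = ms$thin, tau_every = ms$tau_every,
                     age_moves = ms$age_moves)
      bf <- savage_dickey_bf(tr, priors)
      ci <- hpd_interval(tr$phi, 0.95)
      arm_row(estimate = mean(tr$phi), p_or_bf = bf$B10,
              reject = bf$B10 > config$bf_cutoff,
              ci_low = ci[1], ci_high = ci[2])
    }, error = function(e) arm_row(failed = TRUE))
  }
  out
}

#' Power table: percentage of replicates rejecting no-gene-flow
#'
#' @param metrics a `metrics_table` from [run_grid()].
#' @return tibble keyed by (setting, arm) with `power` in percent and the
#'   numbers of successful/failed replicates; cells with no successful
#'   replicate carry `NA`.
#' @export
power_table <- function(metrics) {
  dplyr::summarise(
    dplyr::group_by(metrics, model, L, S, n_sites, theta, arm),
    n_ok = sum(!failed),
    n_failed = sum(failed),
    power = if (sum(!failed) > 0) 100 * mean(reject[!failed]) else NA_real_,
    .groups = "drop")
}

#' Estimation table: bias, CI width and coverage of the gene-flow rate
#'
#' The reference truth is the generating `phi` for pulse models and the
#' expected cumulative introgression probability for migration models
#' analysed under the pulse model (the misspecified-mode expectation).
#'
#' @param metrics a `metrics_table` from [run_grid()].
#' @param truth optional override of the true gene-flow rate.
#' @return tibble keyed by (setting, arm) with mean estimate, bias, mean 95%
#'   CI width, and empirical coverage (%) where CIs exist.
#' @export
estimation_table <- function(metrics, truth = NULL) {
  config <- attr(metrics, "config")
  if (is.null(truth)) {
    if (is.null(config)) stop("metrics carry no config; supply `truth`")
    truth <- config_truth(config$model, metrics$theta, config$phi, config$M)
  }
  metrics$truth <- truth
  dplyr::summarise(
    dplyr::group_by(metrics, model, L, S, n_sites, theta, arm),
    n_ok = sum(!failed),
    truth = truth[1],
    mean_estimate = mean(estimate[!failed]),
    bias = mean(estimate[!failed]) - truth[1],
    mean_ci_width = mean(ci_high[!failed] - ci_low[!failed]),
    coverage = 100 * mean(ci_low[!failed] <= truth[1] &
                            truth[1] <= ci_high[!failed]),
    .groups = "drop")
}
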