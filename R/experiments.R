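# Orchestration of the experiment grid: K-sweeps of prediction quality,
# per-order correlation profiles, and sweeps of the effective infection
# rate around the epidemic threshold. All stages derive their seeds from a
# single root seed, so re-running a manifest reproduces every table.

.metric_set <- function(g, metric, K, alpha = 0.85) {
  switch(metric,
         nwc = nwc_iterate(g, K),
         vp = vp_iterate(g, K, alpha = alpha),
         hi = hi_iterate(g, K),
         stop("unknown iterative metric: ", metric))
}

.report_row <- function(report) {
  s <- attr(report, "summary")
  data.frame(r2_mean = s$mean[1L], r2_sd = s$sd[1L],
             tau_mean = s$mean[2L], tau_sd = s$sd[2L],
             recognition_mean = s$mean[3L], recognition_sd = s$sd[3L])
}

#' K-sweep of prediction quality
#'
#' Evaluates each iterative-metric regression model for every maximum order
#' K in `K_values` (features are the orders 1..K), plus optionally the
#' seven-centrality benchmark model, against a fixed influence table. The
#' same derived split seeds are used for every (metric, K) cell, so curves
#' are paired across models.
#'
#' @param g A connected undirected graph.
#' @param influence Ground-truth influence (an `influence_table` or numeric
#'   vector for all nodes).
#' @param metrics Iterative metrics to sweep (subset of `"nwc"`, `"vp"`,
#'   `"hi"`).
#' @param K_values Integer vector of maximum orders.
#' @param config An [experiment_config()]; its `K` is overridden by the
#'   sweep.
#' @param include_benchmark Also evaluate the benchmark model (default
#'   TRUE; reported with `K = NA`).
#' @return A data frame with one row per (metric, K) holding mean and sd of
#'   the three evaluation measures.
#' @export
run_k_sweep <- function(g, influence, metrics = c("nwc", "vp", "hi"),
                        K_values = 1:8, config = experiment_config(),
                        include_benchmark = TRUE) {
  Kmax <- max(K_values)
  sets <- lapply(stats::setNames(metrics, metrics),
                 function(m) .metric_set(g, m, Kmax))
  rows <- list()
  for (m in metrics) {
    for (K in K_values) {
      cfg <- config
      cfg$K <- as.integer(K)
      rep <- run_experiment(sets[[m]], influence, cfg)
      rows[[length(rows) + 1L]] <- cbind(data.frame(metric = m, K = K),
                                         .report_row(rep))
    }
  }
  if (include_benchmark) {
    rep <- run_experiment(benchmark_centralities(g), influence, config)
    rows[[length(rows) + 1L]] <- cbind(data.frame(metric = "benchmark", K = NA),
                                       .report_row(rep))
  }
  do.call(rbind, rows)
}

#' Per-order correlation profiles
#'
#' For each iterative metric and order k, Kendall's tau-b between the
#' order-k metric and (i) the nodal influence and (ii) the converged global
#' centrality the iteration targets (eigenvector centrality for NWC,
#' PageRank for VP, coreness for HI).
#'
#' @inheritParams run_k_sweep
#' @param K_max Largest order profiled.
#' @param alpha Teleportation parameter for VP/PageRank.
#' @return A data frame with columns `metric`, `order`, `tau_influence`,
#'   `tau_target`.
#' @export
run_correlation_profiles <- function(g, influence, metrics = c("nwc", "vp", "hi"),
                                     K_max = 10L, alpha = 0.85) {
  y <- if (inherits(influence, "influence_table")) influence$influence else as.numeric(influence)
  targets <- list(nwc = function() eigenvector_converged(g),
                  vp = function() pagerank_converged(g, alpha = alpha),
                  hi = function() as.numeric(igraph::coreness(g)))
  rows <- lapply(metrics, function(m) {
    ms <- .metric_set(g, m, K_max, alpha = alpha)
    tgt <- targets[[m]]()
    data.frame(metric = m, order = seq_len(K_max),
               tau_influence = vapply(seq_len(K_max), function(k)
                 kendall_tau(ms$values[, k], y), numeric(1L)),
               tau_target = vapply(seq_len(K_max), function(k)
                 kendall_tau(ms$values[, k], tgt), numeric(1L)))
  })
  do.call(rbind, rows)
}

#' Sweep of the effective infection rate around the threshold
#'
#' Re-estimates ground-truth influence at each `multiplier * lambda_c` and
#' evaluates the requested feature sets at every rate.
#'
#' @param g A connected undirected graph.
#' @param lambda_c Epidemic threshold (e.g. from [estimate_threshold()]).
#' @param multipliers Multiples of `lambda_c` to scan (default
#'   `c(0.5, 1, 1.5, 2)`).
#' @param feature_sets Subset of `"nwc"`, `"vp"`, `"hi"`, `"benchmark"`.
#' @param sir_runs SIR realizations per node for each rate.
#' @param sir_seed Root seed for the SIR stage.
#' @param config An [experiment_config()].
#' @return A data frame with one row per (multiplier, feature set),
#'   including the mean influence at that rate.
#' @export
run_lambda_sweep <- function(g, lambda_c, multipliers = c(0.5, 1, 1.5, 2),
                             feature_sets = c("nwc", "vp", "hi", "benchmark"),
                             sir_runs = 1000L, sir_seed = 1L,
                             config = experiment_config()) {
  features <- lapply(stats::setNames(feature_sets, feature_sets), function(fs) {
    if (fs == "benchmark") benchmark_centralities(g) else .metric_set(g, fs, config$K)
  })
  rows <- list()
  for (i in seq_along(multipliers)) {
    lambda <- multipliers[i] * lambda_c
    infl <- estimate_influence(g, config = sir_config(
      beta = lambda, runs = sir_runs, seed = .derive_seed(sir_seed, i)))
    for (fs in feature_sets) {
      rep <- run_experiment(features[[fs]], infl, config)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(multiplier = multipliers[i], lambda = lambda, metric = fs,
                   mean_influence = mean(infl$influence)),
        .report_row(rep))
    }
  }
  do.call(rbind, rows)
}

#' Run a full experiment manifest
#'
#' A manifest is a plain list describing one end-to-end experiment:
#' \describe{
#'   \item{graph}{either `list(type = "edge_list", path =, dialect =)` or
#'     `list(type = "lfr", n =, mu =, ...)` (extra entries passed to
#'     [generate_lfr()]).}
#'   \item{seed}{root seed for every stage.}
#'   \item{sir}{`list(runs =)`, SIR realizations per node.}
#'   \item{threshold}{optional `list(grid =, runs =, sample_size =)`;
#'     omit to estimate with defaults. `lambda_c` may be given directly.}
#'   \item{multipliers}{multiples of lambda_c for the rate sweep (default
#'     1.0 only).}
#'   \item{K_values}{orders for the K-sweep (default 1:8).}
#'   \item{eval}{`list(q =, realizations =, f_percent =)`.}
#' }
#' Writes `influence.csv`, `ksweep.csv`, `profiles.csv`,
#' `lambda_sweep.csv` and `manifest.lock.json` (the resolved manifest plus
#' derived stage seeds and an md5 of the manifest) to `out_dir`. Re-running
#' with the same manifest reproduces every file byte for byte.
#'
#' @param manifest A manifest list.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory tables.
#' @export
run_experiment_manifest <- function(manifest, out_dir) {
  stopifnot(is.list(manifest), !is.null(manifest$graph), !is.null(manifest$seed))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- manifest$seed

  gspec <- manifest$graph
  membership <- NULL
  if (identical(gspec$type, "edge_list")) {
    g <- largest_component(read_edge_list(gspec$path,
                                          dialect = gspec$dialect %||% "plain"))
  } else if (identical(gspec$type, "lfr")) {
    args <- gspec[setdiff(names(gspec), "type")]
    args$seed <- .derive_seed(seed, 1L)
    net <- do.call(generate_lfr, args)
    g <- net$graph
    membership <- net$membership
  } else stop("unknown graph spec type")

  sir_runs <- manifest$sir$runs %||% 1000L
  lambda_c <- manifest$lambda_c
  if (is.null(lambda_c)) {
    th <- manifest$threshold %||% list()
    scan <- estimate_threshold(
      g, lambda_grid = th$grid,
      config = sir_config(beta = 1, runs = th$runs %||% sir_runs,
                          seed = .derive_seed(seed, 2L)),
      sample_size = th$sample_size)
    lambda_c <- scan$lambda_c
  }

  infl <- estimate_influence(g, config = sir_config(
    beta = lambda_c, runs = sir_runs, seed = .derive_seed(seed, 3L)))

  ev <- manifest$eval %||% list()
  cfg <- experiment_config(q = ev$q %||% 0.10,
                           realizations = ev$realizations %||% 50L,
                           f_percent = ev$f_percent %||% 10,
                           rng_seed = .derive_seed(seed, 4L))

  ks <- run_k_sweep(g, infl, K_values = manifest$K_values %||% 1:8, config = cfg)
  prof <- run_correlation_profiles(g, infl,
                                   K_max = max(manifest$K_values %||% 1:8))
  lsw <- run_lambda_sweep(g, lambda_c,
                          multipliers = manifest$multipliers %||% 1.0,
                          sir_runs = sir_runs,
                          sir_seed = .derive_seed(seed, 5L), config = cfg)

  write.csv(infl, file.path(out_dir, "influence.csv"), row.names = FALSE)
  write.csv(ks, file.path(out_dir, "ksweep.csv"), row.names = FALSE)
  write.csv(prof, file.path(out_dir, "profiles.csv"), row.names = FALSE)
  write.csv(lsw, file.path(out_dir, "lambda_sweep.csv"), row.names = FALSE)

  lock <- list(manifest = manifest, lambda_c = lambda_c,
               stage_seeds = stats::setNames(
                 lapply(1:5, function(k) .derive_seed(seed, k)),
                 c("graph", "threshold", "influence", "eval", "lambda_sweep")),
               n = igraph::vcount(g), m = igraph::gsize(g))
  lock_path <- file.path(out_dir, "manifest.lock.json")
  jsonlite::write_json(lock, lock_path, auto_unbox = TRUE, digits = NA)
  lock$md5 <- unname(tools::md5sum(lock_path))
  jsonlite::write_json(lock, lock_path, auto_unbox = TRUE, digits = NA)

  invisible(list(graph = g, membership = membership, lambda_c = lambda_c,
                 influence = infl, ksweep = ks, profiles = prof,
                 lambda_sweep = lsw))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
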