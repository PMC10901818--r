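# The influence-prediction protocol: random q-fraction training split,
# regression on nodal features (an iterative metric set or the benchmark
# centralities), and evaluation on the held-out nodes, repeated over split
# realizations.

#' Experiment configuration for the prediction protocol
#'
#' @param q Training fraction in (0, 1); default 0.10.
#' @param realizations Number of independent training-split realizations
#'   (default 50).
#' @param K Maximum order of the iterative metric set used as features
#'   (default 4).
#' @param f_percent Top fraction for the recognition rate (default 10).
#' @param regressor `"random_forest"` (100 trees, deep) or `"ridge"`.
#' @param rng_seed Integer root seed; split and model seeds are derived
#'   per realization.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(q = 0.10, realizations = 50L, K = 4L,
                              f_percent = 10, regressor = c("random_forest", "ridge"),
                              rng_seed = 1L) {
  regressor <- match.arg(regressor)
  stopifnot(q > 0, q < 1, realizations >= 1, K >= 1,
            f_percent > 0, f_percent < 100)
  structure(list(q = q, realizations = as.integer(realizations),
                 K = as.integer(K), f_percent = f_percent,
                 regressor = regressor, rng_seed = rng_seed),
            class = "experiment_config")
}

#' Random train/test split of node indices
#'
#' Draws a uniform random training set of `round(q * n)` nodes; the rest
#' form the test set. Uses the caller's RNG stream (seed with
#' [set.seed()] for reproducibility).
#'
#' @param n Number of nodes, or a graph.
#' @param q Training fraction.
#' @return A list with sorted integer vectors `train` and `test`.
#' @export
split_nodes <- function(n, q) {
  if (inherits(n, "igraph")) n <- igraph::vcount(n)
  n <- as.integer(n)
  if (floor(q * n) < 2) stop("training fraction too small: floor(q*n) must be >= 2")
  ntr <- round(q * n)
  train <- sort(sample.int(n, ntr))
  list(train = train, test = setdiff(seq_len(n), train))
}

# Coerce feature containers to a plain numeric matrix, optionally keeping
# only the first K orders of an iterative metric set.
as_features <- function(x, K = NULL) {
  if (inherits(x, "iterative_metric_set")) {
    v <- x$values
    if (!is.null(K)) v <- v[, seq_len(min(K, ncol(v))), drop = FALSE]
    return(v * 1.0)
  }
  if (is.data.frame(x)) {
    x <- x[, setdiff(names(x), "node"), drop = FALSE]
    return(as.matrix(x))
  }
  as.matrix(x)
}

#' Fit a regressor on training nodes and predict the test nodes
#'
#' @param features Feature container: an `iterative_metric_set`, the
#'   benchmark data frame from [benchmark_centralities()], or a numeric
#'   matrix with one row per node.
#' @param influence Ground-truth influence: an `influence_table` or a
#'   numeric vector aligned with the feature rows.
#' @param train Integer indices of the training nodes.
#' @param test Integer indices of the test nodes (default: the complement).
#' @param regressor `"random_forest"` or `"ridge"`.
#' @param seed Seed for the regressor (random forest tree sampling).
#' @param num_trees Number of trees for the random forest (default 100).
#' @param ridge_lambda Ridge penalty on standardized features
#'   (default 1e-3).
#' @return Numeric vector of predictions for `test`.
#' @export
fit_and_predict <- function(features, influence, train, test = NULL,
                            regressor = c("random_forest", "ridge"),
                            seed = NULL, num_trees = 100L,
                            ridge_lambda = 1e-3) {
  regressor <- match.arg(regressor)
  X <- as_features(features)
  y <- if (inherits(influence, "influence_table")) influence$influence else as.numeric(influence)
  stopifnot(nrow(X) == length(y))
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  if (is.null(test)) test <- setdiff(seq_len(nrow(X)), train)
  ytr <- y[train]
  if (stats::var(ytr) == 0) {
    warning("constant target on the training set; predicting the constant")
    return(rep(ytr[1L], length(test)))
  }
  if (regressor == "random_forest") {
    dtr <- as.data.frame(X[train, , drop = FALSE])
    fit <- ranger::ranger(y = ytr, x = dtr, num.trees = num_trees,
                          min.node.size = 1L, seed = seed)
    predict(fit, data = as.data.frame(X[test, , drop = FALSE]))$predictions
  } else {
    # closed-form ridge on standardized features
    mu <- colMeans(X[train, , drop = FALSE])
    sdev <- apply(X[train, , drop = FALSE], 2L, stats::sd)
    sdev[sdev == 0] <- 1
    Xtr <- sweep(sweep(X[train, , drop = FALSE], 2L, mu), 2L, sdev, "/")
    Xte <- sweep(sweep(X[test, , drop = FALSE], 2L, mu), 2L, sdev, "/")
    p <- ncol(Xtr)
    beta <- solve(crossprod(Xtr) + ridge_lambda * diag(p),
                  crossprod(Xtr, ytr - mean(ytr)))
    as.numeric(mean(ytr) + Xte %*% beta)
  }
}

#' Run the full prediction experiment
#'
#' Repeats split -> fit -> evaluate over `config$realizations` independent
#' training-split realizations and aggregates the three evaluation
#' measures. The ground-truth influence is fixed; only the training split
#' and the forest's tree sampling are re-randomized, with all seeds derived
#' from `config$rng_seed`.
#'
#' @param features Feature container (see [fit_and_predict()]); iterative
#'   metric sets are truncated to the first `config$K` orders.
#' @param influence Ground-truth influence for all nodes.
#' @param config An [experiment_config()].
#' @return An `evaluation_report` data frame with one row per realization
#'   (`realization`, `r_squared`, `kendall_tau`, `recognition_rate`) and a
#'   `summary` attribute holding the mean and sd of each measure.
#' @export
run_experiment <- function(features, influence, config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  X <- as_features(features, K = config$K)
  y <- if (inherits(influence, "influence_table")) influence$influence else as.numeric(influence)
  stopifnot(nrow(X) == length(y))
  n <- nrow(X)
  rows <- lapply(seq_len(config$realizations), function(i) {
    state <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    set.seed(.derive_seed(config$rng_seed, i))
    sp <- split_nodes(n, config$q)
    if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
    yhat <- fit_and_predict(X, y, sp$train, sp$test,
                            regressor = config$regressor,
                            seed = .derive_seed(config$rng_seed, i + 500000L))
    ytest <- y[sp$test]
    data.frame(realization = i,
               r_squared = r_squared(ytest, yhat),
               kendall_tau = kendall_tau(yhat, ytest),
               recognition_rate = recognition_rate(yhat, ytest,
                                                   config$f_percent))
  })
  out <- do.call(rbind, rows)
  measures <- c("r_squared", "kendall_tau", "recognition_rate")
  attr(out, "summary") <- data.frame(
    measure = measures,
    mean = vapply(measures, function(m) mean(out[[m]]), numeric(1L)),
    sd = vapply(measures, function(m) stats::sd(out[[m]]), numeric(1L)),
    row.names = NULL
  )
  attr(out, "config") <- config
  class(out) <- c("evaluation_report", "data.frame")
  out
}

#' Summarize an evaluation report
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return The `summary` data frame (measure, mean, sd).
#' @export
summary.evaluation_report <- function(object, ...) {
  attr(object, "summary")
}

#' @export
print.evaluation_report <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("<evaluation_report> %d realizations\n", nrow(x)))
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-17s mean %.4f  sd %.4f\n", s$measure[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}
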