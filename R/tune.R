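#' Declare a hyperparameter search dimension
#'
#' @param name Parameter name.
#' @param type One of \code{"int"}, \code{"float"}, \code{"logfloat"},
#'   \code{"categorical"}.
#' @param lower,upper Bounds (numeric types).
#' @param levels Character vector of levels (categorical).
#' @return A \code{search_param} list.
#' @export
search_param <- function(name, type = c("int", "float", "logfloat",
                                        "categorical"),
                         lower = NULL, upper = NULL, levels = NULL) {
  type <- match.arg(type)
  if (type == "categorical") {
    stopifnot(length(levels) >= 1L)
  } else {
    stopifnot(is.numeric(lower), is.numeric(upper), upper >= lower)
    if (type == "logfloat") stopifnot(lower > 0)
  }
  structure(list(name = name, type = type, lower = lower, upper = upper,
                 levels = levels), class = "search_param")
}

#' Default boosted-tree search space
#'
#' Conservative spans: trees 100--1000, depth 4--10, learning rate
#' 1e-3--0.3 (log-uniform), L2 regularization 1--10.
#'
#' @return List of [search_param()]s.
#' @export
default_search_space <- function() {
  list(search_param("n_trees", "int", 100, 1000),
       search_param("depth", "int", 4, 10),
       search_param("learning_rate", "logfloat", 1e-3, 0.3),
       search_param("l2_reg", "float", 1, 10))
}

# map unit-cube coordinates to parameter values
decode_point <- function(space, u) {
  vals <- list()
  for (i in seq_along(space)) {
    p <- space[[i]]
    vals[[p$name]] <- switch(p$type,
      int = as.integer(round(p$lower + u[i] * (p$upper - p$lower))),
      float = p$lower + u[i] * (p$upper - p$lower),
      logfloat = exp(log(p$lower) + u[i] * (log(p$upper) - log(p$lower))),
      categorical = p$levels[[pmin(length(p$levels),
                                   1L + floor(u[i] * length(p$levels)))]])
  }
  vals
}

# stratified (Latin-hypercube style) unit-cube design
lhs_design <- function(n, d) {
  sapply(seq_len(d), function(j)
    (sample.int(n) - stats::runif(n)) / n)
}

# zero-mean GP posterior with RBF kernel on the unit cube
gp_fit <- function(U, y, lengthscale = 0.25, noise = 1e-4) {
  K <- exp(-as.matrix(stats::dist(U))^2 / (2 * lengthscale^2))
  mu <- mean(y); sdev <- stats::sd(y); if (!is.finite(sdev) || sdev == 0) sdev <- 1
  ch <- chol(K + diag(noise + 1e-8, nrow(U)))
  alpha <- backsolve(ch, forwardsolve(t(ch), (y - mu) / sdev))
  list(U = U, ch = ch, alpha = alpha, mu = mu, sdev = sdev, ls = lengthscale)
}

gp_predict <- function(fit, Unew) {
  cross <- exp(-outer(rowSums(Unew^2), rowSums(fit$U^2), "+") / (2 * fit$ls^2) +
               (Unew %*% t(fit$U)) / fit$ls^2)
  m <- fit$mu + fit$sdev * as.vector(cross %*% fit$alpha)
  v <- backsolve(fit$ch, forwardsolve(t(fit$ch), t(cross)), transpose = FALSE)
  s2 <- pmax(1e-12, 1 - colSums(forwardsolve(t(fit$ch), t(cross))^2))
  list(mean = m, sd = fit$sdev * sqrt(s2))
}

#' Bayesian hyperparameter search
#'
#' Sequential model-based optimization over a declared search space:
#' (1) the space is declared via [search_param()]s; (2) the objective maps a
#' parameter set to a scalar to be maximized (by convention a
#' cross-validated metric such as MCC computed on training data only);
#' (3--5) after a stratified initial design, a Gaussian-process surrogate on
#' the unit cube is refit after every evaluation and the next point
#' maximizes expected improvement over random candidates; (6) the best trial
#' and the full log are returned. Fully seeded.
#'
#' @param space List of [search_param()]s.
#' @param objective \code{function(params_list) -> numeric} (maximized).
#' @param budget Total number of trials (>= 1).
#' @param seed Integer seed.
#' @param n_init Initial design size (default \code{min(budget, max(5, d+1))}).
#' @param n_candidates Random candidates scored per acquisition step.
#' @return List with \code{best} (trial id, params, objective) and
#'   \code{trials} (data.frame log; one row per trial).
#' @export
tune_hyperparameters <- function(space, objective, budget = 25L, seed = 1L,
                                 n_init = NULL, n_candidates = 256L) {
  if (length(space) == 0L) stop("empty search space", call. = FALSE)
  stopifnot(budget >= 1L)
  d <- length(space)
  if (is.null(n_init)) n_init <- min(budget, max(5L, d + 1L))
  with_seed(seed, {
    U <- matrix(lhs_design(n_init, d), n_init, d)
    vals <- numeric(0)
    params_log <- list()
    for (t in seq_len(budget)) {
      if (t > n_init) {
        fit <- gp_fit(U[seq_len(t - 1L), , drop = FALSE], vals)
        cand <- matrix(stats::runif(n_candidates * d), n_candidates, d)
        pr <- gp_predict(fit, cand)
        best_y <- max(vals)
        z <- (pr$mean - best_y) / pr$sd
        ei <- pr$sd * (z * stats::pnorm(z) + stats::dnorm(z))
        U <- rbind(U, cand[which.max(ei), ])
      }
      pars <- decode_point(space, U[t, ])
      params_log[[t]] <- pars
      vals[t] <- objective(pars)
    }
    trials <- cbind(data.frame(trial = seq_len(budget)),
                    do.call(rbind, lapply(params_log, as.data.frame)),
                    objective = vals)
    best_i <- which.max(vals)
    list(best = list(trial = best_i, params = params_log[[best_i]],
                     objective = vals[best_i]),
         trials = trials)
  })
}

#' Cross-validated tuning objective for the boosted-tree classifier
#'
#' Builds an objective for [tune_hyperparameters()]: mean k-fold CV MCC (or
#' another metric) of [train_classifier()] on a fixed feature matrix.
#' Only training data should be passed in; the held-out test split must stay
#' outside the tuning loop.
#'
#' @param X Feature matrix. @param y 0/1 labels.
#' @param n_folds Folds (default 5 for tuning economy).
#' @param metric One of the [compute_metrics()] names (default "MCC").
#' @param seed Fold seed.
#' @return \code{function(params) -> numeric}.
#' @export
cv_objective <- function(X, y, n_folds = 5L, metric = "MCC", seed = 1L) {
  y <- as.integer(y)
  fold <- integer(length(y))
  with_seed(seed, for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(n_folds),
                                                  length(idx))
  })
  function(params) {
    bp <- do.call(boost_params, c(params[intersect(names(params),
      c("n_trees", "depth", "learning_rate", "l2_reg"))], list(seed = seed)))
    mean(vapply(seq_len(n_folds), function(k) {
      tr <- fold != k
      m <- train_classifier(X[tr, , drop = FALSE], y[tr], bp)
      rep <- compute_metrics(y[!tr], predict_proba(m, X[!tr, , drop = FALSE]))
      rep[[metric]]
    }, 0))
  }
}
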