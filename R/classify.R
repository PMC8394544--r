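# One-hidden-layer MLP severity classifiers with the hyperparameter
# grid optimized by bootstrap-averaged Cohen's kappa.

#' Hyperparameter grid for the MLP
#'
#' Hidden-layer sizes 2-20 in steps of 1 and 22-50 in steps of 2,
#' crossed with weight-decay values 0.5-10 in steps of 0.5: 680
#' combinations in total. Rows are ordered by `n_hidden` then `lambda`
#' so that argmax tie-breaking prefers the smaller network.
#'
#' @return Data frame with columns `n_hidden` and `lambda`.
#' @export
mlp_grid <- function() {
  g <- expand.grid(lambda = seq(0.5, 10, by = 0.5),
                   n_hidden = c(2:20, seq(22L, 50L, by = 2L)))
  g <- g[order(g$n_hidden, g$lambda), c("n_hidden", "lambda")]
  rownames(g) <- NULL
  g
}

#' Train a one-hidden-layer MLP classifier
#'
#' Logistic-sigmoid hidden and output units, trained by minimizing the
#' cross-entropy with an additive weight-decay penalty
#' `lambda * sum(w^2)` (the classic regularized MLP). Features are
#' standardized with training-set statistics stored in the model, so
#' later predictions never touch test-set statistics. Weights are
#' randomly initialized; the fit is deterministic given `seed`.
#'
#' @param x Numeric matrix or data frame of features.
#' @param y Binary labels (0/1, logical, or two-level factor); both
#'   classes must be present.
#' @param n_hidden Hidden-layer size.
#' @param lambda Weight-decay coefficient.
#' @param seed Integer RNG seed for weight initialization.
#' @param maxit Maximum optimizer iterations (default 500).
#' @return An object of class `trained_mlp`.
#' @export
train_mlp <- function(x, y, n_hidden = 2L, lambda = 5, seed = 1L,
                      maxit = 500L) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("NaN/NA in features")
  y <- as_binary(y)
  if (length(unique(y)) < 2) stop("both classes must be present in y")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  set.seed(as.integer(seed))
  net <- nnet::nnet(xs, y, size = n_hidden, decay = lambda,
                    entropy = TRUE, maxit = maxit, trace = FALSE)
  structure(list(net = net, center = ctr, scale = scl,
                 spec = list(n_inputs = ncol(x), n_hidden = n_hidden,
                             lambda = lambda, seed = as.integer(seed),
                             maxit = maxit),
                 features = colnames(x)),
            class = "trained_mlp")
}

as_binary <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary (0/1)")
  as.numeric(y)
}

#' Posterior probability from a trained MLP
#'
#' Applies the model's stored standardization and returns the output
#' unit's sigmoid activation, the posterior probability of the
#' positive (severity) class, clamped to the open interval (0, 1).
#'
#' @param model A `trained_mlp`.
#' @param x Feature matrix with the same columns as at training.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_posterior <- function(model, x) {
  stopifnot(inherits(model, "trained_mlp"))
  x <- as.matrix(x)
  if (ncol(x) != model$spec$n_inputs) {
    stop("feature-count mismatch: model expects ", model$spec$n_inputs,
         " features, got ", ncol(x))
  }
  xs <- scale(x, center = model$center, scale = model$scale)
  p <- as.vector(predict(model$net, xs))
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `k = (p_o - p_e) / (1 - p_e)` from the
#' confusion table of two label vectors. When observed and expected
#' agreement are both 1 (identical constant vectors), kappa is defined
#' as 1.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  lev <- sort(unique(c(y_true, y_pred)))
  t1 <- factor(y_true, levels = lev)
  t2 <- factor(y_pred, levels = lev)
  tab <- table(t1, t2)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) return(1)
  (po - pe) / (1 - pe)
}

#' Optimize MLP hyperparameters by bootstrap-averaged kappa
#'
#' For every `(n_hidden, lambda)` grid point, trains on bootstrap
#' resamples of the subjects and computes Cohen's kappa on the
#' out-of-bag subjects (at the 0.5 posterior threshold); the grid
#' point with the highest average kappa wins, ties going to the
#' smaller hidden layer and then the smaller decay. Replicates whose
#' bootstrap sample contains a single class are redrawn (counted in
#' `n_redrawn`). Deterministic given `seed`.
#'
#' @param x Feature matrix.
#' @param y Binary labels.
#' @param grid Data frame of `n_hidden`, `lambda` (default
#'   [mlp_grid()]; pass a reduced grid for exploratory runs).
#' @param B Bootstrap replicates per grid point.
#' @param seed Integer RNG seed.
#' @param maxit Optimizer iterations per fit.
#' @return A list: `best` (one-row data frame), `kappa` (per-grid-row
#'   mean kappa), `n_redrawn`.
#' @export
optimize_hyperparams <- function(x, y, grid = mlp_grid(), B = 50L, seed = 1L,
                                 maxit = 200L) {
  stopifnot(nrow(grid) >= 1)
  x <- as.matrix(x)
  y <- as_binary(y)
  n <- nrow(x)
  set.seed(as.integer(seed))
  # one shared set of bootstrap index draws across grid points
  draws <- list()
  n_redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2 && length(setdiff(seq_len(n), idx)) > 0)
        break
      n_redrawn <- n_redrawn + 1L
    }
    draws[[b]] <- idx
  }
  kappas <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    ks <- vapply(seq_len(B), function(b) {
      idx <- draws[[b]]
      oob <- setdiff(seq_len(n), unique(idx))
      fit <- train_mlp(x[idx, , drop = FALSE], y[idx],
                       n_hidden = grid$n_hidden[g], lambda = grid$lambda[g],
                       seed = as.integer(seed) + 7L * b, maxit = maxit)
      pred <- as.integer(predict_posterior(fit, x[oob, , drop = FALSE]) >= 0.5)
      cohens_kappa(y[oob], pred)
    }, numeric(1))
    kappas[g] <- mean(ks)
  }
  best <- which.max(kappas) # grid ordered n_hidden then lambda: ties -> smaller
  list(best = grid[best, , drop = FALSE], kappa = kappas,
       n_redrawn = n_redrawn)
}
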