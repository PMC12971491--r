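#' Sample a battery of random binary classification tasks
#'
#' Each task is defined by a teacher vector `T` drawn i.i.d. from a standard
#' Gaussian in the `d`-dimensional latent space; its hyperplane "shatters"
#' the latent space into a binary labeling `y = sign(T . z)`.
#'
#' @param d latent dimension.
#' @param n_tasks number of tasks.
#' @param seed optional integer seed (set before drawing, recorded on the
#'   result).
#' @return A `task_battery`: an `n_tasks x d` matrix of teacher vectors with
#'   attribute `seed`.
#' @export
sample_tasks <- function(d, n_tasks, seed = NULL) {
  stopifnot(d >= 1, n_tasks >= 1)
  if (!is.null(seed)) set.seed(seed)
  teachers <- matrix(stats::rnorm(n_tasks * d), nrow = n_tasks, ncol = d)
  structure(teachers, class = c("task_battery", "matrix"), seed = seed)
}

#' Task labels from latents and a task battery
#'
#' Computes `y[mu, t] = sign(T_t . z_mu)` with the tie `sign(0)` mapped to
#' `+1` (a measure-zero event for continuous latents; the deterministic rule
#' keeps runs reproducible).
#'
#' @param Z `p x d` latent matrix.
#' @param battery a [sample_tasks()] battery (or any `n_tasks x d` matrix).
#' @return A `p x n_tasks` matrix with entries in `{-1, +1}`.
#' @export
make_labels <- function(Z, battery) {
  Z <- as.matrix(Z)
  if (ncol(Z) != ncol(battery)) {
    stop("latent dimension of Z does not match the task battery")
  }
  sign_pos(Z %*% t(unclass(battery)))
}

sign_pos <- function(m) {
  out <- matrix(1, nrow(m), ncol(m))
  out[m < 0] <- -1
  out
}

#' Supervised Hebbian readout weights
#'
#' The Hebbian rule assigns each task the label-weighted mean response
#' \deqn{w = \frac{1}{p} \sum_\mu y_\mu x_\mu.}
#' For balanced labels this equals half the difference between the class
#' mean responses, i.e. a difference-of-means classifier.
#'
#' @param X `p x n` response matrix.
#' @param y labels: a length-`p` vector in `{-1, +1}` or a `p x n_tasks`
#'   matrix of such labels.
#' @return An `n`-vector (or `n x n_tasks` matrix) of readout weights.
#' @export
hebbian_weights <- function(X, y) {
  X <- as.matrix(X)
  p <- nrow(X)
  if (p == 0) stop("empty dataset")
  if (is.matrix(y)) {
    if (nrow(y) != p) stop("label rows must match response rows")
    crossprod(X, y) / p
  } else {
    if (length(y) != p) stop("label length must match response rows")
    drop(crossprod(X, y)) / p
  }
}

#' Predict labels with a Hebbian readout
#'
#' `yhat = sign(w . x)` per test point, with `sign(0) -> +1`. Predictions are
#' invariant to positive rescaling of the weights.
#'
#' @param w weight vector (length `n`) or `n x n_tasks` weight matrix.
#' @param X_test `m x n` test response matrix.
#' @return An `m`-vector (or `m x n_tasks` matrix) of predictions in
#'   `{-1, +1}`.
#' @export
hebbian_predict <- function(w, X_test) {
  X_test <- as.matrix(X_test)
  scores <- X_test %*% (if (is.matrix(w)) w else matrix(w, ncol = 1))
  out <- sign_pos(scores)
  if (!is.matrix(w)) drop(out) else out
}

#' Bundle latents, responses and labels into a labeled dataset
#'
#' Centers `X` and `Z` column-wise (the readout theory assumes zero-mean
#' responses) and attaches labels computed from the uncentered latents.
#'
#' @param Z `p x d` latent matrix.
#' @param X `p x n` response matrix.
#' @param battery a [sample_tasks()] battery.
#' @param center center columns of `X` and `Z` (default `TRUE`).
#' @return A `labeled_dataset`: list with `X`, `Z`, `Y`, `p`, `battery`.
#' @export
labeled_dataset <- function(Z, X, battery, center = TRUE) {
  Z <- as.matrix(Z); X <- as.matrix(X)
  if (nrow(Z) != nrow(X)) stop("Z and X must have the same number of rows")
  Y <- make_labels(Z, battery)
  if (center) {
    X <- scale(X, center = TRUE, scale = FALSE)
    Z <- scale(Z, center = TRUE, scale = FALSE)
    attr(X, "scaled:center") <- NULL
    attr(Z, "scaled:center") <- NULL
  }
  structure(list(X = X, Z = Z, Y = Y, p = nrow(X), battery = battery),
            class = "labeled_dataset")
}

#' Empirical task-averaged generalization error
#'
#' Trains one Hebbian readout per task on the training set and reports the
#' fraction of mismatched labels on the test set, per task and averaged.
#' Standard errors across tasks are included as a diagnostic; for comparing
#' repeated simulations the SEM across repeats (see [monte_carlo_error()])
#' is the appropriate uncertainty.
#'
#' @param train,test `labeled_dataset`s built with the same task battery.
#' @return List with `per_task` (error per task), `mean`, `sem_tasks`, and
#'   `balance` (mean fraction of positive training labels, a diagnostic; no
#'   balancing is applied).
#' @export
empirical_task_error <- function(train, test) {
  stopifnot(inherits(train, "labeled_dataset"), inherits(test, "labeled_dataset"))
  if (test$p == 0) stop("empty test set")
  if (!identical(dim(train$battery), dim(test$battery))) {
    stop("train and test must share a task battery")
  }
  W <- hebbian_weights(train$X, train$Y)
  pred <- hebbian_predict(W, test$X)
  err <- colMeans(pred != test$Y)
  list(per_task = err,
       mean = mean(err),
       sem_tasks = stats::sd(err) / sqrt(length(err)),
       balance = mean(train$Y == 1))
}

# Eigen square root of the joint covariance, for sampling (x, z) pairs.
joint_root <- function(code) {
  joint <- rbind(cbind(code$omega, t(code$phi)), cbind(code$phi, code$psi))
  sqrt_sym(joint)
}

# Draw p joint samples; returns list(Z = p x d, X = p x n).
sample_joint <- function(code, p, root = joint_root(code)) {
  g <- matrix(stats::rnorm(p * ncol(root)), nrow = p)
  m <- g %*% t(root)
  list(Z = m[, seq_len(code$d), drop = FALSE],
       X = m[, code$d + seq_len(code$n), drop = FALSE])
}

#' Monte-Carlo estimate of the task-averaged Hebbian error
#'
#' Repeatedly draws a fresh task battery, training set and test set from the
#' joint Gaussian model defined by `code`, trains Hebbian readouts, and
#' averages the empirical task-averaged error over repeats. Each repeat uses
#' `p` training and `n_test` test samples and `n_tasks` tasks.
#'
#' @param code a [gaussian_code()].
#' @param p training-set size.
#' @param n_tasks tasks per repeat.
#' @param n_test test samples per repeat.
#' @param n_repeats independent repeats (default 30).
#' @param seed optional integer seed.
#' @return List with `mean`, `sem` (across repeats), `per_repeat`,
#'   `sem_tasks` (mean across repeats of the per-task SEM) and `theory`, the
#'   matching [theoretical_error()] prediction.
#' @export
monte_carlo_error <- function(code, p, n_tasks = 300, n_test = 1000,
                              n_repeats = 30, seed = NULL) {
  stopifnot(inherits(code, "gaussian_code"),
            p >= 1, n_tasks >= 1, n_test >= 1, n_repeats >= 1)
  if (!is.null(seed)) set.seed(seed)
  root <- joint_root(code)
  errs <- numeric(n_repeats)
  sem_tasks <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    battery <- sample_tasks(code$d, n_tasks)
    tr <- sample_joint(code, p, root)
    te <- sample_joint(code, n_test, root)
    train <- labeled_dataset(tr$Z, tr$X, battery)
    test <- labeled_dataset(te$Z, te$X, battery)
    res <- empirical_task_error(train, test)
    errs[r] <- res$mean
    sem_tasks[r] <- res$sem_tasks
  }
  list(mean = mean(errs),
       sem = if (n_repeats > 1) stats::sd(errs) / sqrt(n_repeats) else NA_real_,
       per_repeat = errs,
       sem_tasks = mean(sem_tasks),
       # a code with phi = 0 carries no task information: chance level
       theory = if (sum(code$phi^2) == 0) 0.5 else theoretical_error(code, p)$e_g)
}
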