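#' Power-law latent covariance
#'
#' Builds a `d x d` latent covariance whose eigenvalues decay as a power
#' law, `omega_i = scale * i^(-alpha)`. `alpha = 0` gives an isotropic
#' covariance; larger `alpha` concentrates latent variance in the leading
#' directions. By default the covariance is diagonal in the coordinate
#' basis; set `rotate = TRUE` for a random orthogonal eigenbasis.
#'
#' @param d latent dimension.
#' @param alpha power-law exponent, `>= 0`.
#' @param scale leading eigenvalue (default 5).
#' @param rotate rotate the eigenbasis randomly.
#' @param seed optional integer seed (used only when `rotate = TRUE`).
#' @return A `d x d` covariance matrix.
#' @export
power_law_omega <- function(d, alpha, scale = 5, rotate = FALSE, seed = NULL) {
  stopifnot(d >= 1, alpha >= 0, scale > 0)
  vals <- scale * seq_len(d)^(-alpha)
  if (!rotate) return(diag(vals, d))
  if (!is.null(seed)) set.seed(seed)
  q <- qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
  q %*% (vals * t(q))
}

#' Sample zero-mean Gaussian latents
#'
#' @param omega PSD latent covariance.
#' @param p number of samples.
#' @param seed optional integer seed.
#' @return A `p x d` matrix of draws from `N(0, omega)`.
#' @export
sample_gaussian_latents <- function(omega, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  omega <- as.matrix(omega)
  root <- sqrt_sym(omega)
  matrix(stats::rnorm(p * nrow(omega)), nrow = p) %*% root
}

#' Linear code specification
#'
#' Describes a linear population code: either an explicit `n x d` mixing
#' matrix `A` (responses `x = A z` plus optional isotropic Gaussian noise)
#' or a whitening transform `x = omega^{-1/2} z` (which equalizes latent
#' variance across coding directions). The two are mutually exclusive.
#'
#' @param a_matrix explicit `n x d` mixing matrix, or `NULL`.
#' @param whiten use the whitening transform instead of a mixing matrix.
#' @param noise_sigma standard deviation of additive isotropic response
#'   noise (default 0).
#' @param omega latent covariance used for whitening; if `NULL`, the sample
#'   covariance of the latents passed to [apply_code()] is used.
#' @return A `linear_code_spec`.
#' @export
linear_code_spec <- function(a_matrix = NULL, whiten = FALSE,
                             noise_sigma = 0, omega = NULL) {
  if (whiten && !is.null(a_matrix)) {
    stop("whitening and an explicit mixing matrix are mutually exclusive")
  }
  if (!whiten && is.null(a_matrix)) {
    stop("provide a mixing matrix or set whiten = TRUE")
  }
  stopifnot(noise_sigma >= 0)
  structure(list(a_matrix = if (!is.null(a_matrix)) as.matrix(a_matrix),
                 whiten = whiten, noise_sigma = noise_sigma,
                 omega = if (!is.null(omega)) as.matrix(omega)),
            class = "linear_code_spec")
}

#' Random Gaussian mixing matrix
#'
#' An `n x d` matrix with i.i.d. standard Gaussian entries, the mixing
#' matrix of the random linear code `x = A z`.
#'
#' @param n units. @param d latents. @param seed optional seed.
#' @return An `n x d` matrix.
#' @export
random_mixing_matrix <- function(n, d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rnorm(n * d), n, d)
}

#' Exact covariance triple of a linear code
#'
#' For `x = A z + eps` with `eps ~ N(0, sigma^2 I)` and `z ~ N(0, omega)`,
#' the covariance triple is `psi = A omega A^T + sigma^2 I`,
#' `phi = A omega`. For the whitening map `A = omega^{-1/2}`.
#'
#' @param spec a [linear_code_spec()] (whitening specs must carry `omega`).
#' @param omega latent covariance.
#' @return A [gaussian_code()].
#' @export
linear_code_covariances <- function(spec, omega) {
  stopifnot(inherits(spec, "linear_code_spec"))
  omega <- as.matrix(omega)
  a <- if (spec$whiten) pinv_sym(sqrt_sym(omega)) else spec$a_matrix
  psi <- a %*% omega %*% t(a) + spec$noise_sigma^2 * diag(nrow(a))
  gaussian_code(psi, a %*% omega, omega, check = FALSE)
}

#' Multilayer-perceptron code specification
#'
#' Describes a feedforward nonlinear code for latent variables: a
#' perceptron whose hidden widths each default to twice the previous width
#' (so the representation dimension never shrinks), with ReLU or tanh
#' activations. Untrained ("random") networks are linear-activation stacks
#' with Gaussian weights scaled by `1/sqrt(fan-in)`; trained networks are
#' built with [train_multitask_mlp()], which adds batch normalization and
#' per-task readouts.
#'
#' @param widths hidden-layer widths; if `NULL`, the default expansion rule
#'   `input_dim * 2^(1:n_layers)` is applied when the network is built.
#' @param n_layers number of hidden layers under the default rule.
#' @param nonlinearity `"relu"` or `"tanh"`.
#' @param seed optional integer seed for the weights.
#' @param trained whether this spec describes a trained network.
#' @param train_settings list of training hyperparameters; see
#'   [train_multitask_mlp()].
#' @return An `mlp_spec`.
#' @export
mlp_spec <- function(widths = NULL, n_layers = 3,
                     nonlinearity = c("relu", "tanh"), seed = NULL,
                     trained = FALSE, train_settings = list()) {
  nonlinearity <- match.arg(nonlinearity)
  if (!is.null(widths) && any(diff(widths) < 0)) {
    warning("hidden widths decrease; representation dimension may shrink")
  }
  structure(list(widths = widths, n_layers = n_layers,
                 nonlinearity = nonlinearity, seed = seed, trained = trained,
                 train_settings = train_settings),
            class = "mlp_spec")
}

default_widths <- function(input_dim, n_layers) input_dim * 2^seq_len(n_layers)

#' Random (untrained) MLP network
#'
#' Builds a perceptron with Gaussian weights (standard deviation
#' `1/sqrt(fan-in)`) and zero biases. Each layer is a linear transform
#' followed by the nonlinearity.
#'
#' @param input_dim input dimension.
#' @param spec an [mlp_spec()] (its `widths`/`seed`/`nonlinearity` are used).
#' @return An `mlp_network` usable with [mlp_forward()].
#' @export
random_mlp <- function(input_dim, spec = mlp_spec()) {
  stopifnot(inherits(spec, "mlp_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  widths <- spec$widths %||% default_widths(input_dim, spec$n_layers)
  dims <- c(input_dim, widths)
  weights <- lapply(seq_along(widths), function(l) {
    matrix(stats::rnorm(dims[l] * dims[l + 1], sd = 1 / sqrt(dims[l])),
           dims[l], dims[l + 1])
  })
  structure(list(weights = weights,
                 biases = lapply(widths, function(w) numeric(w)),
                 nonlinearity = spec$nonlinearity,
                 batchnorm = NULL),
            class = "mlp_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

activation <- function(h, kind) {
  switch(kind, relu = pmax(h, 0), tanh = tanh(h))
}

#' Forward pass through an MLP, returning every stage
#'
#' Evaluates a random or trained network on a matrix of inputs and returns
#' the representation after every linear stage and every nonlinearity
#' stage. Trained networks are evaluated in inference mode: batch
#' normalization uses the running statistics frozen at training time, so
#' representations are deterministic functions of the inputs.
#'
#' @param net an `mlp_network` ([random_mlp()]) or `trained_mlp`
#'   ([train_multitask_mlp()]).
#' @param Z input matrix (`samples x input_dim`).
#' @param layers return all stages (`TRUE`, default) or only the final
#'   representation.
#' @return A named list of matrices (`lin1`, `act1`, `lin2`, ...) or a
#'   single matrix.
#' @export
mlp_forward <- function(net, Z, layers = TRUE) {
  Z <- as.matrix(Z)
  stages <- list()
  h <- Z
  for (l in seq_along(net$weights)) {
    h <- h %*% net$weights[[l]] + rep(net$biases[[l]], each = nrow(h))
    if (!is.null(net$batchnorm)) {
      bn <- net$batchnorm[[l]]
      h <- sweep(h, 2, bn$mean, "-")
      h <- sweep(h, 2, sqrt(bn$var + 1e-5), "/")
      h <- sweep(sweep(h, 2, bn$gamma, "*"), 2, bn$beta, "+")
    }
    stages[[paste0("lin", l)]] <- h
    h <- activation(h, net$nonlinearity)
    stages[[paste0("act", l)]] <- h
  }
  if (layers) stages else h
}

#' Apply a code specification to latent samples
#'
#' Maps a `p x d` latent matrix through a linear or MLP code.
#' * Linear specs return a `p x n` response matrix (`x = A z + noise`, or
#'   the whitening transform).
#' * MLP specs build the random network implied by the spec and return the
#'   full list of per-layer representations (see [mlp_forward()]); to reuse
#'   one network across several latent sets, build it once with
#'   [random_mlp()] and call [mlp_forward()] directly.
#'
#' @param Z latent matrix.
#' @param spec a [linear_code_spec()] or [mlp_spec()].
#' @param seed optional seed for response noise.
#' @return A response matrix, or a named list of per-layer matrices.
#' @export
apply_code <- function(Z, spec, seed = NULL) {
  Z <- as.matrix(Z)
  if (inherits(spec, "linear_code_spec")) {
    if (spec$whiten) {
      omega <- spec$omega %||% stats::cov(Z)
      x <- Z %*% pinv_sym(sqrt_sym(omega))
    } else {
      if (ncol(spec$a_matrix) != ncol(Z)) stop("mixing matrix width mismatch")
      x <- Z %*% t(spec$a_matrix)
    }
    if (spec$noise_sigma > 0) {
      if (!is.null(seed)) set.seed(seed)
      x <- x + matrix(stats::rnorm(length(x), sd = spec$noise_sigma),
                      nrow(x), ncol(x))
    }
    return(x)
  }
  if (inherits(spec, "mlp_spec")) {
    if (spec$trained) {
      stop("trained networks are built with train_multitask_mlp(); ",
           "pass the result to mlp_forward()")
    }
    net <- random_mlp(ncol(Z), spec)
    return(mlp_forward(net, Z, layers = TRUE))
  }
  stop("unknown code specification")
}

# ---- trained multitask MLP (hidden-manifold style) -------------------------

adam_state <- function(shape) {
  list(m = array(0, dim = shape), v = array(0, dim = shape), t = 0)
}

adam_step <- function(state, grad, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$delta <- lr * mhat / (sqrt(vhat) + eps)
  state
}

#' Train a multitask MLP on binary shattering tasks
#'
#' Trains a three-hidden-layer perceptron of linear-batchnorm-ReLU blocks
#' with one linear readout per task from the shared penultimate (last
#' hidden) layer, on labels produced by randomly shattering the latent
#' space. Optimization is minibatch gradient descent with adaptive moment
#' estimation (Adam) on the task-averaged logistic loss, for `epochs`
#' passes over the data (default one). Batch-normalization statistics are
#' accumulated as running averages during training and frozen for
#' evaluation, so [mlp_forward()] on the result is deterministic.
#'
#' @param Z_train `samples x input_dim` training inputs (typically the
#'   output of a random MLP applied to Gaussian latents — the hidden
#'   manifold construction — but any matrix works).
#' @param Y_train `samples x n_tasks` label matrix in `{-1, +1}` (e.g. from
#'   [make_labels()] applied to the underlying latents).
#' @param widths hidden widths; default doubles the input dimension per
#'   layer.
#' @param nonlinearity `"relu"` or `"tanh"`.
#' @param epochs passes over the data (default 1).
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param seed optional integer seed (weight init + batch shuffling).
#' @return A `trained_mlp` (usable with [mlp_forward()]) with extra fields
#'   `readout` (weights, biases), `loss_trace` (per-batch loss) and
#'   `diverged` flag. A non-finite loss aborts with an error.
#' @export
train_multitask_mlp <- function(Z_train, Y_train, widths = NULL,
                                nonlinearity = "relu", epochs = 1,
                                batch_size = 128, lr = 1e-3, seed = NULL) {
  Z_train <- as.matrix(Z_train)
  Y_train <- as.matrix(Y_train)
  stopifnot(nrow(Z_train) == nrow(Y_train))
  if (nonlinearity != "relu") {
    stop("trained networks currently support the relu nonlinearity only")
  }
  if (!is.null(seed)) set.seed(seed)
  input_dim <- ncol(Z_train)
  n_tasks <- ncol(Y_train)
  widths <- widths %||% default_widths(input_dim, 3)
  n_layers <- length(widths)
  dims <- c(input_dim, widths)

  w <- lapply(seq_len(n_layers), function(l) {
    matrix(stats::rnorm(dims[l] * dims[l + 1], sd = 1 / sqrt(dims[l])),
           dims[l], dims[l + 1])
  })
  b <- lapply(widths, function(m) numeric(m))
  gamma <- lapply(widths, function(m) rep(1, m))
  beta <- lapply(widths, function(m) numeric(m))
  run_mean <- lapply(widths, function(m) numeric(m))
  run_var <- lapply(widths, function(m) rep(1, m))
  wr <- matrix(stats::rnorm(widths[n_layers] * n_tasks,
                            sd = 1 / sqrt(widths[n_layers])),
               widths[n_layers], n_tasks)
  br <- numeric(n_tasks)

  st <- list(w = lapply(w, function(x) adam_state(dim(x))),
             b = lapply(b, function(x) adam_state(length(x))),
             gamma = lapply(gamma, function(x) adam_state(length(x))),
             beta = lapply(beta, function(x) adam_state(length(x))),
             wr = adam_state(dim(wr)), br = adam_state(length(br)))

  momentum <- 0.1
  eps_bn <- 1e-5
  p <- nrow(Z_train)
  loss_trace <- numeric(0)

  for (ep in seq_len(epochs)) {
    order <- sample.int(p)
    starts <- seq(1, p, by = batch_size)
    for (s in starts) {
      idx <- order[s:min(s + batch_size - 1, p)]
      nb <- length(idx)
      if (nb < 2) next  # batch statistics undefined for a single sample
      zb <- Z_train[idx, , drop = FALSE]
      yb <- Y_train[idx, , drop = FALSE]

      # forward
      h <- vector("list", n_layers)    # pre-batchnorm
      hat <- vector("list", n_layers)  # normalized
      out <- vector("list", n_layers)  # post-affine (pre-relu)
      act <- vector("list", n_layers)
      sd_b <- vector("list", n_layers)
      a_prev <- zb
      for (l in seq_len(n_layers)) {
        h[[l]] <- a_prev %*% w[[l]] + rep(b[[l]], each = nb)
        mu <- colMeans(h[[l]])
        va <- colMeans(sweep(h[[l]], 2, mu, "-")^2)
        sd_b[[l]] <- sqrt(va + eps_bn)
        hat[[l]] <- sweep(sweep(h[[l]], 2, mu, "-"), 2, sd_b[[l]], "/")
        out[[l]] <- sweep(sweep(hat[[l]], 2, gamma[[l]], "*"), 2, beta[[l]], "+")
        act[[l]] <- pmax(out[[l]], 0)
        run_mean[[l]] <- (1 - momentum) * run_mean[[l]] + momentum * mu
        run_var[[l]] <- (1 - momentum) * run_var[[l]] + momentum * va
        a_prev <- act[[l]]
      }
      scores <- a_prev %*% wr + rep(br, each = nb)

      # task-averaged logistic loss: mean softplus(-y * score)
      m_ys <- yb * scores
      loss <- mean(log1p(exp(-abs(m_ys))) + pmax(-m_ys, 0))
      if (!is.finite(loss)) stop("training diverged: non-finite loss")
      loss_trace <- c(loss_trace, loss)

      dscore <- -yb * stats::plogis(-m_ys) / (nb * n_tasks)
      g_wr <- crossprod(a_prev, dscore)
      g_br <- colSums(dscore)
      dact <- tcrossprod(dscore, wr)  # wrt act[[n_layers]]

      for (l in rev(seq_len(n_layers))) {
        dout <- dact * (out[[l]] > 0)
        g_gamma <- colSums(dout * hat[[l]])
        g_beta <- colSums(dout)
        dhat <- sweep(dout, 2, gamma[[l]], "*")
        # batchnorm backward
        sum_dhat <- colSums(dhat)
        sum_dhat_hat <- colSums(dhat * hat[[l]])
        dh <- sweep(
          nb * dhat -
            rep(sum_dhat, each = nb) -
            hat[[l]] * rep(sum_dhat_hat, each = nb),
          2, nb * sd_b[[l]], "/")
        a_in <- if (l == 1) zb else act[[l - 1]]
        g_w <- crossprod(a_in, dh)
        g_b <- colSums(dh)
        if (l > 1) dact <- tcrossprod(dh, w[[l]])

        st$w[[l]] <- adam_step(st$w[[l]], g_w, lr)
        w[[l]] <- w[[l]] - st$w[[l]]$delta
        st$b[[l]] <- adam_step(st$b[[l]], g_b, lr)
        b[[l]] <- b[[l]] - st$b[[l]]$delta
        st$gamma[[l]] <- adam_step(st$gamma[[l]], g_gamma, lr)
        gamma[[l]] <- gamma[[l]] - st$gamma[[l]]$delta
        st$beta[[l]] <- adam_step(st$beta[[l]], g_beta, lr)
        beta[[l]] <- beta[[l]] - st$beta[[l]]$delta
      }
      st$wr <- adam_step(st$wr, g_wr, lr)
      wr <- wr - st$wr$delta
      st$br <- adam_step(st$br, g_br, lr)
      br <- br - st$br$delta
    }
  }

  structure(list(
    weights = w, biases = b,
    batchnorm = lapply(seq_len(n_layers), function(l) {
      list(mean = run_mean[[l]], var = run_var[[l]],
           gamma = gamma[[l]], beta = beta[[l]])
    }),
    nonlinearity = "relu",
    readout = list(weights = wr, biases = br),
    loss_trace = loss_trace,
    diverged = FALSE
  ), class = c("trained_mlp", "mlp_network"))
}

#' Predict task labels with the trained network's own readouts
#'
#' @param net a `trained_mlp`.
#' @param Z input matrix.
#' @return Matrix of predictions in `{-1, +1}` (`samples x n_tasks`).
#' @export
mlp_predict_tasks <- function(net, Z) {
  stopifnot(inherits(net, "trained_mlp"))
  h <- mlp_forward(net, Z, layers = FALSE)
  sign_pos(h %*% net$readout$weights + rep(net$readout$biases, each = nrow(h)))
}

#' Estimate a covariance triple from paired samples
#'
#' Centers `X` and `Z` column-wise and returns the sample covariance triple
#' with `1/(p-1)` normalization. The joint sample covariance is PSD by
#' construction.
#'
#' @param X `p x n` response matrix.
#' @param Z `p x d` latent matrix.
#' @return A [gaussian_code()].
#' @export
estimate_covariances <- function(X, Z) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  if (nrow(X) != nrow(Z)) stop("X and Z must have the same number of rows")
  p <- nrow(X)
  if (p < 2) stop("need at least 2 samples to estimate covariances")
  xc <- scale(X, center = TRUE, scale = FALSE)
  zc <- scale(Z, center = TRUE, scale = FALSE)
  gaussian_code(crossprod(xc) / (p - 1),
                crossprod(xc, zc) / (p - 1),
                crossprod(zc) / (p - 1),
                check = FALSE)
}

#' Random Gaussian projections of a response matrix
#'
#' Projects responses down to a fixed dimensionality to aid comparisons
#' between representations of different sizes; downstream metrics are
#' typically averaged over the projections.
#'
#' @param X `p x n` matrix.
#' @param target_dim projection dimension, `<= n`.
#' @param n_projections number of independent projections.
#' @param orthogonalize orthonormalize each projection matrix (an
#'   orthonormal square projection preserves all metrics).
#' @param seed optional integer seed.
#' @return A list of `p x target_dim` matrices.
#' @export
random_projection <- function(X, target_dim, n_projections = 20,
                              orthogonalize = FALSE, seed = NULL) {
  X <- as.matrix(X)
  n <- ncol(X)
  if (target_dim > n) stop("target_dim must not exceed the number of columns")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_projections), function(i) {
    pm <- matrix(stats::rnorm(n * target_dim), n, target_dim) / sqrt(target_dim)
    if (orthogonalize) pm <- qr.Q(qr(pm))
    X %*% pm
  })
}

#' Column z-scoring with a standard-deviation floor
#'
#' Centers each column and divides by its standard deviation plus
#' `sd_floor`. A positive floor prevents very quiet units from being
#' massively overweighted (and makes constant columns map to zero rather
#' than dividing by zero).
#'
#' @param M numeric matrix.
#' @param sd_floor non-negative regularizer added to each column sd
#'   (default 0).
#' @return The standardized matrix.
#' @export
zscore_columns <- function(M, sd_floor = 0) {
  M <- as.matrix(M)
  if (nrow(M) < 2) stop("need at least 2 rows")
  stopifnot(sd_floor >= 0)
  mu <- colMeans(M)
  sdv <- apply(M, 2, stats::sd) + sd_floor
  if (any(sdv == 0)) stop("constant column with sd_floor = 0; use a positive floor")
  sweep(sweep(M, 2, mu, "-"), 2, sdv, "/")
}

#' Write a generated dataset as delimited text with a JSON manifest
#'
#' @param X,Z,Y matrices (any may be `NULL`).
#' @param prefix file path prefix.
#' @param manifest named list (specs, seeds) stored alongside.
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(X = NULL, Z = NULL, Y = NULL, prefix,
                          manifest = list()) {
  files <- list()
  wt <- function(m, suffix) {
    path <- paste0(prefix, suffix)
    utils::write.table(m, path, sep = "\t", row.names = FALSE, col.names = FALSE)
    basename(path)
  }
  if (!is.null(X)) files$X <- wt(X, "_X.tsv")
  if (!is.null(Z)) files$Z <- wt(Z, "_Z.tsv")
  if (!is.null(Y)) files$Y <- wt(Y, "_Y.tsv")
  manifest_path <- paste0(prefix, "_manifest.json")
  jsonlite::write_json(c(list(files = files), manifest), manifest_path,
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest_path)
}
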