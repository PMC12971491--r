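#' Configuration for a reproducible synthetic experiment
#'
#' Bundles all generator, readout and optimizer parameters for one of the
#' three built-in synthetic experiments, together with a single top-level
#' seed. The seed is expanded into independent child seeds for each
#' stochastic component via [child_seeds()], so identical configurations
#' reproduce all stochastic outputs exactly.
#'
#' @param experiment `"gaussian"` (theory vs Monte-Carlo readout over a power-law
#'   grid), `"mlp"` (layer-wise geometry of random and trained multitask
#'   perceptrons) or `"optimal"` (closed-form vs numerically optimized
#'   codes).
#' @param seed integer seed.
#' @param output_dir optional directory; when given, results are written as
#'   CSV with a JSON manifest and a plain-text log.
#' @param ... parameter overrides; see Details for per-experiment defaults.
#'
#' @details Defaults follow the study protocols: the Gaussian experiment
#' uses `n = 80` units, `d = 40` latents with eigenvalues `5 i^-alpha` for
#' `alpha` in `{0, 0.5, 1}`, 300 tasks, 1000 test points and 30 repeats
#' over `p` in `{20, 50, 100, 300}`; the MLP experiment uses the desk-scale
#' profile (`d = 20`, `2e4` training samples, 100 training tasks, one
#' epoch) with evaluation on 1000 fresh latents and 300 fresh tasks at
#' `p = 300` (the full-scale profile `d = 40`, `5e5` samples, 500 tasks is
#' available by override); the optimal-code experiment uses `d = 5`,
#' `n = 10`, `p` in `{5, 50, 500}` on a `5 i^-1` latent spectrum.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(experiment = c("gaussian", "mlp", "optimal"),
                              seed = 1, output_dir = NULL, ...) {
  name <- match.arg(experiment)
  defaults <- switch(name,
    gaussian = list(n = 80, d = 40, scale = 5, alphas = c(0, 0.5, 1),
                    p_grid = c(20, 50, 100, 300), n_tasks = 300,
                    n_test = 1000, n_repeats = 30,
                    code_types = c("linear", "whitened")),
    mlp = list(d = 20, alpha = 0.2, scale = 1, n_train = 2e4,
               n_tasks_train = 100, widths_random = NULL,
               widths_trained = NULL, epochs = 1, batch_size = 128,
               lr = 1e-3, n_eval = 1000, n_tasks_eval = 300, p_eval = 300,
               n_splits = 5),
    optimal = list(d = 5, n = 10, alpha = 1, scale = 5,
                   p_grid = c(5, 50, 500), n_restarts = 5))
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown parameter(s) for the ", name, " experiment: ",
         paste(unknown, collapse = ", "))
  }
  params <- utils::modifyList(defaults, overrides)
  structure(list(name = name, seed = as.integer(seed),
                 output_dir = output_dir, params = params),
            class = "experiment_config")
}

#' Expand one seed into independent child seeds
#'
#' Seeds the base generator with `seed` and draws `n` integers uniformly
#' from `[1, 2^31 - 2]`. Components seeded with distinct children are
#' statistically independent, and the expansion is itself deterministic.
#'
#' @param seed integer seed.
#' @param n number of child seeds.
#' @return An integer vector of length `n`.
#' @export
child_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

finish_experiment <- function(config, tables) {
  result <- structure(list(config = config, tables = tables),
                      class = "experiment_result")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables)) {
      utils::write.csv(tables[[nm]],
                       file.path(config$output_dir,
                                 paste0(config$name, "_", nm, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      list(experiment = config$name, seed = config$seed,
           params = config$params, r_version = R.version.string,
           tables = names(tables)),
      file.path(config$output_dir, paste0(config$name, "_manifest.json")),
      auto_unbox = TRUE, digits = NA, null = "null")
  }
  result
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result: %s> seed = %d\n", x$config$name,
              x$config$seed))
  for (nm in names(x$tables)) {
    cat(sprintf("  $tables$%s: %d rows\n", nm, nrow(x$tables[[nm]])))
  }
  invisible(x)
}

#' Gaussian theory-versus-simulation experiment
#'
#' For every cell of the (alpha, code type, p) grid: builds the exact
#' covariance triple of the code (random linear mixing `x = A z` with the
#' mixing matrix drawn once per alpha, or the whitening transform), computes
#' the closed-form error prediction, and estimates the empirical
#' task-averaged Hebbian error by Monte Carlo with fresh tasks, training and
#' test sets per repeat.
#'
#' @param config an [experiment_config()] with `name = "gaussian"`.
#' @return An `experiment_result`; `$tables$errors` has columns `alpha`,
#'   `code`, `p`, `mc_error`, `sem`, `theory`.
#' @export
run_gaussian_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"), config$name == "gaussian")
  pr <- config$params
  seeds <- child_seeds(config$seed,
                       2 * length(pr$alphas) * length(pr$code_types) *
                         length(pr$p_grid) + length(pr$alphas))
  si <- 0L
  next_seed <- function() { si <<- si + 1L; seeds[si] }
  rows <- list()
  for (alpha in pr$alphas) {
    omega <- power_law_omega(pr$d, alpha, pr$scale)
    a <- random_mixing_matrix(pr$n, pr$d, seed = next_seed())
    for (ct in pr$code_types) {
      spec <- if (ct == "whitened") {
        linear_code_spec(whiten = TRUE, omega = omega)
      } else {
        linear_code_spec(a_matrix = a)
      }
      code <- linear_code_covariances(spec, omega)
      for (p in pr$p_grid) {
        mc <- monte_carlo_error(code, p, n_tasks = pr$n_tasks,
                                n_test = pr$n_test,
                                n_repeats = pr$n_repeats,
                                seed = next_seed())
        sem <- if (pr$n_repeats > 1) mc$sem else NA_real_
        rows[[length(rows) + 1]] <- data.frame(
          alpha = alpha, code = ct, p = p,
          mc_error = mc$mean, sem = sem, theory = mc$theory)
      }
    }
  }
  finish_experiment(config, list(errors = do.call(rbind, rows)))
}

# Geometry + theoretical and empirical error of one representation.
layer_metrics <- function(X, Z_eval, Y_eval, p_eval, n_splits, split_seed) {
  code <- estimate_covariances(X, Z_eval)
  g <- geometry_summary(code)
  theory <- theoretical_error(g, p_eval)$e_g
  set.seed(split_seed)
  n <- nrow(X)
  errs <- vapply(seq_len(n_splits), function(i) {
    tr_idx <- sample.int(n, p_eval)
    xc <- scale(X, center = TRUE, scale = FALSE)
    w <- hebbian_weights(xc[tr_idx, , drop = FALSE],
                         Y_eval[tr_idx, , drop = FALSE])
    pred <- hebbian_predict(w, xc[-tr_idx, , drop = FALSE])
    mean(pred != Y_eval[-tr_idx, , drop = FALSE])
  }, numeric(1))
  data.frame(n = ncol(X), c = g$c, pr = g$pr, f = g$f, s = g$s,
             theory_eg = theory, empirical_eg = mean(errs),
             sem = if (n_splits > 1) stats::sd(errs) / sqrt(n_splits) else NA_real_)
}

#' Layer-wise geometry of random and trained multitask MLPs
#'
#' Hidden-manifold protocol: Gaussian latents with a shallow power-law
#' spectrum are passed through a random expanding MLP; its outputs and the
#' labels of randomly drawn shattering tasks train a three-hidden-layer
#' batchnorm-ReLU network with per-task readouts for one epoch. Fresh
#' latents and fresh tasks are then used to compute, at every linear and
#' ReLU stage of both networks, the four geometric statistics, the
#' theoretical error at `p_eval`, and the empirical Hebbian error on random
#' train/test splits of the evaluation set.
#'
#' @param config an [experiment_config()] with `name = "mlp"`.
#' @return An `experiment_result`; `$tables$layers` has one row per
#'   (network, stage) with the metrics above, plus `$tables$training`
#'   (per-batch loss) and `$tables$readout` (held-out accuracy of the
#'   trained network's own task readouts).
#' @export
run_mlp_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"), config$name == "mlp")
  pr <- config$params
  s <- child_seeds(config$seed, 7)
  omega <- power_law_omega(pr$d, pr$alpha, pr$scale)

  z_train <- sample_gaussian_latents(omega, pr$n_train, seed = s[1])
  random_net <- random_mlp(pr$d, mlp_spec(widths = pr$widths_random, seed = s[2]))
  x_train <- mlp_forward(random_net, z_train, layers = FALSE)
  battery_train <- sample_tasks(pr$d, pr$n_tasks_train, seed = s[3])
  y_train <- make_labels(z_train, battery_train)
  trained_net <- train_multitask_mlp(x_train, y_train,
                                     widths = pr$widths_trained,
                                     epochs = pr$epochs,
                                     batch_size = pr$batch_size,
                                     lr = pr$lr, seed = s[4])

  z_eval <- sample_gaussian_latents(omega, pr$n_eval, seed = s[5])
  battery_eval <- sample_tasks(pr$d, pr$n_tasks_eval, seed = s[6])
  y_eval <- make_labels(z_eval, battery_eval)

  random_stages <- c(list(input = z_eval), mlp_forward(random_net, z_eval))
  x_eval_trained_input <- mlp_forward(random_net, z_eval, layers = FALSE)
  trained_stages <- c(list(input = x_eval_trained_input),
                      mlp_forward(trained_net, x_eval_trained_input))

  split_seeds <- child_seeds(s[7], length(random_stages) + length(trained_stages))
  rows <- list()
  k <- 0L
  for (net in c("random", "trained")) {
    stages <- if (net == "random") random_stages else trained_stages
    for (i in seq_along(stages)) {
      k <- k + 1L
      m <- layer_metrics(stages[[i]], z_eval, y_eval, pr$p_eval,
                         pr$n_splits, split_seeds[k])
      rows[[k]] <- cbind(data.frame(network = net, stage = names(stages)[i],
                                    stage_index = i - 1L), m)
    }
  }

  # held-out accuracy of the network's own readouts, on its training tasks
  pred <- mlp_predict_tasks(trained_net, x_eval_trained_input)
  readout_acc <- mean(pred == make_labels(z_eval, battery_train))
  finish_experiment(config, list(
    layers = do.call(rbind, rows),
    training = data.frame(batch = seq_along(trained_net$loss_trace),
                          loss = trained_net$loss_trace),
    readout = data.frame(heldout_accuracy = readout_acc,
                         n_eval = pr$n_eval,
                         n_tasks = pr$n_tasks_eval)))
}

#' Closed-form versus numerically optimized codes
#'
#' For each sample budget in the grid: computes the closed-form optimal
#' spectrum, runs the PSD-parameterized numerical optimizer, and records
#' both spectra (trace-normalized, sorted) together with the alignment
#' between the right singular vectors of the optimized cross-covariance and
#' the latent eigenvectors. Also tabulates the geometry curve of the
#' closed-form code across the grid.
#'
#' @param config an [experiment_config()] with `name = "optimal"`.
#' @return An `experiment_result` with tables `spectra` (columns `p`,
#'   `index`, `psi_closed`, `psi_numerical`, `align_cos`, `converged`) and
#'   `geometry` (the [optimal_geometry_curve()] table).
#' @export
run_optimal_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"), config$name == "optimal")
  pr <- config$params
  omega <- power_law_omega(pr$d, pr$alpha, pr$scale)
  eo <- eigen(omega, symmetric = TRUE)
  seeds <- child_seeds(config$seed, length(pr$p_grid))
  rows <- list()
  for (i in seq_along(pr$p_grid)) {
    p <- pr$p_grid[i]
    closed <- optimal_spectrum(eo$values, p)
    psi_closed <- closed$psi_values / sum(closed$psi_values)
    num_code <- numerical_optimal_code(omega, p, pr$n,
                                       n_restarts = pr$n_restarts,
                                       seed = seeds[i])
    diag_ <- attr(num_code, "diagnostics")
    psi_num <- sort(eigen(num_code$psi, symmetric = TRUE,
                          only.values = TRUE)$values,
                    decreasing = TRUE)[seq_len(pr$d)]
    psi_num <- psi_num / sum(psi_num)
    sv <- svd(num_code$phi)
    align <- abs(colSums(sv$v[, seq_len(pr$d), drop = FALSE] * eo$vectors))
    rows[[i]] <- data.frame(p = p, index = seq_len(pr$d),
                            psi_closed = psi_closed,
                            psi_numerical = psi_num,
                            align_cos = align,
                            converged = diag_$converged)
  }
  finish_experiment(config, list(
    spectra = do.call(rbind, rows),
    geometry = optimal_geometry_curve(omega, pr$p_grid, pr$n)))
}

#' Run a named experiment
#'
#' @param config an [experiment_config()].
#' @return An `experiment_result`.
#' @export
run_experiment <- function(config) {
  switch(config$name,
         gaussian = run_gaussian_experiment(config),
         mlp = run_mlp_experiment(config),
         optimal = run_optimal_experiment(config))
}
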