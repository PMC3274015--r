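#' Three-layer feed-forward network configuration
#'
#' Fixes the `n1:n2:n3` topology of the classifier: `n_in` input neurons
#' (the feature dimension), `n_hidden` log-sigmoid hidden neurons, and
#' `n_out` linear output neurons (one per motion class, one-hot target
#' coding).
#'
#' @param n_in,n_hidden,n_out Positive integer layer sizes.
#' @return An object of class `network_config`.
#' @examples
#' network_config(12, 8, 8)
#' @export
network_config <- function(n_in, n_hidden, n_out = 8L) {
  cfg <- list(n_in = as.integer(n_in), n_hidden = as.integer(n_hidden),
              n_out = as.integer(n_out))
  if (any(vapply(cfg, function(v) is.na(v) || v < 1L, logical(1)))) {
    abort("all layer sizes must be positive integers.")
  }
  class(cfg) <- "network_config"
  cfg
}

#' @export
format.network_config <- function(x, ...) {
  paste(x$n_in, x$n_hidden, x$n_out, sep = ":")
}

#' @export
print.network_config <- function(x, ...) {
  cat("<network_config> ", format(x), "\n", sep = "")
  invisible(x)
}

n_params <- function(cfg) {
  cfg$n_hidden * cfg$n_in + cfg$n_hidden + cfg$n_out * cfg$n_hidden + cfg$n_out
}

#' Levenberg--Marquardt training options
#'
#' Hyperparameters of the damped Gauss--Newton loop: the damping parameter
#' `lambda` starts at `lambda_init`, is multiplied by `lambda_up` after a
#' rejected step and by `lambda_down` after an accepted one; training stops
#' when the mean squared error reaches `goal_mse`, after `max_epochs`
#' accepted epochs, or when `lambda` exceeds `max_lambda`.
#'
#' @param lambda_init,lambda_up,lambda_down,max_lambda Damping schedule
#'   (`lambda_up > 1 > lambda_down > 0`).
#' @param max_epochs Maximum number of accepted update steps.
#' @param goal_mse Target mean squared error (per pattern per output).
#' @return An object of class `training_options`.
#' @export
training_options <- function(lambda_init = 1e-3, lambda_up = 10,
                             lambda_down = 0.1, max_lambda = 1e10,
                             max_epochs = 200L, goal_mse = 1e-4) {
  stopifnot(lambda_up > 1, lambda_down > 0, lambda_down < 1,
            max_epochs >= 1, lambda_init > 0, max_lambda > lambda_init)
  structure(
    list(lambda_init = lambda_init, lambda_up = lambda_up,
         lambda_down = lambda_down, max_lambda = max_lambda,
         max_epochs = as.integer(max_epochs), goal_mse = goal_mse),
    class = "training_options"
  )
}

#' Initialize network weights
#'
#' Weights are drawn uniformly from `[-a, a]` with
#' `a = sqrt(6 / (fan_in + fan_out))` per layer; biases start at zero.
#'
#' @param config A [network_config()].
#' @param seed Integer seed; initialization is deterministic given
#'   `(config, seed)`.
#' @return An object of class `mlp_network` with weight matrices `W1`
#'   (`n_hidden x n_in`), `W2` (`n_out x n_hidden`) and bias vectors `b1`,
#'   `b2`.
#' @export
init_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  with_local_seed(seed, {
    a1 <- sqrt(6 / (config$n_in + config$n_hidden))
    a2 <- sqrt(6 / (config$n_hidden + config$n_out))
    net <- list(
      W1 = matrix(runif(config$n_hidden * config$n_in, -a1, a1),
                  config$n_hidden, config$n_in),
      b1 = numeric(config$n_hidden),
      W2 = matrix(runif(config$n_out * config$n_hidden, -a2, a2),
                  config$n_out, config$n_hidden),
      b2 = numeric(config$n_out),
      config = config
    )
    class(net) <- "mlp_network"
    net
  })
}

logsig <- function(z) 1 / (1 + exp(-z))

#' Forward pass through the network
#'
#' Computes `h = logsig(W1 x + b1)` and the linear outputs
#' `y = W2 h + b2` for one or many input vectors.
#'
#' @param net An `mlp_network`.
#' @param x Numeric vector of length `n_in`, or a matrix with one pattern
#'   per row.
#' @return A list with `output` and `hidden` (matrices with one pattern per
#'   row; vectors for a single pattern input).
#' @export
mlp_forward <- function(net, x) {
  stopifnot(inherits(net, "mlp_network"))
  single <- is.null(dim(x))
  X <- if (single) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(X) != net$config$n_in) {
    abort(sprintf("input has %d columns but the network expects %d.",
                  ncol(X), net$config$n_in))
  }
  H <- logsig(sweep(X %*% t(net$W1), 2, net$b1, "+"))
  Y <- sweep(H %*% t(net$W2), 2, net$b2, "+")
  if (single) list(output = drop(Y), hidden = drop(H))
  else list(output = Y, hidden = H)
}

flatten_params <- function(net) {
  c(as.vector(net$W1), net$b1, as.vector(net$W2), net$b2)
}

unflatten_params <- function(theta, cfg) {
  i <- 0L
  take <- function(n) {
    out <- theta[(i + 1L):(i + n)]
    i <<- i + n
    out
  }
  net <- list(
    W1 = matrix(take(cfg$n_hidden * cfg$n_in), cfg$n_hidden, cfg$n_in),
    b1 = take(cfg$n_hidden),
    W2 = matrix(take(cfg$n_out * cfg$n_hidden), cfg$n_out, cfg$n_hidden),
    b2 = take(cfg$n_out),
    config = cfg
  )
  class(net) <- "mlp_network"
  net
}

# Residuals r (P*O vector, pattern-major) and analytic Jacobian of the
# residuals w.r.t. the flattened parameters (columns ordered as
# flatten_params). Residual r_{p,o} = y_o(x_p) - t_{p,o}.
mlp_residual_jacobian <- function(net, X, T, jacobian = TRUE) {
  cfg <- net$config
  P <- nrow(X)
  fw <- mlp_forward(net, X)
  H <- matrix(fw$hidden, nrow = P)
  Y <- matrix(fw$output, nrow = P)
  R <- Y - T
  r <- as.vector(t(R))  # pattern-major: (p1 o1..oO, p2 o1..oO, ...)
  if (!jacobian) return(list(r = r))
  nh <- cfg$n_hidden; ni <- cfg$n_in; no <- cfg$n_out
  npar <- n_params(cfg)
  J <- matrix(0, P * no, npar)
  Hprime <- H * (1 - H)  # logsig'
  col_W1 <- function(j, i) (i - 1L) * nh + j
  off_b1 <- nh * ni
  off_W2 <- off_b1 + nh
  col_W2 <- function(o, j) off_W2 + (j - 1L) * no + o
  off_b2 <- off_W2 + no * nh
  for (o in seq_len(no)) {
    rows <- (seq_len(P) - 1L) * no + o
    # d y_o / d W2[o, j] = h_j ; d y_o / d b2[o] = 1
    for (j in seq_len(nh)) J[cbind(rows, col_W2(o, j))] <- H[, j]
    J[cbind(rows, off_b2 + o)] <- 1
    # d y_o / d W1[j, i] = W2[o, j] h_j (1 - h_j) x_i
    for (j in seq_len(nh)) {
      gj <- net$W2[o, j] * Hprime[, j]
      J[cbind(rows, off_b1 + j)] <- gj
      for (i in seq_len(ni)) {
        J[cbind(rows, col_W1(j, i))] <- gj * X[, i]
      }
    }
  }
  list(r = r, J = J)
}

#' One-hot target coding
#'
#' @param labels Integer class labels in `1..n_out`.
#' @param n_out Number of classes.
#' @return A `length(labels) x n_out` matrix with exactly one 1 per row.
#' @export
one_hot <- function(labels, n_out = 8L) {
  labels <- as.integer(labels)
  if (any(is.na(labels)) || any(labels < 1L) || any(labels > n_out)) {
    abort(sprintf("labels must be integers in 1..%d.", n_out))
  }
  T <- matrix(0, length(labels), n_out)
  T[cbind(seq_along(labels), labels)] <- 1
  T
}

#' Train the network with the Levenberg--Marquardt algorithm
#'
#' Damped Gauss--Newton minimization of the sum of squared output errors:
#' each step solves `(J'J + lambda I) dw = J' e` with `J` the Jacobian of
#' all per-pattern per-output residuals with respect to every weight and
#' bias. A step is accepted only if it decreases the SSE (so the recorded
#' loss history is non-increasing); otherwise `lambda` is raised and the
#' step recomputed. Training stops at `goal_mse`, `max_epochs` accepted
#' steps, or when `lambda` exceeds `max_lambda`.
#'
#' @param net An initialized `mlp_network`.
#' @param X Pattern matrix (`patterns x n_in`).
#' @param T Target matrix from [one_hot()] (`patterns x n_out`).
#' @param opts A [training_options()].
#' @return An object of class `mlp_fit`: the trained `net`, `loss` (tibble
#'   of accepted-epoch SSE/MSE/lambda), `stopped` (reason), and the final
#'   `sse`/`mse`.
#' @export
lm_train <- function(net, X, T, opts = training_options()) {
  stopifnot(inherits(net, "mlp_network"), inherits(opts, "training_options"))
  X <- as.matrix(X)
  T <- as.matrix(T)
  if (nrow(X) < 1L) abort("at least one training pattern is required.")
  if (!all(is.finite(X)) || !all(is.finite(T))) {
    abort("training inputs and targets must be finite.")
  }
  cfg <- net$config
  theta <- flatten_params(net)
  lambda <- opts$lambda_init
  n_res <- nrow(X) * cfg$n_out

  rj <- mlp_residual_jacobian(net, X, T)
  sse <- sum(rj$r^2)
  history <- list(tibble::tibble(epoch = 0L, sse = sse, mse = sse / n_res,
                                 lambda = lambda))
  stopped <- "max_epochs"
  epoch <- 0L
  while (epoch < opts$max_epochs) {
    if (sse / n_res <= opts$goal_mse) {
      stopped <- "goal_mse"
      break
    }
    g <- crossprod(rj$J, rj$r)
    Hm <- crossprod(rj$J)
    accepted <- FALSE
    while (lambda <= opts$max_lambda) {
      step <- tryCatch(
        solve(Hm + diag(lambda, ncol(Hm)), g),
        error = function(e) NULL
      )
      if (!is.null(step)) {
        theta_new <- theta - as.vector(step)
        net_new <- unflatten_params(theta_new, cfg)
        r_new <- mlp_residual_jacobian(net_new, X, T, jacobian = FALSE)$r
        sse_new <- sum(r_new^2)
        if (!is.finite(sse_new)) {
          abort("non-finite training loss; inputs may be badly scaled.")
        }
        if (sse_new < sse) {
          theta <- theta_new
          net <- net_new
          sse <- sse_new
          lambda <- max(lambda * opts$lambda_down, 1e-20)
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * opts$lambda_up
    }
    if (!accepted) {
      stopped <- "max_lambda"
      break
    }
    epoch <- epoch + 1L
    history[[length(history) + 1L]] <-
      tibble::tibble(epoch = epoch, sse = sse, mse = sse / n_res,
                     lambda = lambda)
    rj <- mlp_residual_jacobian(net, X, T)
  }
  if (epoch >= opts$max_epochs) stopped <- "max_epochs"
  if (sse / n_res <= opts$goal_mse) stopped <- "goal_mse"

  structure(
    list(net = net, loss = dplyr::bind_rows(history), stopped = stopped,
         sse = sse, mse = sse / n_res, options = opts),
    class = "mlp_fit"
  )
}

#' Classify patterns with a trained network
#'
#' Applies the max-selection rule to the linear outputs: the predicted class
#' is the index of the maximal output neuron, ties broken toward the lowest
#' class index.
#'
#' @param object An `mlp_network` or `mlp_fit`.
#' @param x Feature vector or pattern matrix.
#' @param ... Unused.
#' @return Integer class labels.
#' @export
predict.mlp_network <- function(object, x, ...) {
  out <- mlp_forward(object, x)$output
  if (is.null(dim(out))) return(which.max(out))
  apply(out, 1, which.max)
}

#' @rdname predict.mlp_network
#' @export
predict.mlp_fit <- function(object, x, ...) predict(object$net, x, ...)

#' @export
print.mlp_fit <- function(x, ...) {
  cat("<mlp_fit> ", format(x$net$config), ", ", nrow(x$loss) - 1L,
      " accepted epochs, final MSE ", signif(x$mse, 4),
      " (stopped: ", x$stopped, ")\n", sep = "")
  invisible(x)
}

#' Tidy the training history of an LM fit
#'
#' @param x An `mlp_fit`.
#' @param ... Unused.
#' @return The accepted-epoch loss history as a tibble (`epoch`, `sse`,
#'   `mse`, `lambda`).
#' @export
tidy.mlp_fit <- function(x, ...) x$loss

#' One-row summary of an LM fit
#'
#' @param x An `mlp_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the topology, parameter count, epochs,
#'   final MSE and stopping reason.
#' @export
glance.mlp_fit <- function(x, ...) {
  tibble::tibble(
    complexity = format(x$net$config),
    n_parameters = n_params(x$net$config),
    epochs = nrow(x$loss) - 1L,
    mse = x$mse,
    sse = x$sse,
    stopped = x$stopped
  )
}

#' Serialize a network to JSON
#'
#' @param net An `mlp_network` or `mlp_fit`.
#' @param path JSON file path.
#' @return `write_network()` returns `path` invisibly; `read_network()` the
#'   restored `mlp_network`.
#' @export
write_network <- function(net, path) {
  if (inherits(net, "mlp_fit")) net <- net$net
  stopifnot(inherits(net, "mlp_network"))
  obj <- list(
    config = unclass(net$config),
    W1 = as.vector(net$W1), b1 = net$b1,
    W2 = as.vector(net$W2), b2 = net$b2
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- network_config(obj$config$n_in, obj$config$n_hidden,
                        obj$config$n_out)
  net <- list(
    W1 = matrix(obj$W1, cfg$n_hidden, cfg$n_in),
    b1 = obj$b1,
    W2 = matrix(obj$W2, cfg$n_out, cfg$n_hidden),
    b2 = obj$b2,
    config = cfg
  )
  class(net) <- "mlp_network"
  net
}

#' Hidden-layer size search by enlarging
#'
#' Starts from a small hidden layer and grows it in fixed steps, training a
#' fresh network at each size, until the training set is classified with
#' 100% accuracy; returns the smallest such size, or the best-performing
#' size if none reaches 100%.
#'
#' @param n_in,n_out Input and output layer sizes.
#' @param X,T Training patterns and one-hot targets.
#' @param opts A [training_options()].
#' @param h_min,h_step,h_max Search grid over the hidden-layer size.
#' @param seed Seed for the per-size weight initializations.
#' @return A list with `n_hidden` (chosen size), `fit` (the fit at that
#'   size) and `trace` (tibble of size, training accuracy, final MSE).
#' @export
enlarge_hidden <- function(n_in, n_out, X, T, opts = training_options(),
                           h_min = 2L, h_step = 2L, h_max = 32L, seed = 1L) {
  if (nrow(as.matrix(X)) == 0L) abort("the training set is empty.")
  stopifnot(h_min >= 1L, h_step >= 1L, h_min <= h_max)
  labels <- apply(as.matrix(T), 1, which.max)
  sizes <- seq(h_min, h_max, by = h_step)
  trace <- list()
  best <- NULL
  best_acc <- -Inf
  for (h in sizes) {
    net <- init_network(network_config(n_in, h, n_out),
                        seed = derive_seed(seed, h))
    fit <- lm_train(net, X, T, opts)
    acc <- 100 * mean(predict(fit, X) == labels)
    trace[[length(trace) + 1L]] <-
      tibble::tibble(n_hidden = h, train_accuracy = acc, mse = fit$mse)
    if (acc > best_acc) {
      best <- fit
      best_acc <- acc
    }
    if (acc >= 100) break
  }
  list(
    n_hidden = best$net$config$n_hidden,
    fit = best,
    trace = dplyr::bind_rows(trace)
  )
}
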