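test_that("initialization is deterministic, bounded, and sized correctly", {
  cfg <- network_config(12, 8, 8)
  a <- init_network(cfg, seed = 5)
  b <- init_network(cfg, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a$W1, init_network(cfg, seed = 6)$W1))
  # parameter count of the 12:8:8 topology
  theta <- c(as.vector(a$W1), a$b1, as.vector(a$W2), a$b2)
  expect_length(theta, 12 * 8 + 8 + 8 * 8 + 8) # 176
  expect_true(all(abs(a$W1) <= sqrt(6 / 20)))
  expect_true(all(abs(a$W2) <= sqrt(6 / 16)))
  expect_true(all(a$b1 == 0) && all(a$b2 == 0))
  expect_error(network_config(0, 4, 8), "positive")
})

test_that("the forward pass is logsig-hidden with linear outputs", {
  cfg <- network_config(3, 4, 2)
  net <- init_network(cfg, seed = 1)
  net$W1[] <- 0; net$W2[] <- 0
  fw <- mlp_forward(net, c(1, 2, 3))
  expect_equal(unname(fw$hidden), rep(0.5, 4))
  expect_equal(unname(fw$output), c(0, 0))

  # output layer is linear: scaling W2 and b2 scales the outputs
  net2 <- init_network(cfg, seed = 2)
  net2$b2 <- rnorm(2)
  y1 <- mlp_forward(net2, c(0.1, -0.2, 0.3))$output
  net3 <- net2
  net3$W2 <- 5 * net3$W2
  net3$b2 <- 5 * net3$b2
  expect_equal(mlp_forward(net3, c(0.1, -0.2, 0.3))$output, 5 * y1)

  # sigmoid saturation
  sat <- init_network(network_config(1, 1, 1), seed = 1)
  sat$W1[] <- 0; sat$b1 <- 10
  expect_equal(unname(mlp_forward(sat, 0)$hidden), 1, tolerance = 1e-4)

  expect_error(mlp_forward(net, c(1, 2)), "expects")
})

test_that("the analytic Jacobian matches central finite differences", {
  cfg <- network_config(3, 4, 2)
  net <- init_network(cfg, seed = 42)
  net$b1 <- rnorm(4, 0, 0.3)
  net$b2 <- rnorm(2, 0, 0.3)
  set.seed(43)
  X <- matrix(rnorm(5 * 3), 5, 3)
  T <- matrix(rnorm(5 * 2), 5, 2)
  rj <- gyrowave:::mlp_residual_jacobian(net, X, T)
  theta <- gyrowave:::flatten_params(net)
  eps <- 1e-6
  J_fd <- matrix(0, length(rj$r), length(theta))
  for (p in seq_along(theta)) {
    tp <- theta; tp[p] <- tp[p] + eps
    tm <- theta; tm[p] <- tm[p] - eps
    rp <- gyrowave:::mlp_residual_jacobian(
      gyrowave:::unflatten_params(tp, cfg), X, T, jacobian = FALSE)$r
    rm <- gyrowave:::mlp_residual_jacobian(
      gyrowave:::unflatten_params(tm, cfg), X, T, jacobian = FALSE)$r
    J_fd[, p] <- (rp - rm) / (2 * eps)
  }
  expect_lt(max(abs(rj$J - J_fd)) / max(abs(J_fd)), 1e-5)
})

test_that("large damping turns the LM step into a gradient step", {
  cfg <- network_config(2, 3, 2)
  net <- init_network(cfg, seed = 7)
  set.seed(8)
  X <- matrix(rnorm(8), 4, 2)
  T <- matrix(rnorm(8), 4, 2)
  rj <- gyrowave:::mlp_residual_jacobian(net, X, T)
  g <- crossprod(rj$J, rj$r)
  H <- crossprod(rj$J)
  step <- solve(H + diag(1e8, ncol(H)), g)
  cosang <- sum(step * g) / sqrt(sum(step^2) * sum(g^2))
  expect_gt(cosang, 0.999)
})

test_that("LM training recovers the least-squares line", {
  # 1:1:1 network on y = 2x; four parameters against three residuals, so
  # the closed-form least-squares fit (zero residual) is attainable
  X <- matrix(c(1, 2, 3), 3, 1)
  T <- matrix(c(2, 4, 6), 3, 1)
  ls_fit <- unname(cbind(1, X) %*% stats::lm.fit(cbind(1, X), T)$coefficients)
  sses <- sapply(1:3, function(s) {
    net <- init_network(network_config(1, 1, 1), seed = s)
    fit <- lm_train(net, X, T, training_options(max_epochs = 400,
                                                goal_mse = 1e-10))
    fit$sse
  })
  expect_lt(min(sses), 1e-6)
  expect_equal(ls_fit, T) # the oracle itself: exact interpolation
})

test_that("LM learns XOR for most random initializations", {
  X <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2)
  T <- matrix(c(0, 1, 1, 0), 4, 1)
  ok <- 0L
  for (s in 1:10) {
    net <- init_network(network_config(2, 2, 1), seed = s)
    fit <- lm_train(net, X, T, training_options(max_epochs = 300,
                                                goal_mse = 1e-6))
    if (fit$mse < 0.01) ok <- ok + 1L
  }
  expect_gte(ok, 8L)
})

test_that("accepted-step loss history is monotone non-increasing", {
  set.seed(12)
  X <- matrix(rnorm(40), 10, 4)
  T <- one_hot(sample(1:3, 10, replace = TRUE), 3)
  net <- init_network(network_config(4, 5, 3), seed = 2)
  fit <- lm_train(net, X, T, training_options(max_epochs = 50))
  expect_true(all(diff(fit$loss$sse) <= 1e-12))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$complexity, "4:5:3")
})

test_that("prediction applies the max-selection rule with low-index ties", {
  cfg <- network_config(2, 2, 4)
  net <- init_network(cfg, seed = 1)
  net$W1[] <- 0; net$W2[] <- 0
  net$b2 <- c(0.1, 0.9, 0.2, 0.3)
  expect_equal(predict(net, c(0, 0)), 2L)
  net$b2 <- rep(0.5, 4) # all-equal outputs: lowest class index wins
  expect_equal(predict(net, c(0, 0)), 1L)
  net$b2 <- c(0, 0, 7, 0)
  expect_equal(predict(net, matrix(rnorm(6), 3, 2)), rep(3L, 3))
})

test_that("one-hot coding has exactly one 1 per row", {
  T <- one_hot(c(2, 1, 3), 3)
  expect_equal(rowSums(T), rep(1, 3))
  expect_equal(apply(T, 1, which.max), c(2L, 1L, 3L))
  expect_error(one_hot(c(0, 1), 3), "1\\.\\.3")
})

test_that("network JSON serialization round-trips predictions", {
  net <- init_network(network_config(4, 3, 2), seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_network(net, path)
  back <- read_network(path)
  X <- matrix(rnorm(12), 3, 4)
  expect_equal(mlp_forward(back, X)$output, mlp_forward(net, X)$output)
})

test_that("enlarging returns the smallest adequate hidden size", {
  # linearly separable two-class toy problem
  set.seed(30)
  X <- rbind(matrix(rnorm(20, -2, 0.3), 10, 2),
             matrix(rnorm(20, 2, 0.3), 10, 2))
  T <- one_hot(rep(1:2, each = 10), 2)
  res <- enlarge_hidden(2, 2, X, T, training_options(max_epochs = 60),
                        h_min = 2, h_step = 2, h_max = 8, seed = 1)
  expect_equal(res$n_hidden, 2L)
  expect_equal(nrow(res$trace), 1L)

  # contradictory labels can never reach 100%: the full grid is scanned
  Xc <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
  Tc <- one_hot(c(1, 2), 2)
  Xc <- rbind(Xc, Xc)
  Tc <- rbind(Tc, one_hot(c(2, 1), 2))
  res2 <- enlarge_hidden(2, 2, Xc, Tc, training_options(max_epochs = 10),
                         h_min = 2, h_step = 3, h_max = 8, seed = 1)
  expect_equal(res2$trace$n_hidden, c(2, 5, 8))
  expect_error(enlarge_hidden(2, 2, X[0, ], T[0, ], seed = 1), "empty")
})
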