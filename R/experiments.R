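#' Split patterns into training and test sets
#'
#' Randomly assigns a fraction of the patterns to the training set. With
#' `stratified = TRUE` (default) the split preserves per-class proportions
#' to within one pattern, guaranteeing every motion is represented during
#' training; `stratified = FALSE` reproduces a plain random draw.
#'
#' @param patterns A tibble with a `motion_id` column (pattern or feature
#'   table).
#' @param train_fraction Fraction of patterns assigned to training,
#'   in (0, 1).
#' @param seed Integer seed; the split is deterministic given it.
#' @param stratified Stratify by `motion_id`?
#' @return A list with tibbles `train` and `test` (disjoint, exhaustive).
#' @examples
#' d <- tibble::tibble(pattern_id = 1:12, motion_id = rep(1:2, each = 6))
#' split_dataset(d, 1 / 3, seed = 1)$train
#' @export
split_dataset <- function(patterns, train_fraction = 1 / 3, seed = 1L,
                          stratified = TRUE) {
  if (!(train_fraction > 0 && train_fraction < 1)) {
    abort("`train_fraction` must be strictly between 0 and 1.")
  }
  n <- nrow(patterns)
  idx <- with_local_seed(seed, {
    if (stratified) {
      unlist(lapply(split(seq_len(n), patterns$motion_id), function(rows) {
        k <- round(length(rows) * train_fraction)
        k <- min(max(k, 1L), length(rows) - 1L)
        sample(rows, k)
      }), use.names = FALSE)
    } else {
      sample(seq_len(n), round(n * train_fraction))
    }
  })
  train <- patterns[sort(idx), ]
  test <- patterns[setdiff(seq_len(n), idx), ]
  if (stratified && !all(unique(patterns$motion_id) %in% train$motion_id)) {
    abort("a motion class is absent from the training set under stratification.")
  }
  list(train = train, test = test)
}

feature_matrix <- function(features) {
  as.matrix(features[feature_columns(features)])
}

accuracy_pct <- function(predicted, truth) 100 * mean(predicted == truth)

#' Run one train/evaluate experiment
#'
#' The full classification pipeline for one configuration: feature
#' extraction over all patterns, train/test split, training-set min--max
#' normalization, hidden-layer sizing (fixed `n_hidden`, or a full
#' [enlarge_hidden()] search when `n_hidden = NULL`), Levenberg--Marquardt
#' training, and evaluation on both sets.
#'
#' @param dataset Segment tibble from [build_dataset()] (or an already
#'   paired pattern tibble).
#' @param kind Feature set identifier (see [feature_set_kinds()]).
#' @param wavelet Wavelet spec or name.
#' @param level Decomposition level.
#' @param split_seed,init_seed Seeds for the split and the weight
#'   initialization.
#' @param n_hidden Hidden-layer size; `NULL` runs the enlarging search.
#' @param train_fraction Training fraction (default one third).
#' @param opts [training_options()].
#' @param stratified Passed to [split_dataset()].
#' @param features Optional precomputed feature table from
#'   [compute_features()] (skips feature extraction).
#' @return A one-row tibble (class `experiment_result`): `kind`, `wavelet`,
#'   `level`, `complexity` (the `n1:n2:n3` string), `n_hidden`,
#'   `train_accuracy`, `test_accuracy` (percent), `mse`, `epochs`,
#'   `split_seed`, `init_seed`, `elapsed_s`. The fitted model, normalizer
#'   and split are attached as attributes (`fit`, `normalizer`, `split`).
#' @export
run_single <- function(dataset, kind, wavelet, level, split_seed = 1L,
                       init_seed = 1L, n_hidden = 8L,
                       train_fraction = 1 / 3, opts = training_options(),
                       stratified = TRUE, features = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (is.null(features)) {
    features <- compute_features(dataset, kind, wavelet, level)
  }
  kind <- attr(features, "kind") %||% resolve_kind(kind)
  wavelet_name <- attr(features, "wavelet") %||%
    get_wavelet(wavelet)$name

  parts <- split_dataset(features, train_fraction, seed = split_seed,
                         stratified = stratified)
  nrm <- fit_normalizer(parts$train)
  train <- apply_normalizer(nrm, parts$train)
  test <- apply_normalizer(nrm, parts$test)

  X_tr <- feature_matrix(train)
  X_te <- feature_matrix(test)
  n_classes <- max(features$motion_id)
  T_tr <- one_hot(train$motion_id, n_classes)

  if (is.null(n_hidden)) {
    search <- enlarge_hidden(ncol(X_tr), n_classes, X_tr, T_tr, opts,
                             seed = init_seed)
    fit <- search$fit
  } else {
    net <- init_network(network_config(ncol(X_tr), n_hidden, n_classes),
                        seed = init_seed)
    fit <- lm_train(net, X_tr, T_tr, opts)
  }

  out <- tibble::tibble(
    kind = kind,
    wavelet = wavelet_name,
    level = as.integer(level),
    complexity = format(fit$net$config),
    n_hidden = fit$net$config$n_hidden,
    train_accuracy = accuracy_pct(predict(fit, X_tr), train$motion_id),
    test_accuracy = accuracy_pct(predict(fit, X_te), test$motion_id),
    mse = fit$mse,
    epochs = nrow(fit$loss) - 1L,
    split_seed = as.integer(split_seed),
    init_seed = as.integer(init_seed),
    elapsed_s = proc.time()[["elapsed"]] - t0
  )
  class(out) <- c("experiment_result", class(out))
  attr(out, "fit") <- fit
  attr(out, "normalizer") <- nrm
  attr(out, "split") <- list(train = train$pattern_id, test = test$pattern_id)
  out
}

#' Scan decomposition levels
#'
#' Runs [run_single()] for each requested decomposition level with a fixed
#' feature set and wavelet, mirroring a per-level accuracy table: one row
#' per level with training/test accuracy and the `n1:n2:n3` complexity.
#'
#' @inheritParams run_single
#' @param levels Integer vector of levels to scan.
#' @param ... Further arguments passed to [run_single()].
#' @return A tibble of experiment rows (class `level_scan`), with a `best`
#'   attribute naming the level with the highest test accuracy.
#' @export
level_scan <- function(dataset, kind, wavelet, levels = 1:8,
                       split_seed = 1L, init_seed = 1L, n_hidden = 8L,
                       opts = training_options(), ...) {
  rows <- purrr::map(levels, function(lv) {
    run_single(dataset, kind, wavelet, lv, split_seed = split_seed,
               init_seed = init_seed, n_hidden = n_hidden, opts = opts, ...)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "best") <- out$level[which.max(out$test_accuracy)]
  class(out) <- c("level_scan", class(out))
  out
}

#' Scan wavelet families at a fixed level
#'
#' Evaluates every catalogued order of the requested families with a fixed
#' feature set and level, and summarizes test accuracy per family (mean,
#' range, and the orders attaining the extremes).
#'
#' @inheritParams run_single
#' @param families Character vector of family names (default: the full
#'   catalogue).
#' @param ... Further arguments passed to [run_single()].
#' @return A list with `results` (one experiment row per wavelet) and
#'   `summary` (per-family mean/min/max test accuracy with argmin/argmax
#'   orders), both tibbles; class `wavelet_scan`.
#' @export
wavelet_scan <- function(dataset, kind = "k", level = 5L,
                         families = unique(wavelet_catalogue()$family),
                         split_seed = 1L, init_seed = 1L, n_hidden = 8L,
                         opts = training_options(), ...) {
  cat_tbl <- dplyr::filter(wavelet_catalogue(), .data$family %in% families)
  if (nrow(cat_tbl) == 0L) abort("no catalogued wavelets match `families`.")
  rows <- purrr::pmap(cat_tbl, function(family, order) {
    w <- get_wavelet(family, order)
    res <- run_single(dataset, kind, w, level, split_seed = split_seed,
                      init_seed = init_seed, n_hidden = n_hidden,
                      opts = opts, ...)
    res$family <- family
    res$order <- order
    res
  })
  results <- dplyr::bind_rows(rows)
  summary <- results |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(
      n_orders = dplyr::n(),
      mean_test = mean(.data$test_accuracy),
      min_test = min(.data$test_accuracy),
      max_test = max(.data$test_accuracy),
      order_min = .data$order[which.min(.data$test_accuracy)],
      order_max = .data$order[which.max(.data$test_accuracy)],
      .groups = "drop"
    )
  structure(list(results = results, summary = summary),
            class = "wavelet_scan")
}

#' @export
print.wavelet_scan <- function(x, ...) {
  cat("<wavelet_scan> ", nrow(x$results), " wavelets\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Confusion-matrix statistics over repeated runs
#'
#' Repeats the train/evaluate cycle `n_iter` times and accumulates the
#' per-class confusion matrix of the test set, reporting its entry-wise
#' mean and standard deviation in percent (each true-class row of the mean
#' matrix sums to 100). In mode `"fixed_split"` the train/test split is
#' frozen and only the weight initialization is redrawn each iteration,
#' isolating the effect of random initialization; in mode `"resplit"` a new
#' split is drawn too.
#'
#' @inheritParams run_single
#' @param n_iter Number of repetitions (>= 2).
#' @param mode `"fixed_split"` or `"resplit"`.
#' @param seed Master seed from which per-iteration seeds are derived.
#' @param init_seeds Optional integer vector of length `n_iter` overriding
#'   the derived per-iteration initialization seeds (all-equal seeds in
#'   `"fixed_split"` mode remove every source of randomness, so the sd
#'   matrix is identically zero).
#' @return An object of class `confusion_stats`: list with `mean` and `sd`
#'   (8x8 matrices, percent), `overall` (mean +/- sd of overall test
#'   accuracy), `results` (per-iteration experiment rows), `n_iter`,
#'   `mode`.
#' @export
confusion_over_runs <- function(dataset, kind = "k", wavelet = "rbio3.1",
                                level = 5L, n_iter = 10L,
                                mode = c("fixed_split", "resplit"),
                                seed = 1L, n_hidden = 8L,
                                opts = training_options(),
                                features = NULL, init_seeds = NULL) {
  mode <- match.arg(mode)
  if (n_iter < 2L) abort("`n_iter` must be at least 2.")
  if (!is.null(init_seeds) && length(init_seeds) != n_iter) {
    abort("`init_seeds` must have length `n_iter`.")
  }
  if (is.null(features)) {
    features <- compute_features(dataset, kind, wavelet, level)
  }
  n_classes <- max(features$motion_id)
  conf <- array(0, c(n_classes, n_classes, n_iter))
  rows <- list()
  for (it in seq_len(n_iter)) {
    split_seed <- if (mode == "resplit") derive_seed(seed, 500L, it) else
      derive_seed(seed, 500L, 1L)
    init_seed <- if (is.null(init_seeds)) derive_seed(seed, 900L, it) else
      init_seeds[it]
    res <- run_single(dataset, kind, wavelet, level,
                      split_seed = split_seed,
                      init_seed = init_seed,
                      n_hidden = n_hidden, opts = opts, features = features)
    fit <- attr(res, "fit")
    nrm <- attr(res, "normalizer")
    test_ids <- attr(res, "split")$test
    test <- apply_normalizer(nrm, features[features$pattern_id %in% test_ids, ])
    pred <- predict(fit, feature_matrix(test))
    for (m in seq_len(n_classes)) {
      sel <- test$motion_id == m
      counts <- tabulate(pred[sel], nbins = n_classes)
      conf[m, , it] <- 100 * counts / sum(sel)
    }
    rows[[it]] <- res
  }
  results <- dplyr::bind_rows(rows)
  mean_mat <- apply(conf, c(1, 2), mean)
  sd_mat <- apply(conf, c(1, 2), sd)
  dimnames(mean_mat) <- dimnames(sd_mat) <-
    list(paste0("M", seq_len(n_classes)), paste0("M", seq_len(n_classes)))
  structure(
    list(
      mean = mean_mat, sd = sd_mat,
      overall = c(mean = mean(results$test_accuracy),
                  sd = sd(results$test_accuracy)),
      results = results, n_iter = n_iter, mode = mode
    ),
    class = "confusion_stats"
  )
}

#' @export
print.confusion_stats <- function(x, digits = 1, ...) {
  cat("<confusion_stats> ", x$n_iter, " iterations, mode ", x$mode,
      "; overall test accuracy ", round(x$overall["mean"], digits), " +/- ",
      round(x$overall["sd"], digits), " %\n", sep = "")
  print(round(x$mean, digits))
  invisible(x)
}

#' Tidy a confusion-statistics object
#'
#' @param x A `confusion_stats`.
#' @param ... Unused.
#' @return A long tibble with `true`, `classified`, `mean` and `sd`
#'   (percent).
#' @export
tidy.confusion_stats <- function(x, ...) {
  n <- nrow(x$mean)
  tibble::tibble(
    true = rep(rownames(x$mean), each = n),
    classified = rep(colnames(x$mean), times = n),
    mean = as.vector(t(x$mean)),
    sd = as.vector(t(x$sd))
  )
}

#' Render scan results as a markdown table
#'
#' Formats a [level_scan()] result (or any experiment-row tibble) in the
#' level / training / test / complexity layout of the per-level accuracy
#' tables.
#'
#' @param results An experiment-row tibble.
#' @return A character vector of markdown lines.
#' @export
report_markdown <- function(results) {
  header <- "| level | training (%) | test (%) | ANN complexity |"
  sep <- "|---|---|---|---|"
  rows <- sprintf(
    "| %d | %.1f | %.1f | %s |",
    results$level, results$train_accuracy, results$test_accuracy,
    results$complexity
  )
  c(header, sep, rows)
}
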