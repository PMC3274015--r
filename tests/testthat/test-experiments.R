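test_that("stratified splitting preserves class counts exactly at 48/class", {
  pats <- tibble::tibble(pattern_id = 1:384, motion_id = rep(1:8, each = 48))
  sp <- split_dataset(pats, 1 / 3, seed = 1)
  expect_equal(nrow(sp$train), 128L)
  expect_equal(nrow(sp$test), 256L)
  expect_equal(unname(table(sp$train$motion_id)), rep(16L, 8),
               ignore_attr = TRUE)
  # disjoint and exhaustive
  expect_length(intersect(sp$train$pattern_id, sp$test$pattern_id), 0L)
  expect_setequal(c(sp$train$pattern_id, sp$test$pattern_id),
                  pats$pattern_id)
  # deterministic
  sp2 <- split_dataset(pats, 1 / 3, seed = 1)
  expect_identical(sp$train$pattern_id, sp2$train$pattern_id)
  expect_false(identical(
    split_dataset(pats, 1 / 3, seed = 2)$train$pattern_id,
    sp$train$pattern_id
  ))
  expect_error(split_dataset(pats, 0), "between 0 and 1")
})

test_that("a singleton class cannot be stratified into training", {
  pats <- tibble::tibble(pattern_id = 1:7,
                         motion_id = c(rep(1L, 6), 2L))
  expect_error(split_dataset(pats, 1 / 3, seed = 1), "absent")
})

test_that("plain random splits ignore class balance", {
  pats <- tibble::tibble(pattern_id = 1:90, motion_id = rep(1:3, each = 30))
  sp <- split_dataset(pats, 1 / 3, seed = 4, stratified = FALSE)
  expect_equal(nrow(sp$train), 30L)
  expect_equal(nrow(sp$test), 60L)
})

test_that("run_single reports complexity and reproduces itself", {
  d <- tiny_dataset(seed = 2, n_motions = 2L, intervals = 2L, segments = 3L)
  r1 <- run_single(d, "k", "db2", 3, split_seed = 3, init_seed = 4,
                   n_hidden = 3, opts = fast_opts(), train_fraction = 0.5)
  expect_equal(r1$complexity, "8:3:2") # n1 = 2 channels x (3 + 1)
  expect_true(r1$train_accuracy >= 0 && r1$train_accuracy <= 100)
  r2 <- run_single(d, "k", "db2", 3, split_seed = 3, init_seed = 4,
                   n_hidden = 3, opts = fast_opts(), train_fraction = 0.5)
  cols <- setdiff(names(r1), "elapsed_s")
  expect_equal(as.data.frame(r1[cols]), as.data.frame(r2[cols]))
})

test_that("shuffled labels drop test accuracy to chance", {
  f <- default_features()
  shuf <- f
  shuf$motion_id <- with_seed_sample(f$motion_id, 99)
  res <- run_single(NULL, "k", "rbio3.1", 5, features = shuf,
                    opts = fast_opts(60))
  expect_gt(res$test_accuracy, 12.5 - 7.5)
  expect_lt(res$test_accuracy, 12.5 + 7.5)
})

test_that("level scans report one row per level with the n1 formulas", {
  d <- tiny_dataset(seed = 6, n_motions = 2L, intervals = 2L, segments = 3L)
  sc_i <- level_scan(d, "i", "db2", levels = 1:3, n_hidden = 3,
                     opts = fast_opts(), train_fraction = 0.5)
  # means-and-variances: n1 = 4 (i + 1)
  expect_equal(nrow(sc_i), 3L)
  expect_equal(sc_i$complexity, c("8:3:2", "12:3:2", "16:3:2"))
  sc_k <- level_scan(d, "k", "db2", levels = c(2, 4), n_hidden = 3,
                     opts = fast_opts(), train_fraction = 0.5)
  # variances only: n1 = 2 (i + 1)
  expect_equal(sc_k$complexity, c("6:3:2", "10:3:2"))
  expect_s3_class(autoplot(sc_i), "ggplot")
  md <- report_markdown(sc_i)
  expect_length(md, 5L)
})

test_that("wavelet scans cover every catalogued order of a family", {
  d <- tiny_dataset(seed = 7, n_motions = 2L, intervals = 2L, segments = 3L)
  sc <- wavelet_scan(d, kind = "k", level = 3, families = "coiflet",
                     n_hidden = 3, opts = fast_opts(),
                     train_fraction = 0.5)
  expect_equal(nrow(sc$results), 5L) # coiflet orders 1..5
  expect_equal(sc$summary$n_orders, 5L)
  expect_gte(sc$summary$mean_test, sc$summary$min_test)
  expect_lte(sc$summary$mean_test, sc$summary$max_test)
  expect_s3_class(autoplot(sc), "ggplot")
})

test_that("confusion rows sum to 100 and frozen seeds freeze the matrix", {
  d <- tiny_dataset(seed = 8, n_motions = 2L, intervals = 2L, segments = 3L)
  f <- compute_features(d, "k", "db2", 3)
  cs <- confusion_over_runs(NULL, features = f, n_iter = 3, n_hidden = 3,
                            opts = fast_opts(), mode = "resplit")
  expect_equal(unname(rowSums(cs$mean)), rep(100, 2), tolerance = 1e-3)
  expect_true(all(cs$sd >= 0))
  expect_s3_class(tidy(cs), "tbl_df")
  expect_s3_class(autoplot(cs), "ggplot")

  # fixed split and identical init seeds leave no randomness at all
  cs0 <- confusion_over_runs(NULL, features = f, n_iter = 3, n_hidden = 3,
                             opts = fast_opts(), mode = "fixed_split",
                             init_seeds = c(5L, 5L, 5L))
  expect_true(all(cs0$sd == 0))
  expect_error(confusion_over_runs(NULL, features = f, n_iter = 1), "at least 2")
})

test_that("raising the SNR does not hurt variance-feature accuracy", {
  proto <- recording_protocol(intervals_per_motion = 2,
                              segments_per_interval = 3,
                              interval_s = 36, segment_len = 800)
  acc <- sapply(c(5, 30), function(snr) {
    mean(sapply(1:3, function(s) {
      d <- build_dataset(proto, seed = s, snr_db = snr)
      run_single(d, "k", "rbio3.1", 5, split_seed = s, init_seed = s,
                 n_hidden = 6, opts = fast_opts(60),
                 train_fraction = 0.5)$test_accuracy
    }))
  })
  expect_gte(acc[2], acc[1])
})
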