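#' The twelve wavelet feature sets
#'
#' Catalogue of the feature sets that can be computed from the level-`i`
#' wavelet decomposition of a two-channel segment pair. Kinds are labelled
#' `a` to `l`; per-channel dimensionalities are given for a segment of `N`
#' samples (the two-channel pattern doubles them):
#'
#' | kind | contents (per channel) | length |
#' |------|------------------------|--------|
#' | a | approximation coefficients `A_i` | `ceiling(N / 2^i)` |
#' | b | approximation and all detail coefficients | `N` (ceil-halving sum) |
#' | c | `EDR_Dj` ratios | `i` |
#' | d | `EDR_A` and `EDR_Dj` ratios | `i + 1` |
#' | e | `EDR_A` + min/max/mean/var of the `EDR_Dj` | 5 |
#' | f | min/max/mean/var of the `EDR_Dj` | 4 |
#' | g | `EDR_A` + mean/var of the `EDR_Dj` | 3 |
#' | h | mean/var of the `EDR_Dj` | 2 |
#' | i | means and variances of all coefficient vectors | `2(i + 1)` |
#' | j | means of all coefficient vectors | `i + 1` |
#' | k | variances of all coefficient vectors | `i + 1` |
#' | l | variances and EDRs of all coefficient vectors | `2(i + 1)` |
#'
#' Coefficient-valued kinds (a, b) and moment-valued kinds (i--l) are meant
#' to be min--max normalized on the training set (see [fit_normalizer()]);
#' [build_features()] itself returns un-normalized values.
#'
#' @return A tibble with columns `kind` and `name`.
#' @export
feature_set_kinds <- function() {
  tibble::tibble(
    kind = letters[1:12],
    name = c(
      "norm_approx", "norm_approx_detail", "edr_detail", "edr_all",
      "edra_minmaxmeanvar_edrd", "minmaxmeanvar_edrd", "edra_meanvar_edrd",
      "meanvar_edrd", "norm_means_vars", "norm_means", "norm_vars",
      "norm_vars_edrs"
    )
  )
}

resolve_kind <- function(kind) {
  kinds <- feature_set_kinds()
  kind <- as.character(kind)
  if (kind %in% kinds$kind) return(kind)
  hit <- match(kind, kinds$name)
  if (!is.na(hit)) return(kinds$kind[hit])
  abort(paste0(
    "Unknown feature set '", kind, "'. Use one of: ",
    paste(paste0(kinds$kind, " (", kinds$name, ")"), collapse = ", "), "."
  ))
}

#' Per-channel feature length of a feature set
#'
#' @param kind Feature set identifier (`"a"`..`"l"` or a name from
#'   [feature_set_kinds()]).
#' @param level Decomposition level `i`.
#' @param n Segment length in samples (only kinds `a` and `b` depend on it).
#' @return Integer per-channel feature count; the two-channel pattern
#'   dimension is twice this.
#' @examples
#' feature_length("k", 5)       # 6 -> 12 for the two-channel pattern
#' feature_length("i", 3)       # 8 -> 16 = 4 * (3 + 1)
#' @export
feature_length <- function(kind, level, n = 1600L) {
  kind <- resolve_kind(kind)
  lens <- coeff_lengths(n, level)
  as.integer(switch(kind,
    a = lens$A,
    b = lens$A + sum(lens$D),
    c = level,
    d = level + 1L,
    e = 5L,
    f = 4L,
    g = 3L,
    h = 2L,
    i = 2L * (level + 1L),
    j = level + 1L,
    k = level + 1L,
    l = 2L * (level + 1L)
  ))
}

#' Sub-band coefficient statistics of a decomposition
#'
#' Means and unbiased (n-1 denominator) variances of every coefficient
#' vector (`A_i`, `D_1`, ..., `D_i`) -- `i + 1` means and `i + 1` variances
#' per channel -- plus the minimum, maximum, mean and variance over the list
#' of detail energy distribution ratios.
#'
#' @param decomp A [dwt_decompose()] result.
#' @return A list with named numeric vectors `means`, `vars` (names `A`,
#'   `D1`..`Di`) and `edr_d_stats` (`min`, `max`, `mean`, `var`; `var` is 0
#'   for a single detail level).
#' @export
coeff_stats <- function(decomp) {
  stopifnot(inherits(decomp, "wavelet_decomposition"))
  vecs <- c(list(A = decomp$A),
            stats::setNames(decomp$D, paste0("D", seq_len(decomp$level))))
  if (any(lengths(vecs) < 2L)) {
    abort("variance requires every coefficient vector to have length >= 2; decompose a longer segment or use a lower level.")
  }
  e <- edr(decomp)
  edr_d <- e[-1]
  list(
    means = vapply(vecs, mean, numeric(1)),
    vars = vapply(vecs, var, numeric(1)),
    edr_d_stats = c(
      min = min(edr_d), max = max(edr_d), mean = mean(edr_d),
      var = if (length(edr_d) > 1L) var(edr_d) else 0
    )
  )
}

channel_feature_values <- function(x, kind, wavelet, level) {
  decomp <- dwt_decompose(x, wavelet, level)
  switch(kind,
    a = stats::setNames(decomp$A, paste0("A", seq_along(decomp$A))),
    b = {
      v <- c(decomp$A, unlist(rev(decomp$D)))
      stats::setNames(v, paste0("c", seq_along(v)))
    },
    c = edr(decomp)[-1],
    d = edr(decomp),
    e = {
      s <- coeff_stats(decomp)
      c(edr(decomp)["EDR_A"],
        stats::setNames(s$edr_d_stats, paste0("edrD_", names(s$edr_d_stats))))
    },
    f = {
      s <- coeff_stats(decomp)
      stats::setNames(s$edr_d_stats, paste0("edrD_", names(s$edr_d_stats)))
    },
    g = {
      s <- coeff_stats(decomp)
      c(edr(decomp)["EDR_A"],
        stats::setNames(s$edr_d_stats[c("mean", "var")],
                        c("edrD_mean", "edrD_var")))
    },
    h = {
      s <- coeff_stats(decomp)
      stats::setNames(s$edr_d_stats[c("mean", "var")],
                      c("edrD_mean", "edrD_var"))
    },
    i = {
      s <- coeff_stats(decomp)
      c(stats::setNames(s$means, paste0("mean_", names(s$means))),
        stats::setNames(s$vars, paste0("var_", names(s$vars))))
    },
    j = {
      s <- coeff_stats(decomp)
      stats::setNames(s$means, paste0("mean_", names(s$means)))
    },
    k = {
      s <- coeff_stats(decomp)
      stats::setNames(s$vars, paste0("var_", names(s$vars)))
    },
    l = {
      s <- coeff_stats(decomp)
      c(stats::setNames(s$vars, paste0("var_", names(s$vars))), edr(decomp))
    }
  )
}

#' Compute one feature vector from a two-channel segment pair
#'
#' Decomposes each channel with the requested wavelet and level and
#' assembles the chosen feature set, concatenating the above-knee channel's
#' features before the below-knee channel's. Values are un-normalized;
#' training-set min--max scaling is applied separately via
#' [fit_normalizer()].
#'
#' @param above,below Numeric sample vectors of equal length (deg/s).
#' @param kind Feature set identifier (see [feature_set_kinds()]).
#' @param wavelet A wavelet spec or name (see [get_wavelet()]).
#' @param level Decomposition level in `1..8`.
#' @return Named numeric vector of length `2 * feature_length(kind, level)`.
#' @examples
#' x <- generate_rate_signal(4, 12, 133.4, seed = 1)
#' f <- build_features(x$above_knee, x$below_knee, "k", "rbio3.1", 5)
#' length(f) # 12
#' @export
build_features <- function(above, below, kind, wavelet, level) {
  if (length(above) != length(below)) {
    abort("both channels must have the same length.")
  }
  kind <- resolve_kind(kind)
  if (is.character(wavelet)) wavelet <- get_wavelet(wavelet)
  f1 <- channel_feature_values(above, kind, wavelet, level)
  f2 <- channel_feature_values(below, kind, wavelet, level)
  c(stats::setNames(f1, paste0("above_", names(f1))),
    stats::setNames(f2, paste0("below_", names(f2))))
}

#' Compute the feature table of a pattern set
#'
#' Applies [build_features()] to every two-channel pattern and returns a
#' wide tibble ready for splitting, normalization and classification.
#'
#' @param patterns A pattern tibble from [pair_patterns()] (or a segment
#'   tibble from [build_dataset()], which is paired first).
#' @inheritParams build_features
#' @return A tibble with `pattern_id`, `motion_id` and one column per
#'   feature. The `kind`, wavelet name and `level` are attached as
#'   attributes.
#' @export
compute_features <- function(patterns, kind, wavelet, level) {
  if (!"above_knee" %in% names(patterns) || !is.list(patterns$above_knee)) {
    patterns <- pair_patterns(patterns)
  }
  kind <- resolve_kind(kind)
  if (is.character(wavelet)) wavelet <- get_wavelet(wavelet)
  feats <- purrr::map2(
    patterns$above_knee, patterns$below_knee,
    function(a, b) build_features(a, b, kind, wavelet, level)
  )
  mat <- do.call(rbind, feats)
  out <- dplyr::bind_cols(
    patterns[c("pattern_id", "motion_id")],
    tibble::as_tibble(mat)
  )
  attr(out, "kind") <- kind
  attr(out, "wavelet") <- wavelet$name
  attr(out, "level") <- as.integer(level)
  out
}

feature_columns <- function(features) {
  setdiff(names(features), c("pattern_id", "motion_id"))
}

#' Training-set min--max feature normalization
#'
#' `fit_normalizer()` learns per-feature minima and maxima from a training
#' feature table; `apply_normalizer()` rescales a feature table to `[0, 1]`
#' with those statistics, clipping values that fall outside the training
#' range (as test-set values may). A feature that is constant on the
#' training set carries no information and is mapped to 0 with a warning.
#'
#' @param features A feature tibble from [compute_features()] (training
#'   rows only for `fit_normalizer()`).
#' @param normalizer A fitted `feature_normalizer`.
#' @return `fit_normalizer()` returns a `feature_normalizer`;
#'   `apply_normalizer()` returns the rescaled feature tibble.
#' @examples
#' tr <- tibble::tibble(pattern_id = 1:3, motion_id = 1L, f = c(2, 4, 6))
#' nrm <- fit_normalizer(tr)
#' apply_normalizer(nrm, tr)$f # 0, 0.5, 1
#' @export
fit_normalizer <- function(features) {
  cols <- feature_columns(features)
  if (nrow(features) == 0L || length(cols) == 0L) {
    abort("`features` must contain at least one row and one feature column.")
  }
  mins <- vapply(features[cols], min, numeric(1))
  maxs <- vapply(features[cols], max, numeric(1))
  const <- maxs - mins <= 0
  if (any(const)) {
    warn(paste0(
      "constant feature column(s) mapped to 0: ",
      paste(cols[const], collapse = ", ")
    ))
  }
  structure(list(min = mins, max = maxs), class = "feature_normalizer")
}

#' @rdname fit_normalizer
#' @export
apply_normalizer <- function(normalizer, features) {
  stopifnot(inherits(normalizer, "feature_normalizer"))
  cols <- names(normalizer$min)
  if (!all(cols %in% names(features))) {
    abort("`features` is missing columns the normalizer was fitted on.")
  }
  for (cl in cols) {
    rng <- normalizer$max[[cl]] - normalizer$min[[cl]]
    if (rng <= 0) {
      features[[cl]] <- rep(0, nrow(features))
    } else {
      features[[cl]] <- pmin(pmax(
        (features[[cl]] - normalizer$min[[cl]]) / rng, 0), 1)
    }
  }
  features
}

#' Write or read a feature table as delimited text
#'
#' Stores the feature tibble as CSV plus a JSON sidecar recording the
#' feature kind, wavelet and level (and, optionally, fitted normalizer
#' statistics).
#'
#' @param features A feature tibble from [compute_features()].
#' @param path CSV file path; the sidecar is written next to it as
#'   `<path>.json`.
#' @param normalizer Optional `feature_normalizer` to record.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   the feature tibble with attributes restored.
#' @export
write_features <- function(features, path, normalizer = NULL) {
  readr::write_csv(features, path)
  meta <- list(
    kind = attr(features, "kind"),
    wavelet = attr(features, "wavelet"),
    level = attr(features, "level")
  )
  if (!is.null(normalizer)) {
    meta$normalizer <- list(min = as.list(normalizer$min),
                            max = as.list(normalizer$max))
  }
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(out, "kind") <- meta$kind
    attr(out, "wavelet") <- meta$wavelet
    attr(out, "level") <- meta$level
  }
  out
}
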