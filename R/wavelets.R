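# Filter tables are shipped as plain-text CSVs under inst/extdata and cached
# per session. Only the decomposition low-pass (and, for biorthogonal pairs,
# the reconstruction low-pass) is stored; the remaining filters follow from
# the standard modulation relations
#   rec_hi[k] = (-1)^k     dec_lo[k]
#   dec_hi[k] = (-1)^(k+1) rec_lo[k]
# and, for orthogonal families, rec_lo = reverse(dec_lo).
.wavelet_cache <- new.env(parent = emptyenv())

load_filter_tables <- function() {
  if (is.null(.wavelet_cache$orth)) {
    .wavelet_cache$orth <- utils::read.csv(
      system.file("extdata", "wavelet_filters_orthogonal.csv",
                  package = "gyrowave"),
      colClasses = c("character", "character", "integer", "numeric")
    )
    .wavelet_cache$bior <- utils::read.csv(
      system.file("extdata", "wavelet_filters_biorthogonal.csv",
                  package = "gyrowave"),
      colClasses = c("character", "character", "integer", "numeric", "numeric")
    )
  }
  list(orth = .wavelet_cache$orth, bior = .wavelet_cache$bior)
}

bior_orders <- function() {
  c("1.1", "1.3", "1.5", "2.2", "2.4", "2.6", "2.8",
    "3.1", "3.3", "3.5", "3.7", "3.9", "4.4", "5.5", "6.8")
}

#' Catalogue of supported wavelets
#'
#' Lists every (family, order) pair the discrete wavelet transform supports:
#' Haar; Daubechies orders 2--32; Symlets 2--8; Coiflets 1--5; the 15
#' spline biorthogonal and reverse-biorthogonal orders 1.1 ... 6.8; and the
#' 62-tap FIR approximation of the Meyer wavelet.
#'
#' @return A tibble with columns `family` and `order`.
#' @examples
#' dplyr::count(wavelet_catalogue(), family)
#' @export
wavelet_catalogue <- function() {
  dplyr::bind_rows(
    tibble::tibble(family = "haar", order = "1"),
    tibble::tibble(family = "daubechies", order = as.character(2:32)),
    tibble::tibble(family = "symlet", order = as.character(2:8)),
    tibble::tibble(family = "coiflet", order = as.character(1:5)),
    tibble::tibble(family = "biorthogonal", order = bior_orders()),
    tibble::tibble(family = "reverse_biorthogonal", order = bior_orders()),
    tibble::tibble(family = "discrete_meyer", order = "1")
  )
}

#' Construct a wavelet filter bank
#'
#' Returns the analysis and synthesis filters of a catalogued wavelet
#' together with its support widths and (where defined) vanishing moments.
#' Orthogonal families (Haar, Daubechies, Symlet, Coiflet, discrete Meyer)
#' have reconstruction filters equal to the time-reversed decomposition
#' filters; biorthogonal pairs use distinct spline analysis/synthesis
#' filters, and the reverse-biorthogonal family swaps those roles.
#'
#' Support widths follow the conventional tables: filter length minus one
#' for compactly supported orthogonal wavelets (31 for Daubechies 16), and
#' `2*order + 1` per part from the two spline orders for (reverse)
#' biorthogonal wavelets (3 and 7 for the decomposition and reconstruction
#' parts of reverse-biorthogonal 3.1).
#'
#' @param family One of `"haar"`, `"daubechies"`, `"symlet"`, `"coiflet"`,
#'   `"biorthogonal"`, `"reverse_biorthogonal"`, `"discrete_meyer"`. Compact
#'   aliases (`"db"`, `"sym"`, `"coif"`, `"bior"`, `"rbio"`, `"dmey"`) are
#'   accepted, as is a single name such as `"rbio3.1"` or `"db4"`.
#' @param order Wavelet order within the family, e.g. `4` or `"3.1"`;
#'   ignored for Haar and discrete Meyer.
#' @return An object of class `wavelet_spec`: a list with `family`, `order`,
#'   `name`, the four filters `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi`,
#'   `support` (named length-2, decomposition and reconstruction parts) and
#'   `vanishing_moments` (`NA` where not classically tabulated).
#' @examples
#' get_wavelet("rbio3.1")$support
#' get_wavelet("daubechies", 16)$support
#' @export
get_wavelet <- function(family, order = NULL) {
  aliases <- c(
    haar = "haar", db = "daubechies", daubechies = "daubechies",
    sym = "symlet", symlet = "symlet", coif = "coiflet", coiflet = "coiflet",
    bior = "biorthogonal", biorthogonal = "biorthogonal",
    rbio = "reverse_biorthogonal", reverse_biorthogonal = "reverse_biorthogonal",
    dmey = "discrete_meyer", discrete_meyer = "discrete_meyer"
  )
  family <- as.character(family)
  if (is.null(order)) {
    m <- regmatches(family, regexec("^([a-z_]+)([0-9.]*)$", family))[[1]]
    if (length(m) == 3L && nzchar(m[3])) {
      family <- m[2]
      order <- m[3]
    }
  }
  if (!family %in% names(aliases)) {
    abort(paste0(
      "Unknown wavelet family '", family, "'. Supported families: ",
      paste(unique(aliases), collapse = ", "), "."
    ))
  }
  family <- aliases[[family]]
  if (family %in% c("haar", "discrete_meyer")) order <- "1"
  if (is.null(order)) abort("`order` is required for this wavelet family.")
  order <- format(order)

  cat_tbl <- wavelet_catalogue()
  if (!any(cat_tbl$family == family & cat_tbl$order == order)) {
    valid <- cat_tbl$order[cat_tbl$family == family]
    abort(paste0(
      "Unsupported order '", order, "' for family '", family,
      "'. Catalogued orders: ", paste(valid, collapse = ", "), "."
    ))
  }

  tabs <- load_filter_tables()
  if (family %in% c("biorthogonal", "reverse_biorthogonal")) {
    d <- tabs$bior[tabs$bior$order == order, ]
    d <- d[order(d$k), ]
    dec_lo <- d$dec_lo
    rec_lo <- d$rec_lo
    if (family == "reverse_biorthogonal") {
      tmp <- rev(rec_lo)
      rec_lo <- rev(dec_lo)
      dec_lo <- tmp
    }
    parts <- as.numeric(strsplit(order, ".", fixed = TRUE)[[1]])
    support <- c(decomposition = 2 * parts[2] + 1,
                 reconstruction = 2 * parts[1] + 1)
    vm <- NA_real_
  } else {
    d <- tabs$orth[tabs$orth$family == family & tabs$orth$order == order, ]
    d <- d[order(d$k), ]
    dec_lo <- d$dec_lo
    rec_lo <- rev(dec_lo)
    support <- c(decomposition = length(dec_lo) - 1,
                 reconstruction = length(dec_lo) - 1)
    vm <- switch(family,
      haar = 1,
      daubechies = as.numeric(order),
      symlet = as.numeric(order),
      coiflet = 2 * as.numeric(order),
      discrete_meyer = NA_real_
    )
  }
  L <- length(dec_lo)
  k <- seq_len(L) - 1
  w <- list(
    family = family, order = order,
    name = paste0(family, ifelse(family %in% c("haar", "discrete_meyer"),
                                 "", order)),
    dec_lo = dec_lo,
    dec_hi = (-1)^(k + 1) * rec_lo,
    rec_lo = rec_lo,
    rec_hi = (-1)^k * dec_lo,
    support = support,
    vanishing_moments = vm
  )
  class(w) <- "wavelet_spec"
  w
}

#' @export
print.wavelet_spec <- function(x, ...) {
  cat("<wavelet_spec> ", x$name, "\n", sep = "")
  cat("  filter length: ", length(x$dec_lo),
      "; support (dec/rec): ", x$support[1], "/", x$support[2], sep = "")
  if (!is.na(x$vanishing_moments)) {
    cat("; vanishing moments: ", x$vanishing_moments, sep = "")
  }
  cat("\n")
  invisible(x)
}
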