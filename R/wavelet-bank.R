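#' @useDynLib mwtselect, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.bank_env <- new.env(parent = emptyenv())

# Scaling-filter table: standard published coefficients for the orthogonal
# Daubechies/Symlet/Coiflet families, stored as plain text in extdata.
.load_filter_table <- function() {
  if (!is.null(.bank_env$filters)) return(.bank_env$filters)
  path <- system.file("extdata", "scaling_filters.csv", package = "mwtselect")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  filters <- lapply(split(tab, tab$name), function(d) d$value[order(d$index)])
  .bank_env$filters <- filters
  filters
}

#' Derive the high-pass (wavelet) filter from a scaling filter
#'
#' Quadrature-mirror construction: the high-pass analysis filter is the
#' time-reversed scaling filter with alternating signs,
#' `g[n] = (-1)^n h[f - 1 - n]` (0-based). This is the one fixed sign/shift
#' convention used throughout the package; it pairs with the synthesis
#' convention of [idwt_level()] to give exact perfect reconstruction.
#'
#' @param dec_lo numeric vector, the low-pass (scaling) analysis filter; must
#'   have even, positive length.
#' @return numeric vector of the same length: the high-pass analysis filter.
#'   Its taps sum to zero and it is orthogonal to `dec_lo`.
#' @examples
#' qmf_highpass(c(1, 1) / sqrt(2))  # Haar: (1, -1)/sqrt(2)
#' @export
qmf_highpass <- function(dec_lo) {
  f <- length(dec_lo)
  if (f == 0L || f %% 2L != 0L) {
    stop("invalid filter: scaling filter must have even, positive length")
  }
  rev(dec_lo) * rep_len(c(1, -1), f)
}

.validate_wavelet_spec <- function(w, tol = 1e-10) {
  h <- w$dec_lo
  g <- w$dec_hi
  f <- length(h)
  stopifnot(length(g) == f, f %% 2L == 0L)
  if (abs(sum(h) - sqrt(2)) > tol) stop(w$name, ": scaling filter does not sum to sqrt(2)")
  if (abs(sum(g)) > tol) stop(w$name, ": wavelet filter does not sum to 0")
  if (abs(sum(h * h) - 1) > tol) stop(w$name, ": scaling filter not unit norm")
  lags <- if (f >= 4L) seq(2L, f - 2L, by = 2L) else integer(0)
  for (l in lags) {
    if (abs(sum(h[seq_len(f - l)] * h[seq_len(f - l) + l])) > tol) {
      stop(w$name, ": scaling filter not orthogonal to its even shifts")
    }
  }
  if (abs(sum(h * g)) > tol) stop(w$name, ": filter pair not orthogonal")
  invisible(w)
}

.new_wavelet_spec <- function(name, family, order, dec_lo) {
  dec_hi <- qmf_highpass(dec_lo)
  w <- structure(
    list(
      name = name, family = family, order = order,
      dec_lo = dec_lo, dec_hi = dec_hi,
      # analysis is correlation and synthesis convolution, so the synthesis
      # taps coincide with the analysis taps (packages implementing both as
      # convolution store the time-reversed pair instead)
      rec_lo = dec_lo, rec_hi = dec_hi
    ),
    class = "wavelet_spec"
  )
  .validate_wavelet_spec(w)
}

#' Look up one candidate wavelet by name
#'
#' @param name wavelet name such as `"db4"`, `"sym9"`, `"coif3"`. `"sym1"` is
#'   an alias for the Haar wavelet (`"db1"`), so that the Symlet family counts
#'   twenty members sym1-sym20.
#' @return a `wavelet_spec`: list with `name`, `family`, `order`, analysis
#'   filter pair `dec_lo`/`dec_hi` and synthesis pair `rec_lo`/`rec_hi`.
#' @export
wavelet_spec <- function(name) {
  filters <- .load_filter_table()
  key <- tolower(name)
  fam <- sub("[0-9]+$", "", key)
  ord <- as.integer(sub("^[a-z]+", "", key))
  family <- switch(fam,
    db = "daubechies", sym = "symlet", coif = "coiflet",
    stop("unknown wavelet family: ", name)
  )
  lookup <- if (key == "sym1") "db1" else key
  if (is.null(filters[[lookup]])) stop("unknown wavelet: ", name)
  .new_wavelet_spec(key, family, ord, filters[[lookup]])
}

#' The 45-wavelet candidate bank
#'
#' Enumerates the orthogonal candidate basis functions considered for EEG
#' denoising: Daubechies db1-db20, Symlets sym1-sym20 and Coiflets
#' coif1-coif5, in that order. sym1 is the Haar wavelet (identical to db1);
#' Symlets proper start at order 2, and the alias keeps the bank at 45
#' members.
#'
#' @param names optional character vector restricting the bank to a subset
#'   (order preserved from the full bank).
#' @return named list of 45 (or fewer) `wavelet_spec` objects.
#' @examples
#' length(list_candidate_wavelets())  # 45
#' @export
list_candidate_wavelets <- function(names = NULL) {
  all_names <- c(
    paste0("db", 1:20), paste0("sym", 1:20), paste0("coif", 1:5)
  )
  if (!is.null(names)) {
    bad <- setdiff(tolower(names), all_names)
    if (length(bad)) stop("unknown wavelets: ", paste(bad, collapse = ", "))
    all_names <- all_names[all_names %in% tolower(names)]
  }
  if (is.null(.bank_env$bank)) {
    .bank_env$bank <- lapply(
      c(paste0("db", 1:20), paste0("sym", 1:20), paste0("coif", 1:5)),
      wavelet_spec
    )
    names(.bank_env$bank) <- c(paste0("db", 1:20), paste0("sym", 1:20), paste0("coif", 1:5))
  }
  .bank_env$bank[all_names]
}

#' @export
print.wavelet_spec <- function(x, ...) {
  cat(sprintf(
    "<wavelet_spec> %s (%s, order %d), filter length %d\n",
    x$name, x$family, x$order, length(x$dec_lo)
  ))
  invisible(x)
}
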