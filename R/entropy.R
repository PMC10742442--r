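#' Shannon entropy of a discrete probability vector
#'
#' Computes \eqn{H = -\sum_i p_i \log_b p_i} with the convention
#' \eqn{0 \log 0 = 0}.
#'
#' @param p Numeric vector of probabilities: non-negative, summing to 1
#'   (within `tol`).
#' @param base Logarithm base (> 1). `exp(1)` gives nats (the default),
#'   2 gives bits.
#' @param tol Tolerance on the sum-to-one check.
#' @return Entropy in `log(base)` units; a value in `[0, log_base(length(p))]`.
#' @examples
#' shannon_entropy(c(0.5, 0.5), base = 2)  # 1 bit
#' shannon_entropy(c(1, 0))                # 0
#' @export
shannon_entropy <- function(p, base = exp(1), tol = 1e-9) {
  validate_probabilities(p, tol = tol)
  if (base <= 1) stop("`base` must be > 1", call. = FALSE)
  nz <- p > 0
  -sum(p[nz] * log(p[nz], base = base))
}

validate_probabilities <- function(p, tol = 1e-9) {
  if (!is.numeric(p) || length(p) < 1L) {
    stop("probabilities must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(p)) stop("probabilities contain NA", call. = FALSE)
  if (any(p < 0)) {
    stop(sprintf("negative probability entry: %g", min(p)), call. = FALSE)
  }
  s <- sum(p)
  if (abs(s - 1) > tol) {
    stop(sprintf("probabilities sum to %.12g, not 1 (tolerance %g)", s, tol),
         call. = FALSE)
  }
  invisible(p)
}

#' Bin scheme for shared discretisation
#'
#' A set of strictly increasing bin edges defining half-open bins
#' `[e_i, e_{i+1})`, with the last bin closed at the upper edge. One scheme
#' is shared across all samples of an ensemble so that their histograms are
#' comparable bin by bin.
#'
#' @param edges Strictly increasing numeric vector of length >= 2.
#' @return An object of class `bin_scheme`.
#' @seealso [shared_bins()] for deriving edges from pooled data.
#' @export
bin_scheme <- function(edges) {
  edges <- as.numeric(edges)
  if (length(edges) < 2L || anyNA(edges) || any(diff(edges) <= 0)) {
    stop("`edges` must be >= 2 strictly increasing finite values",
         call. = FALSE)
  }
  structure(list(edges = edges), class = "bin_scheme")
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat(sprintf("<bin_scheme> %d bins over [%g, %g]\n",
              length(x$edges) - 1L, x$edges[1L], x$edges[length(x$edges)]))
  invisible(x)
}

#' Derive a shared bin scheme from pooled observations
#'
#' Applies the Freedman-Diaconis rule to the pooled observations of an
#' ensemble and returns identical edges for every sample. Falls back to
#' Sturges when the interquartile range is zero, and to a single bin when
#' the data are constant.
#'
#' @param pooled Numeric vector: all observations of all samples combined.
#' @param rule `"fd"` (Freedman-Diaconis, default) or `"sturges"`.
#' @param max_bins Upper cap on the bin count (default 1024), guarding
#'   against near-degenerate data whose interquartile range is tiny
#'   relative to the full range.
#' @return A [bin_scheme()].
#' @export
shared_bins <- function(pooled, rule = c("fd", "sturges"),
                        max_bins = 1024L) {
  rule <- match.arg(rule)
  pooled <- as.numeric(pooled)
  if (length(pooled) < 1L || anyNA(pooled)) {
    stop("`pooled` must be non-empty and free of NA", call. = FALSE)
  }
  rng <- range(pooled)
  if (diff(rng) == 0) {
    # constant data: one bin of nominal width around the value
    eps <- max(abs(rng[1L]) * 1e-8, 1e-8)
    return(bin_scheme(c(rng[1L] - eps, rng[1L] + eps)))
  }
  n_bins <- if (rule == "fd") {
    h <- 2 * stats::IQR(pooled) / length(pooled)^(1 / 3)
    if (h <= 0) grDevices::nclass.Sturges(pooled) else
      max(1L, ceiling(diff(rng) / h))
  } else {
    grDevices::nclass.Sturges(pooled)
  }
  n_bins <- min(n_bins, max_bins)
  bin_scheme(seq(rng[1L], rng[2L], length.out = n_bins + 1L))
}

#' Discretise continuous observations on a bin scheme
#'
#' Counts observations per bin (half-open `[e_i, e_{i+1})`, last bin closed)
#' and normalises the counts to a probability vector.
#'
#' @param observations Numeric vector, all values within
#'   `[first edge, last edge]`.
#' @param bins A [bin_scheme()].
#' @return Probability vector of length `length(edges) - 1`.
#' @export
discretise <- function(observations, bins) {
  stopifnot(inherits(bins, "bin_scheme"))
  observations <- as.numeric(observations)
  if (length(observations) < 1L) stop("no observations", call. = FALSE)
  e <- bins$edges
  out <- observations < e[1L] | observations > e[length(e)]
  if (any(out)) {
    stop(sprintf("observation %g outside bin range [%g, %g]",
                 observations[which(out)[1L]], e[1L], e[length(e)]),
         call. = FALSE)
  }
  idx <- findInterval(observations, e, rightmost.closed = TRUE,
                      left.open = FALSE)
  counts <- tabulate(idx, nbins = length(e) - 1L)
  counts / sum(counts)
}

#' Normalised binned Shannon entropy
#'
#' Shannon entropy of the histogram of `observations` on `n_bins` equal bins
#' over `support`, divided by `log(n_bins)` so the result lies in `[0, 1]`.
#' This is the classic bin-dependent baseline that the density-variance
#' estimator is designed to track without needing a bin count.
#'
#' @param observations Numeric vector.
#' @param n_bins Number of equal-width bins (>= 2).
#' @param support Length-2 numeric interval containing the observations.
#' @return A value in `[0, 1]`.
#' @export
normalised_binned_entropy <- function(observations, n_bins,
                                      support = range(observations)) {
  if (n_bins < 2L) stop("`n_bins` must be >= 2", call. = FALSE)
  bins <- bin_scheme(seq(support[1L], support[2L], length.out = n_bins + 1L))
  p <- discretise(observations, bins)
  shannon_entropy(p) / log(n_bins)
}
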