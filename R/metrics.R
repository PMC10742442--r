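#' Pooled (point-wise mean) distribution of an ensemble
#'
#' The weighted point-wise mean of the per-sample probability vectors,
#' continuous samples having been discretised on the ensemble's shared bin
#' scheme.
#'
#' @param ens An [ensemble()].
#' @return A probability vector over the shared bins/categories.
#' @export
pooled_distribution <- function(ens) {
  stopifnot(inherits(ens, "ensemble"))
  drop(ens$weights %*% ens$probs)
}

#' Incoherence of an ensemble
#'
#' The weighted spread of per-sample entropies \eqn{H_k} around the entropy
#' \eqn{\tilde H} of the pooled distribution:
#' \deqn{I = \sqrt{\frac{1}{\tilde H} \sum_k w_k (\tilde H - H_k)^2}}
#' An incoherent ensemble is one whose replicates manifest materially
#' different outcome distributions; `I = 0` iff every sample entropy equals
#' the pooled entropy.
#'
#' @param ens An [ensemble()].
#' @param base Entropy logarithm base (nats by default; the value of `I`
#'   depends on the unit through the `1/\tilde H` factor).
#' @param variant `"rooted"` (default) or `"squared"` — the un-rooted form
#'   \eqn{(1/\tilde H) \sum_k w_k (\tilde H - H_k)^2}; the squared variant
#'   equals the rooted one squared.
#' @param estimator Entropy estimator for the per-sample and pooled
#'   entropies: `"binned"` (Shannon entropy on the ensemble's shared
#'   bins/categories; the default) or `"density"` (the bin-free
#'   density-variance estimator applied to the raw observations of
#'   continuous samples, rescaled to `[0, 1]`). The density estimator is
#'   insensitive to sub-resolution noise in near-degenerate ensembles and
#'   its entropies are already normalised, which removes the `1/\tilde H`
#'   amplification when the pooled entropy is small.
#' @param params Calibrated [dv_params()] (density estimator only).
#' @param scale_range Length-2 interval mapped affinely onto `[0, 1]`
#'   before density estimation; defaults to the range of the pooled
#'   observations. Supply a fixed physical range to compare ensembles on a
#'   common absolute scale.
#' @return `I >= 0`, with attribute `degenerate = TRUE` (and a warning) when
#'   the pooled entropy is 0, in which case `I = 0`.
#' @export
incoherence <- function(ens, base = exp(1),
                        variant = c("rooted", "squared"),
                        estimator = c("binned", "density"),
                        params = dv_default_calibrated(),
                        scale_range = NULL) {
  stopifnot(inherits(ens, "ensemble"))
  variant <- match.arg(variant)
  estimator <- match.arg(estimator)
  if (estimator == "binned") {
    h_pool <- shannon_entropy(pooled_distribution(ens), base = base)
    h_k <- apply(ens$probs, 1L, shannon_entropy, base = base)
  } else {
    if (ens$kind != "continuous") {
      stop("estimator = 'density' requires continuous samples",
           call. = FALSE)
    }
    obs <- lapply(ens$samples, `[[`, "observations")
    pooled <- unlist(obs, use.names = FALSE)
    if (is.null(scale_range)) scale_range <- range(pooled)
    span <- diff(scale_range)
    if (span <= 0) {
      warning("degenerate observations (zero range); incoherence set to 0")
      return(structure(0, degenerate = TRUE))
    }
    rescale <- function(x) (x - scale_range[1L]) / span
    h_k <- vapply(obs, function(o) {
      density_variance_entropy(rescale(o), params)
    }, numeric(1L))
    h_pool <- density_variance_entropy(rescale(pooled), params)
  }
  if (h_pool <= 0) {
    warning("pooled entropy is 0; incoherence set to 0")
    return(structure(0, degenerate = TRUE))
  }
  i2 <- sum(ens$weights * (h_pool - h_k)^2) / h_pool
  if (variant == "rooted") sqrt(i2) else i2
}

# JSD between two probability vectors (same support) with mixture weights
# wa + wb = 1; nats. Clips tiny negative rounding noise to 0.
jsd_probs <- function(p, q, wa, wb) {
  h_mix <- shannon_entropy(wa * p + wb * q)
  d <- wa * (h_mix - shannon_entropy(p)) + wb * (h_mix - shannon_entropy(q))
  if (d < -1e-12) stop("internal error: JSD < -1e-12", call. = FALSE)
  max(d, 0)
}

#' Pairwise Jensen-Shannon divergence between two samples
#'
#' \eqn{d_{ab} = w_a(\tilde H_{ab} - H_a) + w_b(\tilde H_{ab} - H_b)} where
#' \eqn{\tilde H_{ab}} is the entropy of the \eqn{w}-weighted pooled pair.
#' Symmetric, non-negative, and bounded by the entropy of the weight vector
#' (at most `ln 2` nats). The JSD is used rather than the Kullback-Leibler
#' divergence because it stays finite for distributions with disjoint
#' support.
#'
#' @param a,b [replicate_sample()] objects of the same kind.
#' @param weighting `"equal"` (w = 1/2 each, default) or `"proportional"`
#'   (w = n / (n_a + n_b)).
#' @param bins Shared [bin_scheme()] for continuous samples; derived from
#'   the pooled pair when omitted.
#' @return Divergence in nats.
#' @export
pairwise_jsd <- function(a, b, weighting = c("equal", "proportional"),
                         bins = NULL) {
  weighting <- match.arg(weighting)
  ens <- ensemble(list(a, b), weighting = weighting, bins = bins)
  jsd_probs(ens$probs[1L, ], ens$probs[2L, ],
            ens$weights[1L], ens$weights[2L])
}

#' All pairwise divergences of an ensemble
#'
#' Computes the Jensen-Shannon divergence for every unordered pair of
#' samples (K(K-1)/2 values) and normalises by `ln 2`, the theoretical
#' maximum for equal pairwise weights, so normalised values lie in `[0, 1]`.
#'
#' @param ens An [ensemble()]. Pairwise mixture weights follow its weighting
#'   scheme: 1/2 each under `"equal"`, n/(n_a+n_b) under `"proportional"`.
#' @return An object of class `divergence_set`: a data frame with columns
#'   `a`, `b` (sample ids), `raw` (nats) and `normalised`, plus attribute
#'   `normaliser = log(2)`.
#' @export
divergence_set <- function(ens) {
  stopifnot(inherits(ens, "ensemble"))
  k <- nrow(ens$probs)
  pairs <- utils::combn(k, 2L)
  raw <- apply(pairs, 2L, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    if (ens$weighting == "equal") {
      wa <- 0.5; wb <- 0.5
    } else {
      wa <- ens$n[i] / (ens$n[i] + ens$n[j]); wb <- 1 - wa
    }
    jsd_probs(ens$probs[i, ], ens$probs[j, ], wa, wb)
  })
  out <- data.frame(a = ens$ids[pairs[1L, ]], b = ens$ids[pairs[2L, ]],
                    raw = raw, normalised = raw / log(2),
                    stringsAsFactors = FALSE)
  structure(out, normaliser = log(2),
            class = c("divergence_set", "data.frame"))
}

#' Cohesion of an ensemble
#'
#' \eqn{C = (1 - H(G))^2}, where \eqn{H(G)} is the density-variance entropy
#' of the set of normalised pairwise Jensen-Shannon divergences. Cohesion is
#' 1 when all replicate distributions are identical (all divergences 0) and
#' approaches 0 when the divergences spread evenly over `[0, 1]` — i.e. when
#' the replicates share no recognisable set of scenarios. Ensembles whose
#' replicates fall into a few well-separated scenarios score high on
#' cohesion even when their incoherence is large.
#'
#' @param ens An [ensemble()].
#' @param params Calibrated [dv_params()] for the density-variance
#'   estimator.
#' @return A value in `[0, 1]`.
#' @export
cohesion <- function(ens, params = dv_default_calibrated()) {
  d <- divergence_set(ens)
  (1 - density_variance_entropy(d$normalised, params))^2
}

#' Full incoherence/cohesion report for an ensemble
#'
#' Bundles the pooled entropy, per-sample entropies, incoherence (both
#' variants), the divergence set, the divergence entropy and the cohesion
#' into one report.
#'
#' @param ens An [ensemble()].
#' @param params Calibrated [dv_params()].
#' @param base Entropy base for the incoherence part (nats by default).
#' @return An object of class `ensemble_report`: a list with elements
#'   `H_pooled`, `H_k`, `incoherence`, `incoherence_squared`,
#'   `incoherence_variant`, `degenerate`, `divergences_raw`,
#'   `divergences_normalised`, `pairs`, `H_G`, `cohesion`, `weighting`,
#'   `base`, `params`.
#' @export
analyse_ensemble <- function(ens, params = dv_default_calibrated(),
                             base = exp(1)) {
  stopifnot(inherits(ens, "ensemble"))
  h_pool <- shannon_entropy(pooled_distribution(ens), base = base)
  h_k <- apply(ens$probs, 1L, shannon_entropy, base = base)
  degenerate <- h_pool <= 0
  i2 <- if (degenerate) 0 else sum(ens$weights * (h_pool - h_k)^2) / h_pool
  d <- divergence_set(ens)
  h_g <- density_variance_entropy(d$normalised, params)
  structure(list(
    H_pooled = h_pool,
    H_k = stats::setNames(h_k, ens$ids),
    incoherence = sqrt(i2),
    incoherence_squared = i2,
    incoherence_variant = "rooted",
    degenerate = degenerate,
    pairs = d[, c("a", "b")],
    divergences_raw = d$raw,
    divergences_normalised = d$normalised,
    H_G = h_g,
    cohesion = (1 - h_g)^2,
    weighting = ens$weighting,
    base = base,
    params = params[c("k", "r_points", "support", "v0", "v1")]
  ), class = "ensemble_report")
}

#' @export
print.ensemble_report <- function(x, ...) {
  cat("<ensemble_report>\n")
  cat(sprintf("  pooled entropy : %.6g (base %g)\n", x$H_pooled, x$base))
  cat(sprintf("  incoherence    : %.6g (%s%s)\n", x$incoherence,
              x$incoherence_variant,
              if (x$degenerate) ", degenerate pool" else ""))
  cat(sprintf("  divergences    : %d pairs, median normalised %.4g\n",
              length(x$divergences_raw),
              stats::median(x$divergences_normalised)))
  cat(sprintf("  cohesion       : %.6g (H_G = %.6g)\n", x$cohesion, x$H_G))
  invisible(x)
}
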