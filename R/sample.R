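#' A replicate sample
#'
#' One replicate's outcome distribution: either a vector of continuous
#' observations (e.g. the per-patch temperatures of one simulation run) or a
#' named vector of categorical counts (e.g. species counts).
#'
#' @param id Label for the replicate.
#' @param observations Numeric vector of continuous observations, or `NULL`.
#' @param counts Named non-negative numeric vector of categorical counts, or
#'   `NULL`. Exactly one of `observations` / `counts` must be given.
#' @param weight Optional explicit weight (normalised across the ensemble).
#' @return An object of class `replicate_sample`.
#' @export
replicate_sample <- function(id, observations = NULL, counts = NULL,
                             weight = NULL) {
  if (is.null(observations) == is.null(counts)) {
    stop("give exactly one of `observations` or `counts`", call. = FALSE)
  }
  if (!is.null(observations)) {
    observations <- as.numeric(observations)
    if (length(observations) < 1L || anyNA(observations)) {
      stop("`observations` must be non-empty and free of NA", call. = FALSE)
    }
    kind <- "continuous"
    n <- length(observations)
  } else {
    if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
      stop("`counts` must be a named vector", call. = FALSE)
    }
    counts <- stats::setNames(as.numeric(counts), names(counts))
    if (anyNA(counts) || any(counts < 0) || sum(counts) <= 0) {
      stop("`counts` must be non-negative with at least one positive entry",
           call. = FALSE)
    }
    kind <- "categorical"
    n <- sum(counts)
  }
  structure(list(id = as.character(id), kind = kind,
                 observations = observations, counts = counts,
                 n = n, weight = weight),
            class = "replicate_sample")
}

#' @export
print.replicate_sample <- function(x, ...) {
  cat(sprintf("<replicate_sample> id=%s kind=%s n=%g\n", x$id, x$kind, x$n))
  invisible(x)
}

#' An ensemble of replicate samples
#'
#' Groups >= 2 [replicate_sample()]s of the same kind with a weighting
#' scheme. Continuous samples are discretised on one shared bin scheme
#' (Freedman-Diaconis on the pooled observations unless `bins` is given);
#' categorical samples are aligned on the union of their category labels.
#'
#' @param samples List of [replicate_sample()] objects (>= 2, same kind).
#' @param weighting `"equal"` (w = 1/K globally, 1/2 pairwise; the default)
#'   or `"proportional"` (w = n/N).
#' @param bins Optional [bin_scheme()] shared by all continuous samples.
#' @return An object of class `ensemble` with elements `samples`,
#'   `weighting`, `kind`, `weights`, `bins`/`categories`, and `probs` (the
#'   K x B matrix of per-sample probability vectors).
#' @export
ensemble <- function(samples, weighting = c("equal", "proportional"),
                     bins = NULL) {
  weighting <- match.arg(weighting)
  if (!is.list(samples) || length(samples) < 2L) {
    stop("an ensemble needs at least 2 samples", call. = FALSE)
  }
  if (!all(vapply(samples, inherits, logical(1L), "replicate_sample"))) {
    stop("all elements must be replicate_sample objects", call. = FALSE)
  }
  kinds <- vapply(samples, `[[`, character(1L), "kind")
  if (length(unique(kinds)) != 1L) {
    stop("all samples must share one data kind (continuous or categorical)",
         call. = FALSE)
  }
  kind <- kinds[1L]
  ids <- vapply(samples, `[[`, character(1L), "id")
  ns <- vapply(samples, `[[`, numeric(1L), "n")
  weights <- if (weighting == "equal") {
    rep(1 / length(samples), length(samples))
  } else {
    ns / sum(ns)
  }
  explicit <- lapply(samples, `[[`, "weight")
  if (!all(vapply(explicit, is.null, logical(1L)))) {
    w <- vapply(explicit, function(x) if (is.null(x)) NA_real_ else x,
                numeric(1L))
    if (anyNA(w)) stop("either all or no samples may carry explicit weights",
                       call. = FALSE)
    weights <- w / sum(w)
  }
  stopifnot(abs(sum(weights) - 1) < 1e-9)

  if (kind == "continuous") {
    pooled <- unlist(lapply(samples, `[[`, "observations"), use.names = FALSE)
    if (is.null(bins)) bins <- shared_bins(pooled)
    probs <- do.call(rbind, lapply(samples, function(s) {
      discretise(s$observations, bins)
    }))
    categories <- NULL
  } else {
    categories <- unique(unlist(lapply(samples, function(s) names(s$counts))))
    probs <- do.call(rbind, lapply(samples, function(s) {
      full <- stats::setNames(numeric(length(categories)), categories)
      full[names(s$counts)] <- s$counts
      full / sum(full)
    }))
    bins <- NULL
  }
  rownames(probs) <- ids
  structure(list(samples = samples, weighting = weighting, kind = kind,
                 ids = ids, n = ns, weights = weights,
                 bins = bins, categories = categories, probs = probs),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d %s samples, %s weights, %d %s\n",
              length(x$samples), x$kind, x$weighting, ncol(x$probs),
              if (x$kind == "continuous") "shared bins" else "categories"))
  invisible(x)
}
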