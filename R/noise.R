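#' Random alphabet of burst "letters"
#'
#' Each letter is a mixture of two Gaussian components. Component means are
#' uniform on `[0, 20)`, standard deviations are drawn from Normal(1, 0.5)
#' truncated below at `sd_floor`, and each component carries a fixed
#' observation count drawn uniformly from the integers 1..9. A message built
#' from a small alphabet is "organised": bursts repeat a few underlying
#' patterns up to sampling noise.
#'
#' @param n_letters Number of letters (>= 1).
#' @param sd_floor Lower truncation for component standard deviations
#'   (default 0.05), preventing degenerate zero-width components.
#' @return A list of class `alphabet`; each letter has numeric vectors
#'   `mean`, `sd`, `count` of length 2.
#' @export
make_alphabet <- function(n_letters, sd_floor = 0.05) {
  if (n_letters < 1L) stop("`n_letters` must be >= 1", call. = FALSE)
  letters_list <- lapply(seq_len(n_letters), function(i) {
    sd <- stats::rnorm(2L, mean = 1, sd = 0.5)
    while (any(sd <= sd_floor)) {
      bad <- sd <= sd_floor
      sd[bad] <- stats::rnorm(sum(bad), mean = 1, sd = 0.5)
    }
    list(mean = stats::runif(2L, 0, 20), sd = sd,
         count = sample(1:9, 2L, replace = TRUE))
  })
  structure(letters_list, class = "alphabet")
}

#' Generate an organised-noise message
#'
#' For each timestep one letter is picked uniformly from the alphabet and a
#' fresh burst of observations is drawn from that letter's two Gaussian
#' components (component `i` contributes `count[i]` draws). Bursts of the
#' same letter therefore share a pattern but never repeat exactly.
#'
#' @param alphabet An [make_alphabet()] result.
#' @param n_timesteps Number of bursts (>= 2; default 20).
#' @return A list of class `message` with `bursts` (list of numeric
#'   vectors), `labels` (letter index per burst) and `alphabet`.
#' @export
generate_message <- function(alphabet, n_timesteps = 20L) {
  stopifnot(inherits(alphabet, "alphabet"))
  if (length(alphabet) < 1L) stop("empty alphabet", call. = FALSE)
  if (n_timesteps < 2L) stop("`n_timesteps` must be >= 2", call. = FALSE)
  labels <- sample.int(length(alphabet), n_timesteps, replace = TRUE)
  bursts <- lapply(labels, function(l) {
    spec <- alphabet[[l]]
    unlist(lapply(1:2, function(i) {
      stats::rnorm(spec$count[i], mean = spec$mean[i], sd = spec$sd[i])
    }))
  })
  structure(list(bursts = bursts, labels = labels, alphabet = alphabet),
            class = "message")
}

#' @export
print.message <- function(x, ...) {
  cat(sprintf("<message> %d bursts, %d-letter alphabet, %d observations\n",
              length(x$bursts), length(x$alphabet),
              sum(lengths(x$bursts))))
  invisible(x)
}

#' Convert a message to an ensemble
#'
#' One continuous [replicate_sample()] per burst, ids carrying the timestep;
#' the ground-truth letter labels are kept as an attribute.
#'
#' @param msg A [generate_message()] result.
#' @param ... Passed to [ensemble()] (e.g. `weighting`).
#' @return An [ensemble()] with attribute `labels`.
#' @export
message_to_ensemble <- function(msg, ...) {
  stopifnot(inherits(msg, "message"))
  samples <- lapply(seq_along(msg$bursts), function(t) {
    replicate_sample(id = sprintf("t%03d", t), observations = msg$bursts[[t]])
  })
  ens <- ensemble(samples, ...)
  attr(ens, "labels") <- msg$labels
  ens
}

#' Message summary dispersion statistics
#'
#' The naive dispersion summaries of a message: the standard deviation of
#' the pooled observations, the standard deviation of per-burst means, and
#' the standard deviation of per-burst standard deviations. These are the
#' baselines that fail to rank how organised a message is.
#'
#' @param msg A [generate_message()] result.
#' @return Named numeric vector `c(sigma, sigma_mu, sigma_sigma)`.
#' @export
message_dispersion <- function(msg) {
  stopifnot(inherits(msg, "message"))
  mus <- vapply(msg$bursts, mean, numeric(1L))
  sds <- vapply(msg$bursts, stats::sd, numeric(1L))
  c(sigma = stats::sd(unlist(msg$bursts)),
    sigma_mu = stats::sd(mus),
    sigma_sigma = stats::sd(sds, na.rm = TRUE))
}
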