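#' Daisyworld model configuration
#'
#' Parameters of the two-species Daisyworld agent-based model: a toroidal
#' grid of patches, each empty or holding a black or white daisy. Black
#' daisies (low albedo) warm their surroundings, white daisies (high
#' albedo) cool them; through local feedback the population self-regulates
#' the planetary temperature. The solar luminosity `luminosity` is the main
#' control parameter.
#'
#' @param width,height Grid size in patches (default 29 x 29).
#' @param luminosity Solar luminosity `l` (dimensionless multiplier).
#' @param albedo_black,albedo_white,albedo_surface Albedos of black daisies,
#'   white daisies and bare ground (defaults 0.25, 0.75, 0.4).
#' @param solar_constant Scale factor on the incoming flux (default 1).
#' @param max_age Daisy lifespan in ticks (default 25).
#' @param start_black,start_white Initial daisy fractions (defaults 0.30
#'   each; the rest starts empty).
#' @param steps Ticks per run (default 400, comfortably past equilibrium).
#' @param hard_kill If `TRUE`, daisies outside the `[5, 40]` degree
#'   viability band are killed outright each tick; by default viability is
#'   enforced only through the sprouting probability's support.
#' @param seed Optional integer seed applied by [dw_run()].
#' @return An object of class `dw_config`.
#' @export
dw_config <- function(width = 29L, height = 29L, luminosity = 1.0,
                      albedo_black = 0.25, albedo_white = 0.75,
                      albedo_surface = 0.4, solar_constant = 1.0,
                      max_age = 25L, start_black = 0.30, start_white = 0.30,
                      steps = 400L, hard_kill = FALSE, seed = NULL) {
  if (width < 1L || height < 1L) stop("grid must be >= 1x1", call. = FALSE)
  for (a in c(albedo_black, albedo_white, albedo_surface)) {
    if (a < 0 || a > 1) stop("albedos must lie in [0, 1]", call. = FALSE)
  }
  if (start_black < 0 || start_white < 0 || start_black + start_white > 1) {
    stop("start fractions must be non-negative and sum to <= 1",
         call. = FALSE)
  }
  if (steps < 1L) stop("`steps` must be >= 1", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 luminosity = luminosity, albedo_black = albedo_black,
                 albedo_white = albedo_white, albedo_surface = albedo_surface,
                 solar_constant = solar_constant, max_age = as.integer(max_age),
                 start_black = start_black, start_white = start_white,
                 steps = as.integer(steps), hard_kill = hard_kill,
                 seed = seed),
            class = "dw_config")
}

#' Initial Daisyworld state
#'
#' Each patch is independently assigned a species by the start fractions;
#' daisy ages are uniform on `0..max_age-1`; all temperatures start at 0
#' degrees. Uses the current RNG state (seed the session or use [dw_run()]).
#'
#' @param config A [dw_config()].
#' @return A list of class `dw_state` with integer vectors `species`
#'   (0 = empty, 1 = black, 2 = white) and `age`, numeric `temperature`,
#'   and the grid dimensions.
#' @export
dw_init <- function(config) {
  stopifnot(inherits(config, "dw_config"))
  n <- config$width * config$height
  species <- sample(0:2, n, replace = TRUE,
                    prob = c(1 - config$start_black - config$start_white,
                             config$start_black, config$start_white))
  age <- integer(n)
  living <- species != 0L
  age[living] <- sample.int(config$max_age, sum(living), replace = TRUE) - 1L
  structure(list(species = species, age = age, temperature = numeric(n),
                 width = config$width, height = config$height, tick = 0L),
            class = "dw_state")
}

#' Advance a Daisyworld state
#'
#' Applies `n_steps` ticks. Each tick: solar heating (local heating
#' `72 log(absorbed) + 80` with `absorbed = (1 - albedo) l S`, averaged into
#' the patch temperature), 50% diffusion to the 8 toroidal Moore
#' neighbours, ageing and death on reaching `max_age`, then sprouting:
#' each surviving daisy, visited in shuffled order, attempts with
#' probability `0.1457 T - 0.0032 T^2 - 0.6443` (positive roughly for T in
#' [5, 40] degrees) to seed one uniformly chosen Moore neighbour,
#' succeeding only if that patch is empty, so growth slows as
#' neighbourhoods fill.
#'
#' @param state A `dw_state`.
#' @param config The matching [dw_config()].
#' @param n_steps Number of ticks to apply (default 1).
#' @return The advanced `dw_state`.
#' @export
dw_step <- function(state, config, n_steps = 1L) {
  stopifnot(inherits(state, "dw_state"), inherits(config, "dw_config"))
  res <- cpp_dw_simulate(state$species, state$age, state$temperature,
                         config$width, config$height, config$luminosity,
                         as.integer(n_steps), config$albedo_black,
                         config$albedo_white, config$albedo_surface,
                         config$solar_constant, config$max_age,
                         config$hard_kill, FALSE)
  state$species <- res$species
  state$age <- res$age
  state$temperature <- res$temperature
  state$tick <- state$tick + as.integer(n_steps)
  state
}

#' Run one Daisyworld simulation
#'
#' Seeds the RNG (when `config$seed` is set), initialises the world and
#' applies `config$steps` ticks.
#'
#' @param config A [dw_config()].
#' @param record_counts If `TRUE`, keep the per-tick species-count
#'   time series.
#' @return A list of class `dw_run` with `temperature` (final per-patch
#'   values), `counts` (named black/white/empty totals), `species`, `age`,
#'   `config`, and optionally `counts_ts`.
#' @export
dw_run <- function(config, record_counts = FALSE) {
  stopifnot(inherits(config, "dw_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  state <- dw_init(config)
  res <- cpp_dw_simulate(state$species, state$age, state$temperature,
                         config$width, config$height, config$luminosity,
                         config$steps, config$albedo_black,
                         config$albedo_white, config$albedo_surface,
                         config$solar_constant, config$max_age,
                         config$hard_kill, record_counts)
  n <- config$width * config$height
  counts <- c(black = sum(res$species == 1L),
              white = sum(res$species == 2L),
              empty = sum(res$species == 0L))
  stopifnot(sum(counts) == n)
  out <- list(temperature = res$temperature, counts = counts,
              species = res$species, age = res$age, config = config)
  if (record_counts) {
    out$counts_ts <- res$counts_ts
    colnames(out$counts_ts) <- c("black", "white", "empty")
  }
  structure(out, class = "dw_run")
}

#' @export
print.dw_run <- function(x, ...) {
  cat(sprintf(
    "<dw_run> l=%g, %d ticks: %d black, %d white, %d empty; mean T %.2f\n",
    x$config$luminosity, x$config$steps, x$counts[["black"]],
    x$counts[["white"]], x$counts[["empty"]], mean(x$temperature)))
  invisible(x)
}

#' Luminosity sweep with replicate ensembles
#'
#' For each luminosity on the grid, runs `replicates` independently seeded
#' simulations, builds (a) a continuous ensemble of final per-patch
#' temperature distributions and (b) a categorical ensemble of species
#' counts, and computes incoherence and cohesion for both, together with
#' the pooled mean temperature, the mean of replicate means, and the
#' dispersion diagnostics sigma(mu) and sigma(sigma). Replicate seeds are
#' split from `seed` by drawing one integer per run from the master-seeded
#' RNG, so the whole sweep is reproducible end to end.
#'
#' Temperature incoherence is reported twice: `incoherence_temp` uses the
#' density-variance entropy of the raw temperatures on one absolute scale
#' shared by the whole sweep (robust around near-degenerate lifeless or
#' fully-vegetated worlds, and the trace used for tipping-point
#' detection), while `incoherence_temp_binned` applies the shared-bin
#' Shannon form on `temp_bin_width`-degree bins.
#'
#' @param config Base [dw_config()] (its `luminosity` and `seed` are
#'   overridden per run).
#' @param l_min,l_max,l_step Luminosity grid (defaults 0.45 to 1.45 by
#'   0.05).
#' @param replicates Runs per luminosity (default 30).
#' @param seed Master seed for the sweep (default 1).
#' @param params Calibrated [dv_params()] for the cohesion part.
#' @param temp_bin_width Bin width in degrees for the temperature
#'   ensembles (default 1). Temperatures are physical quantities with a
#'   natural measurement resolution; a fixed absolute width keeps
#'   ensembles whose replicates agree to within a bin coherent instead of
#'   resolving sub-degree equilibrium noise.
#' @param keep_runs Keep the individual `dw_run` objects (default `TRUE`).
#' @return A list of class `dw_sweep` with `summary` (one row per
#'   luminosity) and, when kept, `runs` (list of lists of `dw_run`).
#' @export
dw_sweep <- function(config = dw_config(), l_min = 0.45, l_max = 1.45,
                     l_step = 0.05, replicates = 30L, seed = 1L,
                     params = dv_default_calibrated(), temp_bin_width = 1,
                     keep_runs = TRUE) {
  stopifnot(inherits(config, "dw_config"))
  if (!(l_min < l_max)) stop("`l_min` must be < `l_max`", call. = FALSE)
  if (replicates < 2L) stop("`replicates` must be >= 2", call. = FALSE)
  lums <- seq(l_min, l_max, by = l_step)
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max, length(lums) * replicates),
                  nrow = replicates)
  all_runs <- lapply(seq_along(lums), function(li) {
    lapply(seq_len(replicates), function(r) {
      cfg <- config
      cfg$luminosity <- lums[li]
      cfg$seed <- seeds[r, li]
      dw_run(cfg)
    })
  })
  # one absolute temperature scale for the whole sweep, so the density
  # estimator resolves the same physical detail at every luminosity
  sweep_range <- range(unlist(lapply(all_runs, function(rr) {
    lapply(rr, `[[`, "temperature")
  })))
  rows <- vector("list", length(lums))
  for (li in seq_along(lums)) {
    runs <- all_runs[[li]]
    temp_samples <- lapply(seq_along(runs), function(r) {
      replicate_sample(sprintf("rep%02d", r),
                       observations = runs[[r]]$temperature)
    })
    # species counts can be all-empty; counts include the empty category so
    # the categorical sample is always valid
    count_samples <- lapply(seq_along(runs), function(r) {
      replicate_sample(sprintf("rep%02d", r), counts = runs[[r]]$counts)
    })
    pooled_t <- unlist(lapply(runs, `[[`, "temperature"))
    tbins <- temperature_bins(pooled_t, temp_bin_width)
    temp_ens <- ensemble(temp_samples, bins = tbins)
    rep_temp <- suppressWarnings(
      analyse_ensemble(temp_ens, params = params))
    i_temp_dv <- suppressWarnings(
      incoherence(temp_ens, estimator = "density", params = params,
                  scale_range = sweep_range))
    rep_spec <- suppressWarnings(
      analyse_ensemble(ensemble(count_samples), params = params))
    mus <- vapply(runs, function(x) mean(x$temperature), numeric(1L))
    sds <- vapply(runs, function(x) stats::sd(x$temperature), numeric(1L))
    rows[[li]] <- data.frame(
      luminosity = lums[li],
      mean_of_means = mean(mus),
      pooled_mean = mean(unlist(lapply(runs, `[[`, "temperature"))),
      sigma_mu = stats::sd(mus),
      sigma_sigma = stats::sd(sds),
      incoherence_temp = as.numeric(i_temp_dv),
      incoherence_temp_binned = as.numeric(rep_temp$incoherence),
      cohesion_temp = rep_temp$cohesion,
      incoherence_species = as.numeric(rep_spec$incoherence),
      cohesion_species = rep_spec$cohesion,
      black_mean = mean(vapply(runs, function(x) x$counts[["black"]],
                               numeric(1L))),
      white_mean = mean(vapply(runs, function(x) x$counts[["white"]],
                               numeric(1L))))
  }
  structure(list(summary = do.call(rbind, rows),
                 runs = if (keep_runs) all_runs else NULL,
                 seed = seed, replicates = replicates, config = config,
                 temperature_range = sweep_range),
            class = "dw_sweep")
}

#' @export
print.dw_sweep <- function(x, ...) {
  cat(sprintf("<dw_sweep> %d luminosities x %d replicates (seed %s)\n",
              nrow(x$summary), x$replicates, format(x$seed)))
  print(x$summary[, c("luminosity", "mean_of_means", "incoherence_temp",
                      "cohesion_temp")], row.names = FALSE)
  invisible(x)
}

# Fixed-width bins spanning the pooled temperatures, aligned to multiples
# of the width; collapses to a single bin when the range fits inside one.
temperature_bins <- function(pooled, width) {
  lo <- floor(min(pooled) / width) * width
  hi <- ceiling(max(pooled) / width) * width
  if (hi <= lo) hi <- lo + width
  bin_scheme(seq(lo, hi, by = width))
}

#' Detect elevated regions in an incoherence trace
#'
#' Finds maximal runs of consecutive grid points whose value exceeds the
#' trace mean plus one standard deviation. Around tipping points the
#' replicate ensembles split between attractor states, so the incoherence
#' trace rises above its background in a contiguous run of luminosities.
#'
#' @param values Numeric trace (>= 5 points), e.g.
#'   `summary$incoherence_temp` of a [dw_sweep()].
#' @param x Optional grid coordinates (defaults to the indices).
#' @return A data frame with one row per region: `start`, `end` (grid
#'   coordinates), `peak_x`, `peak_value`; zero rows for a flat trace.
#' @export
detect_peaks <- function(values, x = seq_along(values)) {
  if (length(values) < 5L) stop("need >= 5 trace points", call. = FALSE)
  if (length(x) != length(values)) stop("`x` length mismatch", call. = FALSE)
  threshold <- mean(values) + stats::sd(values)
  above <- values > threshold
  if (!any(above)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      peak_x = numeric(0), peak_value = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  do.call(rbind, lapply(keep, function(i) {
    idx <- starts[i]:ends[i]
    data.frame(start = x[starts[i]], end = x[ends[i]],
               peak_x = x[idx[which.max(values[idx])]],
               peak_value = max(values[idx]))
  }))
}
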