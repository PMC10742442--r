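test_that("world initialisation respects grid size and start fractions", {
  cfg <- dw_config()
  set.seed(181)
  st <- dw_init(cfg)
  expect_length(st$species, 841L)
  # binomial expectation 252.3, sd 13.3: check within 4 sd
  expect_lt(abs(sum(st$species == 1L) - 0.3 * 841), 4 * sqrt(841 * 0.3 * 0.7))
  expect_true(all(st$age[st$species == 0L] == 0L))
  expect_true(all(st$age < cfg$max_age))
  expect_true(all(st$temperature == 0))
  set.seed(99); a <- dw_init(cfg)
  set.seed(99); b <- dw_init(cfg)
  expect_identical(a, b)
})

test_that("config validation rejects impossible parameters", {
  expect_error(dw_config(albedo_black = 1.5), "albedo")
  expect_error(dw_config(start_black = 0.7, start_white = 0.5), "fractions")
  expect_error(dw_config(steps = 0), "steps")
})

test_that("heating follows 72*log(absorbed)+80 with 50% equal diffusion", {
  # bare world with albedo 0 and luminosity 1: absorbed = 1, heating = 80,
  # temperature moves from 0 to (0+80)/2 = 40 on every patch; diffusion
  # between equal patches changes nothing
  cfg <- dw_config(width = 5, height = 5, luminosity = 1,
                   albedo_surface = 0, start_black = 0, start_white = 0)
  st <- structure(list(species = integer(25), age = integer(25),
                       temperature = numeric(25), width = 5L, height = 5L,
                       tick = 0L), class = "dw_state")
  st1 <- dw_step(st, cfg)
  expect_equal(st1$temperature, rep(40, 25))
  # absorbed <= 0 uses the fallback heating of 80
  cfg0 <- dw_config(width = 5, height = 5, luminosity = 0,
                    albedo_surface = 0.4, start_black = 0, start_white = 0)
  st2 <- dw_step(st, cfg0)
  expect_equal(st2$temperature, rep(40, 25))
})

test_that("patch counts are conserved and empty worlds stay empty", {
  cfg <- dw_config(luminosity = 1.0, steps = 50, seed = 191)
  run <- dw_run(cfg, record_counts = TRUE)
  expect_equal(sum(run$counts), 841L)
  expect_true(all(rowSums(run$counts_ts) == 841L))
  empty_cfg <- dw_config(start_black = 0, start_white = 0, luminosity = 1,
                         steps = 30, seed = 201)
  empty_run <- dw_run(empty_cfg)
  expect_equal(empty_run$counts[["empty"]], 841L)
})

test_that("runs are deterministic under a fixed seed", {
  a <- dw_run(dw_config(luminosity = 0.9, steps = 120, seed = 211))
  b <- dw_run(dw_config(luminosity = 0.9, steps = 120, seed = 211))
  expect_identical(a$temperature, b$temperature)
  expect_identical(a$species, b$species)
  expect_true(all(is.finite(a$temperature)))
})

test_that("lifeless equilibrium temperature increases with luminosity", {
  temps <- vapply(c(0.5, 0.8, 1.1, 1.4), function(l) {
    cfg <- dw_config(start_black = 0, start_white = 0, luminosity = l,
                     steps = 100, seed = 221)
    mean(dw_run(cfg)$temperature)
  }, numeric(1L))
  expect_true(all(diff(temps) > 0))
})

test_that("luminosity selects the surviving community", {
  r_dead <- dw_run(dw_config(luminosity = 0.45, seed = 231))
  expect_equal(r_dead$counts[["black"]] + r_dead$counts[["white"]], 0L)
  r_black <- dw_run(dw_config(luminosity = 0.6, seed = 241))
  expect_gt(r_black$counts[["black"]], 0L)
  expect_equal(r_black$counts[["white"]], 0L)
  r_both <- dw_run(dw_config(luminosity = 1.0, seed = 251))
  expect_gt(r_both$counts[["black"]], 0L)
  expect_gt(r_both$counts[["white"]], 0L)
})

test_that("the dead-to-black transition is bistable near l = 0.53", {
  outcomes <- vapply(1:10, function(s) {
    run <- dw_run(dw_config(luminosity = 0.53, steps = 200, seed = 7000 + s))
    run$counts[["black"]] > 0L
  }, logical(1L))
  expect_gt(sum(outcomes), 0L)
  expect_lt(sum(outcomes), 10L)
})

test_that("coexistence-band replicates self-regulate into the viability band", {
  mus <- vapply(1:5, function(s) {
    mean(dw_run(dw_config(luminosity = 1.0, steps = 200, seed = 260 + s))$temperature)
  }, numeric(1L))
  expect_true(stats::median(mus) > 5 && stats::median(mus) < 40)
})

test_that("identical replicate seeds give a fully coherent ensemble", {
  runs <- lapply(1:5, function(i) {
    dw_run(dw_config(luminosity = 0.9, steps = 100, seed = 271))
  })
  samples <- lapply(seq_along(runs), function(i) {
    replicate_sample(i, observations = runs[[i]]$temperature)
  })
  ens <- ensemble(samples)
  expect_equal(suppressWarnings(as.numeric(incoherence(ens))), 0)
  expect_equal(cohesion(ens, acc_params), 1)
})

test_that("sweep bookkeeping: grids, replicates, mean identities", {
  sw <- dw_sweep(dw_config(steps = 60), l_min = 0.8, l_max = 1.0,
                 l_step = 0.1, replicates = 3, seed = 281)
  expect_equal(nrow(sw$summary), 3L)
  expect_length(sw$runs[[1]], 3L)
  expect_length(sw$runs[[1]][[1]]$temperature, 841L)
  # equal replicate sizes make mean-of-means equal the pooled mean
  expect_equal(sw$summary$mean_of_means, sw$summary$pooled_mean,
               tolerance = 1e-9)
  # resuming from the same master seed reproduces the sweep
  sw2 <- dw_sweep(dw_config(steps = 60), l_min = 0.8, l_max = 1.0,
                  l_step = 0.1, replicates = 3, seed = 281)
  expect_equal(sw$summary, sw2$summary)
})

test_that("peak detection isolates contiguous super-threshold runs", {
  expect_equal(nrow(detect_peaks(rep(1, 10))), 0L)
  spike <- c(0, 0, 0, 5, 0, 0, 0, 0)
  pk <- detect_peaks(spike, seq(0.1, 0.8, by = 0.1))
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$peak_x, 0.4)
  three <- c(0, 3, 0, 0, 3, 3, 0, 0, 0, 4, 0)
  pk3 <- detect_peaks(three)
  expect_equal(nrow(pk3), 3L)
  expect_equal(pk3$peak_value, c(3, 3, 4))
  expect_error(detect_peaks(1:3), ">= 5")
})
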