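two_point_ensemble <- function(weighting = "equal") {
  ensemble(list(replicate_sample("a", counts = c(x = 1)),
                replicate_sample("b", counts = c(y = 1))),
           weighting = weighting)
}

test_that("ensembles validate membership and homogeneity", {
  s <- replicate_sample("a", counts = c(x = 1))
  expect_error(ensemble(list(s)), "at least 2")
  expect_error(ensemble(list(s, replicate_sample("b", observations = 1:3))),
               "kind")
  expect_error(replicate_sample("a"), "exactly one")
  expect_error(replicate_sample("a", counts = c(x = -1)), "non-negative")
  expect_error(replicate_sample("a", counts = 5), "named")
})

test_that("pooled distribution is the weighted point-wise mean", {
  expect_equal(pooled_distribution(two_point_ensemble()), c(x = 0.5, y = 0.5))
  same <- ensemble(list(replicate_sample("a", counts = c(x = 2, y = 6)),
                        replicate_sample("b", counts = c(x = 2, y = 6))))
  expect_equal(pooled_distribution(same), c(x = 0.25, y = 0.75))
  prop <- ensemble(list(replicate_sample("a", counts = c(x = 3)),
                        replicate_sample("b", counts = c(y = 1))),
                   weighting = "proportional")
  expect_equal(pooled_distribution(prop), c(x = 0.75, y = 0.25))
})

test_that("incoherence matches hand-evaluated anchors", {
  same <- ensemble(list(replicate_sample("a", counts = c(x = 2, y = 6)),
                        replicate_sample("b", counts = c(x = 2, y = 6))))
  expect_equal(incoherence(same), 0)
  # two degenerate samples on disjoint categories, base 2: H~=1, H_k=0
  expect_equal(incoherence(two_point_ensemble(), base = 2), 1)
  # squared variant is the square of the rooted one
  set.seed(71)
  ens <- ensemble(random_categorical_samples(4, 3))
  expect_equal(incoherence(ens, variant = "squared"), incoherence(ens)^2)
})

test_that("degenerate pooled entropy yields zero incoherence with a flag", {
  ens <- ensemble(list(replicate_sample("a", counts = c(x = 5)),
                       replicate_sample("b", counts = c(x = 2))))
  expect_warning(i <- incoherence(ens), "pooled entropy")
  expect_equal(as.numeric(i), 0)
  expect_true(attr(i, "degenerate"))
})

test_that("pairwise JSD reproduces closed-form values", {
  a <- replicate_sample("a", counts = c(x = 4))
  b <- replicate_sample("b", counts = c(y = 9))
  expect_equal(pairwise_jsd(a, a), 0)
  # disjoint support, equal weights: entropy of the weights = ln 2
  expect_equal(pairwise_jsd(a, b), log(2))
  # [1,0] vs [0.5,0.5]: pooled [0.75,0.25], 0.311278 bits
  c1 <- replicate_sample("c", counts = c(x = 2, y = 2))
  expect_equal(pairwise_jsd(a, c1) / log(2), 0.3112781, tolerance = 1e-6)
  # proportional weighting is bounded by the weight entropy
  d <- pairwise_jsd(replicate_sample("a", counts = c(x = 3)),
                    replicate_sample("b", counts = c(y = 1)),
                    weighting = "proportional")
  expect_equal(d, oracle_entropy(c(0.75, 0.25)))
})

test_that("JSD is symmetric, non-negative and bounded by ln 2 (fuzzed)", {
  set.seed(81)
  for (i in 1:100) {
    ss <- random_categorical_samples(2, sample(2:6, 1L))
    d_ab <- pairwise_jsd(ss[[1]], ss[[2]])
    d_ba <- pairwise_jsd(ss[[2]], ss[[1]])
    expect_equal(d_ab, d_ba)
    expect_gte(d_ab, 0)
    expect_lte(d_ab, log(2) + 1e-12)
  }
})

test_that("divergence sets enumerate all unordered pairs, normalised", {
  same <- lapply(1:3, function(i) {
    replicate_sample(i, counts = c(x = 2, y = 1))
  })
  d <- divergence_set(ensemble(same))
  expect_equal(nrow(d), 3L)
  expect_equal(d$normalised, rep(0, 3))
  d2 <- divergence_set(two_point_ensemble())
  expect_equal(d2$normalised, 1)
  set.seed(91)
  d30 <- divergence_set(ensemble(random_categorical_samples(30, 3)))
  expect_equal(nrow(d30), choose(30, 2))
  expect_true(all(d30$normalised >= 0 & d30$normalised <= 1))
})

test_that("incoherence and divergences agree with the brute-force oracle", {
  set.seed(101)
  for (i in 1:25) {
    k <- sample(2:4, 1L)
    n_cat <- sample(2:3, 1L)
    samples <- random_categorical_samples(k, n_cat)
    ens <- ensemble(samples)
    rows <- lapply(seq_len(k), function(j) ens$probs[j, ])
    expect_equal(as.numeric(incoherence(ens)),
                 oracle_incoherence(rows, ens$weights), tolerance = 1e-12)
    d <- divergence_set(ens)
    pair_idx <- utils::combn(k, 2L)
    for (pi in seq_len(ncol(pair_idx))) {
      i1 <- pair_idx[1L, pi]; i2 <- pair_idx[2L, pi]
      expect_equal(d$raw[pi], oracle_jsd(rows[[i1]], rows[[i2]], 0.5, 0.5),
                   tolerance = 1e-12)
    }
  }
})

test_that("cohesion is 1 for identical samples and low for spread ones", {
  same <- lapply(1:5, function(i) {
    replicate_sample(i, counts = c(x = 3, y = 1, z = 2))
  })
  expect_equal(cohesion(ensemble(same), acc_params), 1)
  # incoherence 0 implies cohesion 1 (identical samples force both)
  expect_equal(incoherence(ensemble(same)), 0)
})

test_that("density-estimator incoherence handles continuous ensembles", {
  set.seed(111)
  obs <- lapply(1:4, function(i) stats::rnorm(100, mean = (i > 2) * 10))
  ens <- ensemble(lapply(1:4, function(i) {
    replicate_sample(i, observations = obs[[i]])
  }))
  i_dv <- incoherence(ens, estimator = "density", params = acc_params)
  expect_gte(as.numeric(i_dv), 0)
  # near-identical narrow replicates register as coherent
  flat <- ensemble(lapply(1:4, function(i) {
    replicate_sample(i, observations = stats::rnorm(100, 0, 1e-4))
  }))
  i_flat <- suppressWarnings(
    incoherence(flat, estimator = "density", params = acc_params,
                scale_range = c(-50, 50)))
  expect_lt(as.numeric(i_flat), 0.05)
  expect_error(incoherence(ensemble(random_categorical_samples(2, 2)),
                           estimator = "density"), "continuous")
})

test_that("analyse_ensemble bundles consistent metrics", {
  set.seed(121)
  obs <- lapply(1:5, function(i) stats::rnorm(200, mean = (i > 2) * 10))
  ens <- ensemble(lapply(1:5, function(i) {
    replicate_sample(i, observations = obs[[i]])
  }))
  rep <- analyse_ensemble(ens, acc_params)
  expect_equal(rep$incoherence, as.numeric(incoherence(ens)))
  expect_equal(rep$cohesion, cohesion(ens, acc_params))
  expect_equal(rep$incoherence_squared, rep$incoherence^2)
  expect_equal(rep$cohesion, (1 - rep$H_G)^2)
  expect_length(rep$divergences_raw, 10L)
  # two well-separated scenarios: incoherent but cohesive
  expect_gt(rep$incoherence, 0)
  expect_gt(rep$cohesion, 0.5)
})
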