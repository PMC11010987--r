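test_that("normalization centres the negative cluster at zero", {
  set.seed(21)
  # constant well: everything maps to zero
  wc <- normalize_well(make_well(rep(1234, 500)))
  expect_true(all(abs(wc$ch1) < 1e-9))

  # two well-separated clusters
  neg <- rnorm(19700, 1000, 50)
  pos <- rnorm(300, 5000, 50)
  w <- normalize_well(make_well(c(neg, pos)))
  neg_centre <- mean(w$ch1[seq_along(neg)])
  expect_lt(abs(neg_centre), 5)
  pos_centre <- mean(w$ch1[19700 + seq_along(pos)])
  expect_lt(abs(pos_centre - 4000), 25)
})

test_that("few-droplet wells warn instead of erroring", {
  expect_warning(normalize_well(make_well(rnorm(50, 1000, 10))),
                 "low-confidence")
})

test_that("classification counts droplets above the threshold", {
  set.seed(22)
  amp <- c(rnorm(19700, 0, 50), rnorm(300, 4000, 50))
  w <- make_well(amp, normalized = TRUE)
  expect_identical(classify_droplets(w, threshold = 2000)$k_m, 300L)
  expect_identical(classify_droplets(w, threshold = max(amp) + 1)$k_m, 0L)
  wpos <- make_well(abs(rnorm(200, 4000, 10)) + 1, normalized = TRUE)
  expect_identical(classify_droplets(wpos, threshold = 0)$k_m, 200L)
  expect_error(classify_droplets(w, threshold = -5), "below 0")
  # automatic threshold agrees with the counting oracle
  auto <- classify_droplets(w)
  expect_identical(auto$k_m, 300L)
})

test_that("classification is invariant to a constant amplitude offset", {
  set.seed(23)
  amp <- c(rnorm(9800, 1000, 60), rnorm(200, 5000, 60))
  w1 <- normalize_well(make_well(amp))
  w2 <- normalize_well(make_well(amp + 750))
  expect_identical(classify_droplets(w1)$k_m, classify_droplets(w2)$k_m)
})

test_that("single-cluster wells yield zero positives under the automatic threshold", {
  set.seed(24)
  w <- make_well(rnorm(20000, 0, 50), normalized = TRUE)
  expect_identical(classify_droplets(w)$k_m, 0L)
})

test_that("Poisson inversion matches its closed form", {
  expect_equal(poisson_concentration(0, 100)$lambda, 0)
  expect_equal(poisson_concentration(50, 100)$lambda, log(2))
  q <- poisson_concentration(3935, 20000)
  expect_equal(q$lambda, -log(1 - 3935 / 20000))
  expect_equal(q$copies_reaction, -log(1 - 0.19675) * 20000)
  expect_equal(q$copies_reaction, 4381.4, tolerance = 1e-4)
  expect_error(poisson_concentration(100, 100), "saturated")
  expect_error(poisson_concentration(-1, 100), "0 <= k <= n")
})

test_that("lambda is monotone in k and copies/mL scales linearly", {
  lam <- sapply(0:99, function(k) poisson_concentration(k, 100)$lambda)
  expect_true(all(diff(lam) > 0))
  vm <- volume_model(plasma_ml = 2)
  expect_equal(copies_per_ml(200, vm), 2 * copies_per_ml(100, vm))
})

test_that("volume back-calculation follows the unit-factor chain", {
  vm <- volume_model(plasma_ml = 3, eluate_ul = 12, input_ul = 4,
                     preamp_gain = 1)
  expect_equal(copies_per_ml(300, vm), 300)  # 300 * (12/4) / 1 / 3
  # ideal 12-cycle doubling gain cancels against 4096x more copies
  vm_gain <- volume_model(plasma_ml = 3, preamp_gain = 2^12)
  expect_equal(copies_per_ml(300 * 4096, vm_gain), copies_per_ml(300, vm))
  vm1 <- volume_model(plasma_ml = 1, eluate_ul = 1, input_ul = 1,
                      preamp_gain = 1)
  expect_equal(copies_per_ml(123.4, vm1), 123.4)
  expect_error(volume_model(plasma_ml = 0), "> 0")
})

test_that("the positive-call rule needs two wells above five droplets", {
  expect_true(call_sample(c(7, 12)))
  expect_false(call_sample(c(7, 5)))   # 5 is not "more than 5"
  expect_false(call_sample(c(0, 0)))
  expect_true(call_sample(c(6, 6, 0)))
  expect_warning(ind <- call_sample(7), "indeterminate")
  expect_true(is.na(ind))
})

test_that("fractional abundance behaves as a percentage split", {
  expect_equal(fractional_abundance(30, 70), 30)
  expect_equal(fractional_abundance(5, 0), 100)
  expect_equal(fractional_abundance(4, 4), 50)
  expect_error(fractional_abundance(0, 0), "undefined")
  for (i in 1:20) {
    m <- runif(1, 0.1, 100); u <- runif(1, 0.1, 100)
    expect_equal(fractional_abundance(m, u) + fractional_abundance(u, m), 100)
  }
})

test_that("spike recovery reports percent with QC flags", {
  expect_equal(spike_recovery(100, 100)$recovery_pct, 100)
  r0 <- spike_recovery(0, 100)
  expect_equal(r0$recovery_pct, 0)
  expect_false(r0$qc_pass)
  expect_equal(spike_recovery(80, 100)$recovery_pct, 80)
  expect_false(spike_recovery(200, 100)$qc_pass)
  expect_error(spike_recovery(10, 0), "> 0")
})

test_that("simulate-then-quantify recovers the true occupancy", {
  set.seed(25)
  n <- 20000
  lambda <- 0.5
  rel_err <- replicate(60, {
    w <- simulate_well(round(lambda * n), 1000, ddpcr_params())
    q <- quantify_well(w, volume_model())
    (q$lambda_m - lambda) / lambda
  })
  expect_lt(abs(mean(rel_err)), 0.05)
  expect_lt(max(abs(rel_err)), 0.10)
})

test_that("replicate aggregation averages wells and applies the call rule", {
  set.seed(26)
  coh <- generate_cohort(sim_config(group_sizes = c(cs_PCa = 2L), seed = 8))
  p <- ddpcr_params(preamp_gain_m = 8, preamp_gain_u = 2)
  wells <- unlist(lapply(seq_len(nrow(coh)), function(i)
    simulate_patient_wells(coh[i, ], "MIR129_2", p,
                           recovery_fraction = 1, bisulphite_survival = 1,
                           ge_per_ng = 50)),
    recursive = FALSE)
  vm <- volume_model(preamp_gain = c(p$preamp_gain_m, p$preamp_gain_u))
  quant <- quantify_samples(wells, vm, sample_sheet = coh)
  expect_identical(nrow(quant), 2L)
  expect_identical(quant$n_replicates, c(2L, 2L))
  expect_true(all(!is.na(quant$positive_call)))
  # with lossless processing the recovered copies/mL tracks the truth
  truth <- coh$MIR129_2[match(quant$sample_id, coh$sample_id)]
  big <- truth > 50
  if (any(big))
    expect_lt(max(abs(quant$copies_per_ml_m[big] - truth[big]) / truth[big]),
              0.35)
})
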