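test_that("QfPSA is the free-to-total percentage", {
  expect_equal(qfpsa(1, 4), 25)
  expect_equal(qfpsa(3.2, 3.2), 100)
  expect_equal(qfpsa(0, 5), 0)
  expect_error(qfpsa(1, 0), "> 0")
})

# a hand-built model for flag/score unit tests
fixed_model <- function(theta = c(RASSF1A = 100, age = 65, QfPSA = 20),
                        tau = 2L) {
  structure(list(variant = "PRISK2",
                 components = names(theta),
                 direction = ifelse(names(theta) == "QfPSA",
                                    "below", "above"),
                 theta = theta, tau = tau,
                 sensitivity_target = "cs_PCa",
                 achieved = list(sen_pct = 100, spe_pct = NA,
                                 n_target = 0, n_bph = 0),
                 search = "fixed", call = NULL),
            class = "risk_model")
}

test_that("component flags follow the per-component risk direction", {
  m <- fixed_model()
  safe <- data.frame(RASSF1A = 0, age = 30, QfPSA = 80)
  expect_equal(unname(component_flags(safe, m)[1, ]),
               c(FALSE, FALSE, FALSE))
  risky <- data.frame(RASSF1A = 500, age = 80, QfPSA = 10)
  expect_equal(unname(component_flags(risky, m)[1, ]), c(TRUE, TRUE, TRUE))
  # low QfPSA is the risk side
  expect_true(component_flags(data.frame(RASSF1A = 0, age = 0, QfPSA = 10),
                              m)[1, "QfPSA"])
  # strict exceedance: a value exactly at the cutoff scores no point
  at_cut <- data.frame(RASSF1A = 100, age = 65, QfPSA = 20)
  expect_equal(unname(component_flags(at_cut, m)[1, ]),
               c(FALSE, FALSE, FALSE))
  expect_error(component_flags(data.frame(RASSF1A = 1), m), "age")
})

test_that("the score counts flags and calls at the threshold", {
  m <- fixed_model(tau = 2L)
  df <- data.frame(RASSF1A = c(0, 500, 500), age = c(30, 80, 30),
                   QfPSA = c(80, 50, 10))
  rs <- risk_score(df, m)
  expect_equal(rs$score, c(0L, 2L, 2L))
  expect_equal(rs$call, c(FALSE, TRUE, TRUE))
  # two flags under a threshold of three stay negative
  m3 <- fixed_model(tau = 3L)
  expect_false(risk_score(df[2, ], m3)$call)
})

test_that("the score is monotone in every risk direction", {
  set.seed(51)
  m <- fixed_model()
  for (i in 1:50) {
    rec <- data.frame(RASSF1A = runif(1, 0, 300), age = runif(1, 20, 90),
                      QfPSA = runif(1, 1, 60))
    s0 <- risk_score(rec, m)$score
    bumped <- rec
    bumped$RASSF1A <- rec$RASSF1A + runif(1, 0, 200)
    bumped$age <- rec$age + runif(1, 0, 15)
    bumped$QfPSA <- rec$QfPSA - runif(1, 0, 10)  # lower QfPSA = riskier
    expect_gte(risk_score(bumped, m)$score, s0)
  }
})

test_that("calibration on a separable toy cohort is perfect and matches the oracle", {
  coh <- make_tiny_cohort(
    group = c("BPH", "BPH", "BPH", "cs_PCa", "cs_PCa", "cs_PCa"),
    RASSF1A = c(0, 0, 0, 150, 200, 400),
    cfDNA_ng_ml = c(10, 30, 20, 15, 25, 35),
    age = c(70, 60, 65, 68, 72, 63))
  fit <- risk_model(coh, "piRISK2", components = c("RASSF1A", "cfDNA_ng_ml",
                                                   "age"),
                    tau = 1L, sensitivity_target = "cs_PCa")
  expect_equal(fit$achieved$sen_pct, 100)
  expect_equal(fit$achieved$spe_pct, 100)
  expect_identical(fit$search, "exhaustive")
  oracle <- oracle_best_spe(coh, c("RASSF1A", "cfDNA_ng_ml", "age"),
                            c("above", "above", "above"), 1L, "cs_PCa")
  expect_equal(fit$achieved$spe_pct, oracle)
  # the decisive marker separates at a cutoff between 0 and 150
  expect_gt(fit$theta[["RASSF1A"]], 0)
  expect_lt(fit$theta[["RASSF1A"]], 150)
})

test_that("an indistinguishable case forces SPE below 100 but never breaks SEN", {
  coh <- make_tiny_cohort(
    group = c("BPH", "BPH", "cs_PCa", "cs_PCa"),
    RASSF1A = c(50, 200, 200, 400),   # one BPH identical to one cs_PCa
    cfDNA_ng_ml = c(20, 40, 40, 60),
    age = c(65, 70, 70, 75))
  fit <- risk_model(coh, "piRISK2", components = c("RASSF1A", "cfDNA_ng_ml",
                                                   "age"),
                    tau = 2L, sensitivity_target = "cs_PCa")
  expect_equal(fit$achieved$sen_pct, 100)
  expect_lt(fit$achieved$spe_pct, 100)
})

test_that("exhaustive search agrees with the brute-force oracle on random small cohorts", {
  set.seed(52)
  comps <- c("RASSF1A", "cfDNA_ng_ml", "age")
  for (i in 1:10) {
    n <- sample(5:8, 1)
    grp <- c("BPH", "cs_PCa",
             sample(c("BPH", "cs_PCa"), n - 2, replace = TRUE))
    coh <- make_tiny_cohort(group = grp,
                            RASSF1A = round(runif(n, 0, 300)),
                            cfDNA_ng_ml = round(runif(n, 5, 80)),
                            age = round(runif(n, 50, 85)))
    fit <- risk_model(coh, "piRISK2", components = comps, tau = 2L,
                      sensitivity_target = "cs_PCa")
    expect_identical(fit$search, "exhaustive")
    oracle <- oracle_best_spe(coh, comps, rep("above", 3), 2L, "cs_PCa")
    expect_equal(fit$achieved$spe_pct, oracle)
  }
})

test_that("calibration is invariant to patient order", {
  coh <- generate_cohort(sim_config(
    group_sizes = c(BPH = 20L, indolent_PCa = 4L, cs_PCa = 12L), seed = 53))
  fit1 <- risk_model(coh, "PRISK2")
  set.seed(99)
  fit2 <- risk_model(coh[sample(nrow(coh)), ], "PRISK2")
  expect_equal(fit1$theta, fit2$theta)
  expect_equal(fit1$achieved$spe_pct, fit2$achieved$spe_pct)
})

test_that("variant rules and infeasibility are enforced", {
  coh <- make_tiny_cohort(group = c("BPH", "cs_PCa", "indolent_PCa"),
                          RASSF1A = c(1, 2, 3), MIR129_2 = c(1, 2, 3),
                          NRIP3 = c(1, 2, 3), SOX8 = c(1, 2, 3),
                          cfDNA_ng_ml = c(1, 2, 3), age = c(60, 70, 65),
                          QfPSA = c(30, 10, 20))
  expect_error(risk_model(coh, "piRISK1",
                          components = c("RASSF1A", "QfPSA")), "exclude")
  expect_error(risk_model(coh, "PRISK1", components = c("RASSF1A", "age")),
               "include QfPSA")
  # tau above the component count can never reach 100% sensitivity
  expect_error(risk_model(coh, "piRISK2", components = c("RASSF1A", "age"),
                          tau = 3L), "100% sensitivity")
  # missing target class
  expect_error(risk_model(coh[coh$group != "cs_PCa", ], "piRISK2"),
               "target class")
})

test_that("fitted models survive a JSON round trip and methods work", {
  coh <- generate_cohort(sim_config(
    group_sizes = c(BPH = 15L, indolent_PCa = 3L, cs_PCa = 10L), seed = 54))
  fit <- risk_model(coh, "PRISK1")
  expect_output(print(fit), "PRISK1")
  expect_output(print(summary(fit)), "cutoff")
  expect_named(coef(fit), fit$components)
  pr <- predict(fit, coh)
  expect_identical(nrow(pr), nrow(coh))
  expect_true(all(pr$call[coh$group %in% c("cs_PCa", "indolent_PCa")]))
  f <- tempfile(fileext = ".json")
  write_model_json(fit, f)
  back <- read_model_json(f)
  expect_equal(coef(back), coef(fit))
  expect_identical(predict(back, coh, type = "score"),
                   predict(fit, coh, type = "score"))
  # plot method returns the ROC invisibly on a null device
  grDevices::pdf(NULL)
  r <- plot(fit, coh)
  grDevices::dev.off()
  expect_true(r$auc >= 0 && r$auc <= 1)
})

test_that("simulate() draws fresh cohorts and scores them", {
  coh <- generate_cohort(sim_config(
    group_sizes = c(BPH = 10L, indolent_PCa = 2L, cs_PCa = 8L), seed = 55))
  fit <- risk_model(coh, "piRISK1")
  sims <- simulate(fit, nsim = 2, seed = 7,
                   config = sim_config(group_sizes = c(BPH = 5L,
                                                       cs_PCa = 5L)))
  expect_length(sims, 2L)
  expect_identical(nrow(sims[[1]]), 10L)
  expect_true(all(c("score", "call", "group") %in% names(sims[[1]])))
})
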