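make_bm <- function(beta, tissue) beta_matrix(beta, tissue)

test_that("probe masking is an order-preserving set difference", {
  set.seed(41)
  beta <- matrix(runif(10 * 6), nrow = 10,
                 dimnames = list(paste0("cg", 1:10), NULL))
  bm <- make_bm(beta, rep(c("PCa_tissue", "prostate_normal"), each = 3))
  expect_identical(rownames(apply_probe_mask(bm, character())$beta),
                   paste0("cg", 1:10))
  expect_warning(empty <- apply_probe_mask(bm, paste0("cg", 1:10)),
                 "every probe")
  expect_identical(nrow(empty$beta), 0L)
  masked <- apply_probe_mask(bm, c("cg2", "cg5", "cg9"))
  expect_identical(rownames(masked$beta),
                   setdiff(paste0("cg", 1:10), c("cg2", "cg5", "cg9")))
})

test_that("contrasts recover a large planted methylation difference", {
  set.seed(42)
  beta <- rbind(strong = c(rep(0.8, 20), rep(0.05, 20)) +
                  runif(40, 0, 1e-4),
                flat = rep(0.3, 40) + runif(40, 0, 1e-4))
  bm <- make_bm(beta, rep(c("PCa_tissue", "prostate_normal"), each = 20))
  ct <- probe_contrasts(bm, normal_labels = "prostate_normal")
  strong <- ct[ct$probe_id == "strong", ]
  expect_equal(strong$delta_beta, 0.75, tolerance = 1e-3)
  expect_lt(strong$p_value, 1e-6)
  # permutation oracle: a full label swap never reaches the observed gap
  obs <- abs(mean(beta["strong", 1:20]) - mean(beta["strong", 21:40]))
  perm <- replicate(500, {
    idx <- sample(40, 20)
    abs(mean(beta["strong", idx]) - mean(beta["strong", -idx]))
  })
  expect_lt(mean(perm >= obs), 0.01)
  flat <- ct[ct$probe_id == "flat", ]
  expect_lt(abs(flat$delta_beta), 0.01)
  expect_gt(flat$p_value, 0.05)
})

test_that("null probes give roughly uniform p-values", {
  set.seed(43)
  beta <- matrix(rbeta(200 * 30, 2, 8), nrow = 200)
  bm <- make_bm(beta, rep(c("PCa_tissue", "prostate_normal"), each = 15))
  ct <- probe_contrasts(bm, normal_labels = "prostate_normal")
  frac <- mean(ct$p_value < 0.05)
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.15)
})

test_that("constant probes take the conventional delta 0, p 1", {
  beta <- matrix(0.4, nrow = 2, ncol = 10,
                 dimnames = list(c("c1", "c2"), NULL))
  bm <- make_bm(beta, rep(c("PCa_tissue", "prostate_normal"), each = 5))
  ct <- probe_contrasts(bm, normal_labels = "prostate_normal")
  expect_equal(ct$delta_beta, c(0, 0))
  expect_equal(ct$p_value, c(1, 1))
})

test_that("missing labels and small groups are rejected", {
  beta <- matrix(runif(20), nrow = 4)
  bm <- make_bm(beta, rep(c("PCa_tissue", "liver"), c(4, 1)))
  expect_error(probe_contrasts(bm, normal_labels = "kidney"), "kidney")
  expect_error(probe_contrasts(bm, normal_labels = "liver"), ">= 2")
})

test_that("selection keeps the perfect probe, applies exceptions, ranks by margin", {
  set.seed(44)
  tissue <- rep(c("PCa_tissue", "prostate_normal", "liver", "WBC",
                  "serum_ctrl"), each = 10)
  mk_probe <- function(pca, liver, bg = 0.03) {
    c(rnorm(10, pca, 0.02), rnorm(10, 0.05, 0.02), rnorm(10, liver, 0.02),
      rnorm(10, bg, 0.01), rnorm(10, bg, 0.01))
  }
  beta <- rbind(perfect = mk_probe(0.80, 0.05),
                liver_high = mk_probe(0.60, 0.45),
                weak = mk_probe(0.40, 0.05),
                background = mk_probe(0.80, 0.05, bg = 0.30))
  beta[beta < 0] <- 0; beta[beta > 1] <- 1
  bm <- make_bm(beta, tissue)
  ct <- probe_contrasts(bm, normal_labels = c("prostate_normal", "liver"))
  sel <- select_markers(ct, selection_criteria(min_delta_beta = 0.2))
  expect_identical(sel$probe_id[1], "perfect")
  expect_false("liver_high" %in% sel$probe_id)  # liver contrast fails
  expect_false("background" %in% sel$probe_id)  # WBC/serum too high
  # the liver exception readmits the probe without changing its other
  # contrasts
  sel_ex <- select_markers(ct, selection_criteria(
    min_delta_beta = 0.2,
    allowed_exceptions = data.frame(probe_id = "liver_high",
                                    tissue = "liver")))
  expect_true("liver_high" %in% sel_ex$probe_id)
  # vacuous criteria admit everything
  sel_all <- select_markers(ct, selection_criteria(
    alpha = 0.999, min_delta_beta = -1, max_background_beta = 1))
  expect_setequal(sel_all$probe_id, rownames(beta))
})

test_that("selection is invariant to sample-column permutation", {
  sim <- simulate_beta_matrix(n_probes = 20, planted = 3, seed = 45)
  bm <- sim$bm
  perm <- sample(ncol(bm$beta))
  bm2 <- beta_matrix(bm$beta[, perm], bm$tissue[perm])
  crit <- selection_criteria(min_delta_beta = 0.2)
  s1 <- select_markers(probe_contrasts(bm), crit)
  s2 <- select_markers(probe_contrasts(bm2), crit)
  expect_identical(s1$probe_id, s2$probe_id)
})

test_that("planted differential probes are recovered exactly (brute-force oracle)", {
  for (seed in 1:3) {
    sim <- simulate_beta_matrix(n_probes = 50, planted = 5, seed = seed)
    ct <- probe_contrasts(sim$bm)
    crit <- selection_criteria(min_delta_beta = 0.2)
    sel <- select_markers(ct, crit)
    # recall of planted probes is 1
    expect_true(all(sim$planted %in% sel$probe_id))
    # brute-force filter oracle: explicit loop over probes x contrasts
    oracle_keep <- character()
    for (p in unique(ct$probe_id)) {
      rows <- ct[ct$probe_id == p, ]
      pass <- all(rows$p_value < 0.001 & rows$delta_beta > 0.2)
      if (pass && rows$background_beta_WBC[1] <= 0.10 &&
          rows$background_beta_serum_ctrl[1] <= 0.10)
        oracle_keep <- c(oracle_keep, p)
    }
    expect_setequal(sel$probe_id, oracle_keep)
  }
})

test_that("beta TSV round trip preserves values and labels", {
  sim <- simulate_beta_matrix(n_probes = 8, planted = 2, seed = 46)
  fb <- tempfile(fileext = ".tsv"); fl <- tempfile(fileext = ".csv")
  write_beta_tsv(sim$bm, fb, fl)
  back <- read_beta_tsv(fb, fl)
  expect_equal(back$beta, sim$bm$beta, tolerance = 1e-6)
  expect_identical(back$tissue, sim$bm$tissue)
})
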