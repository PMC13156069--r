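test_that("daily-dose derivation filters invalid rows and takes the median", {
  rx <- data.frame(
    subject = c("s1", "s2", "s2", "s3", "s4"),
    strength_mg = c(500, 500, 1000, 850, NA),
    quantity = c(56, 56, 56, 28, 10),
    duration_days = c(28, 28, 28, NA, 7))
  dd <- derive_daily_dose(rx)
  expect_equal(dd$daily_dose[dd$subject == "s1"], 1000)  # 500*56/28
  expect_equal(dd$daily_dose[dd$subject == "s2"], 1500)  # median(1000, 2000)
  expect_false("s3" %in% dd$subject)                     # no valid rows
  expect_equal(attr(dd, "n_dropped_rows"), 2L)
  expect_true(all(c("s3", "s4") %in% attr(dd, "excluded_subjects")))
  expect_equal(derive_daily_dose(rx, summary = "mean")$daily_dose[2], 1500)
})

test_that("MAF filtering is strictly below threshold", {
  v <- data.frame(id = c("a", "b", "c", "d"),
                  maf = c(0.049, 0.05, 0.002, NA))
  expect_warning(kept <- maf_filter(v), "without MAF")
  expect_equal(kept$id, c("a", "c"))
  expect_equal(nrow(maf_filter(v[0, ])), 0L)
})

test_that("burden scores are weighted dosage sums, linear and additive", {
  G <- matrix(c(1, 0, 2, 0, 1, 1, 0, 0, 2, 1, 0, 1), nrow = 4,
              dimnames = list(NULL, c("v1", "v2", "v3")))
  w <- c(v1 = -0.5, v2 = 1, v3 = 0.25)
  sc <- burden_score(G, w)
  brute <- sapply(1:4, function(s) sum(G[s, ] * w[colnames(G)]))
  expect_equal(sc, brute)
  expect_equal(burden_score(matrix(1, 1, 1, dimnames = list(NULL, "v1")),
                            c(v1 = -0.5)), -0.5)
  expect_equal(burden_score(G * 0, w), rep(0, 4))  # no carried variants
  # linearity in the weights, additivity over disjoint variant sets
  expect_equal(burden_score(G, 3 * w), 3 * sc)
  expect_equal(burden_score(G[, 1:2], w[1:2]) + burden_score(G[, 3, drop = FALSE], w[3]),
               sc)
  expect_error(burden_score(G, w[1:2]), "v3")
})

test_that("dose regression reproduces closed-form least squares", {
  set.seed(21)
  n <- 200
  burden <- rnorm(n)
  dose <- 3 * burden + 1000
  fit0 <- suppressWarnings(fit_dose_model(burden, NULL, dose)) # exact fit
  expect_equal(fit0$beta, 3, tolerance = 1e-10)
  expect_lt(fit0$p, 1e-12)
  expect_true(fit0$ci95[1] <= fit0$beta && fit0$beta <= fit0$ci95[2])

  covs <- data.frame(age_at_prescription = rnorm(n, 60, 10),
                     sex = sample(c("F", "M"), n, TRUE),
                     bmi = rnorm(n, 28, 4))
  dose2 <- 1500 + 25 * burden + 2 * covs$age_at_prescription +
    40 * (covs$sex == "M") + rnorm(n, 0, 100)
  fit <- fit_dose_model(burden, covs, dose2)
  # textbook closed form on the same design
  X <- cbind(1, burden, covs$age_at_prescription, covs$sex == "M", covs$bmi)
  bhat <- solve(t(X) %*% X, t(X) %*% dose2)
  expect_equal(fit$beta, bhat[2], tolerance = 1e-8)

  # rank-deficient design errors with the aliased column
  covs$dup <- covs$bmi
  expect_error(fit_dose_model(burden, covs, dose2), "aliased.*dup|dup")
})

test_that("permuted-burden regression p-values are uniform (type-I control)", {
  set.seed(33)
  n <- 500
  dose <- rnorm(n, 1500, 300)
  ps <- replicate(200, fit_dose_model(rnorm(n), NULL, dose)$p)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.035)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("planted cohort effects are recovered within the 95% CI", {
  hits <- 0L
  for (s in 1:20) {
    coh <- simulate_cohort(n_subjects = 5000, seed = s)
    b <- burden_score(coh$genotypes, coh$weights)
    fit <- fit_dose_model(
      b, coh$subjects[, c("age_at_prescription", "sex", "ethnic_group", "bmi")],
      coh$subjects$daily_dose)
    if (fit$ci95[1] <= coh$beta && coh$beta <= fit$ci95[2]) hits <- hits + 1L
  }
  expect_gte(hits, 17L)  # ~95% nominal coverage over 20 cohorts
})

test_that("damaging classification applies direction-aware thresholds", {
  thr <- default_damaging_thresholds()
  expect_true(all(c("predictor", "cutoff", "direction") %in% names(thr)))
  scores <- data.frame(
    variant = c("p.A2V", "p.R3C", "p.G4S"),
    ssep = c(-0.5, -0.1, 0.2),       # lower is damaging, cutoff -0.301
    SIFT = c(0.01, 0.2, 0.04),       # lower is damaging, cutoff 0.05
    CADD = c(25, 10, 30))            # higher is damaging, cutoff 20
  out <- classify_damaging(scores)
  expect_equal(out$ssep$variants, "p.A2V")
  expect_equal(out$SIFT$variants, c("p.A2V", "p.G4S"))
  expect_equal(out$CADD$n, 2L)
  scores$mystery <- c(1, 2, 3)
  expect_warning(classify_damaging(scores), "mystery")
})

test_that("gene-level burden test detects planted effects and respects nulls", {
  coh <- simulate_cohort(n_subjects = 2000, beta = 120, seed = 77,
                         weights = setNames(rep(-1, 11), sprintf("rv%02d", 1:11)))
  covs <- coh$subjects[, c("age_at_prescription", "sex", "ethnic_group", "bmi")]
  bt <- burden_test(coh$genotypes, coh$subjects$daily_dose, covs)
  expect_lt(bt$p, 0.01)

  # zero carriers: p = 1 with warning
  expect_warning(b0 <- burden_test(coh$genotypes * 0,
                                   coh$subjects$daily_dose, covs),
                 "zero carriers")
  expect_equal(b0$p, 1)

  # single carrier, no effect: p is an unremarkable draw
  G1 <- matrix(0, 2000, 1, dimnames = list(NULL, "v1")); G1[1, 1] <- 1
  p1 <- burden_test(G1, rnorm(2000), NULL)$p
  expect_true(p1 > 1e-4 && p1 <= 1)
})

test_that("SKAT-style test gains power over burden for bidirectional effects", {
  set.seed(99)
  n <- 2000
  mafs <- setNames(rep(0.02, 10), paste0("v", 1:10))
  G <- sapply(mafs, function(f) rbinom(n, 2, f))
  eff <- rep(c(200, -200), each = 5)   # half up, half down: burden cancels
  phen <- drop(G %*% eff) + rnorm(n, 0, 300)
  sk <- skat_style_test(G, phen, n_perm = 500, seed = 5)
  expect_lt(sk$p_variance, sk$p_burden)
  expect_lt(sk$p, 0.05)

  # all-zero weights: no information
  expect_equal(skat_style_test(G, phen, weights = rep(0, 10))$p, 1)
  expect_warning(skat_style_test(G, phen, n_perm = 50, seed = 1), "resolution")
})

test_that("both gene-level tests hold their size under permuted phenotypes", {
  coh <- simulate_cohort(n_subjects = 500, seed = 123)
  covs <- coh$subjects[, c("age_at_prescription", "sex", "ethnic_group", "bmi")]
  n_null <- 300
  p_b <- p_s <- numeric(n_null)
  for (i in seq_len(n_null)) {
    ph <- with_seed(child_seed(555, i), sample(coh$subjects$daily_dose))
    p_b[i] <- burden_test(coh$genotypes, ph, covs)$p
    p_s[i] <- skat_style_test(coh$genotypes, ph, covs, n_perm = 300,
                              seed = child_seed(556, i))$p
  }
  # nominal 0.05 within ~3 Monte-Carlo SEs
  expect_lt(abs(mean(p_b < 0.05) - 0.05), 0.04)
  expect_lt(abs(mean(p_s < 0.05) - 0.05), 0.04)
})

test_that("matched substrate-specific weights beat averaged weights on dose", {
  wins <- 0L
  for (s in 1:5) {
    sim <- simulate_activity(seed = s)
    ve <- sim$truth$variant_effects
    w_spec <- ve + sim$truth$interaction[, 1]
    w_mean <- ve + rowMeans(sim$truth$interaction)
    vn <- names(ve)[1:11]
    coh <- simulate_cohort(
      n_subjects = 5000,
      mafs = setNames(seq(0.002, 0.04, length.out = 11), vn),
      weights = w_spec[vn], seed = 100 + s)
    covs <- coh$subjects[, c("age_at_prescription", "sex", "ethnic_group", "bmi")]
    f_m <- fit_dose_model(burden_score(coh$genotypes, w_spec[vn]), covs,
                          coh$subjects$daily_dose, "substrate_specific")
    f_a <- fit_dose_model(burden_score(coh$genotypes, w_mean[vn]), covs,
                          coh$subjects$daily_dose, "mean_activity")
    if (f_m$p < f_a$p) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})
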