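test_that("spearman matches rank arithmetic and is monotone-invariant", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  s <- spearman(x, y)
  # 1 - 6*sum(d^2)/(n(n^2-1)) with d = (-1,1,-1,1,0)
  expect_equal(s$rho, 1 - 6 * 4 / (5 * 24))
  expect_equal(s$rho, 0.8)
  expect_equal(spearman(x, exp(x))$rho, 1)
  expect_equal(spearman(x, -x)$rho, -1)
  # invariance under strictly monotone transforms of either argument
  set.seed(2)
  a <- rnorm(12); b <- rnorm(12)
  expect_equal(spearman(a, b)$rho, spearman(exp(a), b)$rho)
  expect_equal(spearman(a, b)$rho, spearman(a, b^3 + 2 * b)$rho)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
})

test_that("spearman exact p equals the brute-force permutation oracle", {
  set.seed(31)
  for (n in c(4, 5, 6, 7)) {
    for (rep in 1:3) {
      x <- rnorm(n); y <- rnorm(n)
      s <- spearman(x, y)
      expect_equal(s$p, oracle_spearman_p(x, y), tolerance = 1e-12)
    }
  }
  # one tied case
  x <- c(1, 2, 2, 3, 4); y <- c(2, 1, 3, 3, 5)
  expect_equal(spearman(x, y)$p, oracle_spearman_p(x, y))
})

test_that("rmse and rank error behave under shifts and match brute ranking", {
  p <- c(0.1, 0.5, -0.2, 0.9); o <- c(0.1, 0.5, -0.2, 0.9)
  expect_equal(rmse(p, o), 0)
  expect_equal(rank_error(p, o), rep(0, 4))
  expect_equal(rmse(p + 1, o), 1)
  expect_equal(rank_error(p + 1, o), rep(0, 4))  # rank-invariant to shifts
  p2 <- c(3, 1, 2, 4); o2 <- c(10, 20, 30, 40)
  expect_equal(rank_error(p2, o2), abs(rank(p2) - rank(o2)) / 4)
})

test_that("activity binning uses the documented strict boundaries", {
  expect_equal(as.character(bin_activity(c(49.9, 50, 200, 201), "three_bin")),
               c("decreased", "neutral", "neutral", "increased"))
  incl <- bin_activity(c(50, 200), "three_bin", inclusive = TRUE)
  expect_equal(as.character(incl), c("decreased", "increased"))
  # threshold schemes: positive class direction
  expect_true(bin_activity(30, "threshold_50"))     # reduced function
  expect_false(bin_activity(60, "threshold_50"))
  expect_true(bin_activity(160, "threshold_150"))   # gain of function
  expect_false(bin_activity(140, "threshold_150"))
})

test_that("Jonckheere test matches the exhaustive assignment oracle", {
  j <- jonckheere_test(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(j$JT, 12)          # maximal: all 12 cross-pairs ascending
  expect_equal(j$p, 1 / 90)       # 2!2!2!/6! x (orderings achieving max) = 8/720
  # identical constants -> no trend
  expect_equal(jonckheere_test(list(c(5, 5), c(5, 5)))$p, 1)
  # reversed data -> one-sided p near 1
  expect_gt(jonckheere_test(list(c(5, 6), c(3, 4), c(1, 2)))$p, 0.98)
  expect_error(jonckheere_test(list(1:3)), "2 non-empty")

  set.seed(13)
  for (rep in 1:4) {
    sizes <- sample(2:3, 3, replace = TRUE)
    groups <- split(rnorm(sum(sizes)), rep(seq_along(sizes), sizes))
    expect_equal(jonckheere_test(groups)$p, oracle_jt_exact_p(groups),
                 tolerance = 1e-12)
  }
})

test_that("Jonckheere normal approximation tracks the exact tail within 0.02", {
  set.seed(17)
  for (rep in 1:6) {
    sizes <- sample(3:4, 3, replace = TRUE)
    while (sum(sizes) > 10) sizes <- sample(3:4, 3, replace = TRUE)
    groups <- split(rnorm(sum(sizes)), rep(seq_along(sizes), sizes))
    pe <- jonckheere_test(groups, method = "exact")$p
    pn <- jonckheere_test(groups, method = "normal")$p
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("Kruskal-Wallis matches kruskal.test and the permutation oracle", {
  g <- list(c(1, 2, 3), c(4, 5, 6))
  k <- kruskal_wallis(g)
  expect_equal(k$H, unname(kruskal.test(unlist(g),
                                        factor(rep(1:2, each = 3)))$statistic))
  expect_equal(k$p, oracle_kw_exact_p(g), tolerance = 1e-12)
  # identical groups -> H = 0, all-identical values -> p = 1
  expect_equal(kruskal_wallis(list(c(1, 1), c(1, 1)))$p, 1)
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$H, 0)
  expect_error(kruskal_wallis(list(1:3, numeric(0), 1:2)), "non-empty")

  set.seed(23)
  for (rep in 1:4) {
    sizes <- sample(2:3, sample(2:3, 1), replace = TRUE)
    groups <- split(rnorm(sum(sizes)), rep(seq_along(sizes), sizes))
    expect_equal(kruskal_wallis(groups)$p, oracle_kw_exact_p(groups),
                 tolerance = 1e-12)
  }
})

test_that("ROC-AUC equals exhaustive pair counting and pROC", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(5, 6, 1, 2), c(1, 1, 0, 0)), 1)   # separated
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(6:20, 1)
    sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # with ties
    lab <- rbinom(n, 1, 0.5)
    if (sum(lab) == 0 || sum(lab) == n) next
    a <- roc_auc(sc, lab)
    expect_equal(a, oracle_auc(sc, lab))
    expect_equal(a, as.numeric(suppressMessages(
      pROC::auc(pROC::roc(lab, sc, quiet = TRUE, direction = "<")))))
  }
  # complement property for tie-free scores
  sc <- rnorm(15); lab <- rbinom(15, 1, 0.4); lab[1] <- 1; lab[2] <- 0
  expect_equal(roc_auc(sc, lab) + roc_auc(-sc, lab), 1)
  # null behaviour: labels independent of scores
  set.seed(55)
  sc <- rnorm(4000); lab <- rbinom(4000, 1, 0.5)
  expect_lt(abs(roc_auc(sc, lab) - 0.5), 0.03)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "one class")
})

test_that("Benjamini-Hochberg adjustment matches the step-up oracle", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), method = "BH"),
               rep(0.03, 3))
  set.seed(3)
  for (rep in 1:5) {
    p <- runif(sample(3:12, 1))
    q <- p.adjust(p, method = "BH")
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p - 1e-15))
  }
})

test_that("per-substrate benchmarking filters, ranks methods and tests omnibus", {
  sim <- simulate_activity(n_variants = 25, n_substrates = 6, seed = 77)
  tab <- sim$table
  truth_scores <- data.frame(gene = tab$gene, variant = tab$variant,
                             substrate = tab$substrate,
                             score = sim$truth$pairs$log_activity)
  set.seed(1)
  noise_scores <- data.frame(gene = tab$gene, variant = tab$variant,
                             score = rnorm(nrow(tab)))[!duplicated(tab$variant), ]
  bench <- per_substrate_benchmark(
    list(generator = truth_scores, noise = noise_scores), tab,
    min_variants = 10)
  expect_equal(names(bench$medians)[1], "generator")
  expect_lt(bench$kruskal$p, 0.05)

  # identical methods -> KW p ~ 1
  same <- per_substrate_benchmark(
    list(a = truth_scores, b = truth_scores), tab, min_variants = 10)
  expect_gt(same$kruskal$p, 0.9)

  # a substrate below the variant filter is excluded
  small <- tab[tab$substrate != unique(tab$substrate)[1] |
                 tab$variant %in% unique(tab$variant)[1:9], ]
  b2 <- per_substrate_benchmark(list(a = truth_scores, b = noise_scores),
                                small, min_variants = 10)
  expect_false(unique(tab$substrate)[1] %in% b2$per_substrate$substrate)

  expect_error(per_substrate_benchmark(
    list(a = truth_scores, b = noise_scores), tab[1:5, ], min_variants = 10),
    "filter")
})

test_that("per-substrate AUC summary averages with SEM and guards degeneracy", {
  sim <- simulate_activity(n_variants = 30, n_substrates = 5, seed = 78)
  tab <- sim$table
  gen <- data.frame(gene = tab$gene, variant = tab$variant,
                    substrate = tab$substrate,
                    score = sim$truth$pairs$log_activity)
  set.seed(2)
  noise <- data.frame(gene = tab$gene, variant = tab$variant,
                      score = rnorm(nrow(tab)))[!duplicated(tab$variant), ]
  out <- per_substrate_auc_summary(list(generator = gen, noise = noise), tab,
                                   scheme = "threshold_50", min_variants = 10)
  s <- out$summary
  expect_gt(s$mean_auc[s$method == "generator"],
            s$mean_auc[s$method == "noise"])

  # single-substrate input: mean is that AUC, SEM 0
  one_sub <- tab[tab$substrate == tab$substrate[1], ]
  o1 <- per_substrate_auc_summary(list(generator = gen), one_sub,
                                  min_variants = 5)
  expect_equal(o1$summary$sem, 0)
  expect_equal(o1$summary$mean_auc, o1$per_substrate$auc)

  # constant-score method excluded with a warning (one per substrate)
  const <- noise; const$score <- 1
  ws <- capture_warnings(
    o2 <- per_substrate_auc_summary(list(generator = gen, flat = const), tab,
                                    min_variants = 10))
  expect_true(length(ws) > 0 && all(grepl("constant", ws)))
  expect_false("flat" %in% o2$summary$method)
})

test_that("the evaluation report combines rho, RMSE and the bin trend", {
  sim <- simulate_activity(n_variants = 30, n_substrates = 6, seed = 12)
  pred <- sim$truth$pairs$log_activity
  rep <- evaluate_predictions(pred, sim$table$uptake_pct_wt,
                              substrate = sim$table$substrate)
  expect_gt(rep$spearman_rho, 0.9)   # near-oracle predictions
  expect_lt(rep$jonckheere$p, 1e-4)  # strong increasing trend over bins
  expect_true(all(abs(rep$per_substrate_rho) <= 1, na.rm = TRUE))
})
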