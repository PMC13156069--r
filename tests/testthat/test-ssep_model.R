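test_that("target transform anchors wildtype at 0 and clips at the floor", {
  expect_equal(target_transform(100), 0)
  expect_equal(target_transform(1000), 1)     # log10 of ratio 10
  expect_equal(target_transform(0), -3)       # clip at ratio 1e-3
  expect_equal(target_transform(50), log10(0.5))
  expect_equal(inverse_transform(target_transform(c(25, 100, 340))),
               c(25, 100, 340))
  # monotone
  u <- sort(runif(20, 0, 500))
  expect_true(!is.unsorted(target_transform(u)))
})

test_that("model construction validates blocks and reports parameter count", {
  cfg <- model_config(encoder_width = 4, trunk_widths = c(8), seed = 2)
  m <- build_model(cfg, "SNV", c(embedding = 3, ligand = 2))
  # params: enc 3*4+4 + 2*4+4 -> 28; trunk 8*8+8 -> 72; out 8+1 -> 9
  expect_equal(m$n_params, (3 * 4 + 4) + (2 * 4 + 4) + (8 * 8 + 8) + (8 + 1))
  expect_error(build_model(cfg, "SNV", c(3, 2)), "named")

  # forward pass on a bundle returns one finite scalar
  b <- feature_bundle("p.A2V", "m", list(embedding = c(1, 2, 3), ligand = c(4, 5)))
  m$scaler <- NULL
  expect_length(predict(m, list(b)), 1L)
  expect_true(is.finite(predict(m, list(b))))

  # a route rejects blocks it was not configured for
  uv <- build_model(cfg, "UV", c(embedding = 3))
  expect_error(predict(uv, list(b)), "not configured")
})

test_that("the degenerate affine model converges to ordinary least squares", {
  fx <- make_linear_bundles(n = 100, seed = 4)
  y <- fx$y + rnorm(100, 0, 0.05)
  cfg <- model_config(encoder_width = 0, trunk_widths = integer(0),
                      activation = "identity", dropout = 0,
                      learning_rate = 0.05, batch_size = 0,
                      max_epochs = 3000, patience = 3000, seed = 3)
  m <- build_model(cfg, "SNV", c(embedding = 3, ligand = 2))
  m <- pretrain(m, fx$bundles, y, split_fraction = 1)
  ols <- coef(lm(y ~ fx$X))
  expect_lt(max(abs(linear_coefficients(m) - ols)), 1e-3)
})

test_that("training is bit-reproducible under a fixed seed", {
  fx <- make_linear_bundles(n = 40, seed = 9)
  cfg <- model_config(encoder_width = 4, trunk_widths = c(8), dropout = 0.1,
                      learning_rate = 0.01, batch_size = 16, max_epochs = 30,
                      patience = 30, seed = 11)
  m1 <- pretrain(build_model(cfg, "SNV", c(embedding = 3, ligand = 2)),
                 fx$bundles, fx$y, seed = 5)
  m2 <- pretrain(build_model(cfg, "SNV", c(embedding = 3, ligand = 2)),
                 fx$bundles, fx$y, seed = 5)
  expect_identical(m1$log, m2$log)
  expect_identical(predict(m1, fx$bundles), predict(m2, fx$bundles))
})

test_that("pretraining handles constant targets and refuses tiny datasets", {
  fx <- make_linear_bundles(n = 40, seed = 2)
  cfg <- model_config(encoder_width = 0, trunk_widths = integer(0),
                      activation = "identity", dropout = 0,
                      learning_rate = 0.05, max_epochs = 500,
                      patience = 500, seed = 1)
  m <- pretrain(build_model(cfg, "SNV", c(embedding = 3, ligand = 2)),
                fx$bundles, rep(0.7, 40), split_fraction = 1)
  expect_equal(unname(predict(m, fx$bundles)), rep(0.7, 40), tolerance = 0.01)
  expect_error(pretrain(build_model(cfg, "SNV", c(embedding = 3, ligand = 2)),
                        fx$bundles[1:5], fx$y[1:5]), "at least 10")
})

test_that("fine-tuning continues optimisation; zero rate leaves weights unchanged", {
  fx <- make_linear_bundles(n = 60, seed = 6)
  cfg <- model_config(encoder_width = 4, trunk_widths = c(8), dropout = 0,
                      learning_rate = 0.01, max_epochs = 100, patience = 20,
                      seed = 7, fine_tune_learning_rate = 0)
  m <- pretrain(build_model(cfg, "SNV", c(embedding = 3, ligand = 2)),
                fx$bundles, fx$y, seed = 7)
  m0 <- fine_tune(m, fx$bundles, fx$y, seed = 8, epochs = 5)
  expect_identical(m0$params, m$params)   # lr 0 -> no movement

  # empty DMS set is a warning no-op
  expect_warning(m1 <- fine_tune(m, list(), numeric(0)), "empty DMS")
  expect_identical(m1$params, m$params)

  # fine-tuning on the pretraining data does not degrade held-out rho
  cfg2 <- model_config(encoder_width = 4, trunk_widths = c(8), dropout = 0,
                       learning_rate = 0.01, max_epochs = 100, patience = 20,
                       seed = 7)
  m2 <- pretrain(build_model(cfg2, "SNV", c(embedding = 3, ligand = 2)),
                 fx$bundles, fx$y, seed = 7)
  va <- m2$val_idx
  m3 <- fine_tune(m2, fx$bundles[-va], fx$y[-va],
                  eval_bundles = fx$bundles[va], eval_targets = fx$y[va],
                  seed = 9, epochs = 50)
  expect_gte(m3$fine_tune_report$rho_after,
             m3$fine_tune_report$rho_before - 0.05)
})

test_that("grid search selects by mean held-out rho with size tie-breaks", {
  fx <- make_linear_bundles(n = 60, seed = 8)
  y <- fx$y + rnorm(60, 0, 0.2)
  lin <- model_config(encoder_width = 0, trunk_widths = integer(0),
                      activation = "identity", dropout = 0,
                      learning_rate = 0.05, max_epochs = 200, patience = 50)
  dims <- c(embedding = 3, ligand = 2)

  # a one-config grid returns that config
  g1 <- grid_search(list(lin), fx$bundles, y, dims, n_repeats = 2)
  expect_equal(g1$best_index, 1L)

  # true (linear) generating architecture beats a crippled learning rate
  bad <- model_config(encoder_width = 8, trunk_widths = c(16), dropout = 0,
                      learning_rate = 1e-6, max_epochs = 20, patience = 20)
  g2 <- grid_search(list(bad, lin), fx$bundles, y, dims, n_repeats = 3)
  expect_equal(g2$best_index, 2L)
  expect_equal(nrow(g2$report), 2L)
})

test_that("pair prediction averages structures and routes by completeness", {
  # five-block bundles: full when every block (incl. interaction) is present
  set.seed(3)
  mk_full <- function(seed, sid) {
    set.seed(seed)
    feature_bundle("p.A2V", "m",
                   list(embedding = rnorm(3), insilico = rnorm(1),
                        mutation = rnorm(2), ligand = rnorm(2),
                        interaction = rnorm(1)),
                   structure_id = sid)
  }
  mk_partial <- function(seed) {
    set.seed(seed)
    feature_bundle("p.A2V", "m",
                   list(embedding = rnorm(3), insilico = rnorm(1),
                        mutation = rnorm(2)))
  }
  train_full <- lapply(1:30, mk_full, sid = "t")
  y <- rnorm(30)
  cfg <- model_config(encoder_width = 0, trunk_widths = integer(0),
                      activation = "identity", dropout = 0,
                      learning_rate = 0.05, max_epochs = 100, patience = 100,
                      seed = 1)
  dims_full <- c(embedding = 3, insilico = 1, mutation = 2, ligand = 2,
                 interaction = 1)
  snv <- pretrain(build_model(cfg, "SNV", dims_full), train_full, y,
                  split_fraction = 1)
  uv <- pretrain(build_model(cfg, "UV", dims_full[1:3]),
                 ablate_blocks(train_full, c("ligand", "interaction")), y,
                 split_fraction = 1)
  models <- list(snv = snv, uv = uv)

  b1 <- mk_full(101, "s1"); b2 <- mk_full(102, "s2")
  expect_equal(b1$completeness, "full")
  sc <- predict_pair(models, list(b1, b2))
  expect_equal(sc$route, "SNV")
  expect_equal(sc$n_structures_averaged, 2L)
  expect_equal(sc$score,
               mean(c(predict(snv, list(b1)), predict(snv, list(b2)))))
  # structure order is irrelevant
  expect_equal(predict_pair(models, list(b2, b1))$score, sc$score)
  # single structure -> its prediction
  expect_equal(predict_pair(models, list(b1))$score,
               unname(predict(snv, list(b1))))

  # partial-majority pairs go to the UV route
  p1 <- mk_partial(201); p2 <- mk_partial(202)
  expect_equal(p1$completeness, "partial")
  expect_equal(predict_pair(models, list(p1, p2, b1))$route, "UV")
  # tie -> SNV, using only the full bundles
  tie <- predict_pair(models, list(p1, b1))
  expect_equal(tie$route, "SNV")
  expect_equal(tie$score, unname(predict(snv, list(b1))))

  expect_error(predict_pair(models, list()), "empty")
  other <- mk_full(300, "sx"); other$variant <- "p.R3C"
  expect_error(predict_pair(models, list(b1, other)), "more than one")
})
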