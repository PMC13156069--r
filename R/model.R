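## The substrate-specific effect predictor model layer: target scale,
## construction, pretraining, DMS fine-tuning, grid search and per-structure
## score integration.

#' Model configuration
#'
#' @param encoder_width width of the per-block affine encoders; 0 passes the
#'   raw block through (used for the degenerate linear architecture).
#' @param trunk_widths integer vector of trunk layer widths; `integer(0)`
#'   gives a single affine map from the concatenated encoders.
#' @param activation `"relu"` (default) or `"identity"`.
#' @param dropout trunk dropout rate in `[0, 1)`.
#' @param learning_rate Adam learning rate for pretraining.
#' @param fine_tune_learning_rate learning rate during DMS fine-tuning;
#'   defaults to `learning_rate / 10` (all weights stay trainable).
#' @param batch_size minibatch size; 0 = full batch.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without held-out MSE
#'   improvement).
#' @param seed seed for weight initialisation and minibatch order.
#' @return A `model_config` list.
#' @export
model_config <- function(encoder_width = 32, trunk_widths = c(64, 32),
                         activation = c("relu", "identity"), dropout = 0.1,
                         learning_rate = 1e-3,
                         fine_tune_learning_rate = learning_rate / 10,
                         batch_size = 0, max_epochs = 500, patience = 20,
                         seed = 1) {
  activation <- match.arg(activation)
  stopifnot(encoder_width >= 0, all(trunk_widths >= 1),
            dropout >= 0, dropout < 1, learning_rate > 0,
            fine_tune_learning_rate >= 0, max_epochs >= 1, patience >= 1)
  structure(list(encoder_width = as.integer(encoder_width),
                 trunk_widths = as.integer(trunk_widths),
                 activation = activation, dropout = dropout,
                 learning_rate = learning_rate,
                 fine_tune_learning_rate = fine_tune_learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Map percent-of-wildtype uptake to the model target scale
#'
#' The regression target is `log10` of the uptake ratio relative to
#' wildtype, so 100 %WT maps to 0, gains are positive and losses negative.
#' Ratios below the floor (default `1e-3`) are clipped, keeping complete
#' loss of function finite at -3.
#'
#' @param uptake_pct_wt percent-of-wildtype values (>= 0).
#' @param floor_ratio lower clip on the uptake ratio.
#' @return Model-scale scores.
#' @export
target_transform <- function(uptake_pct_wt, floor_ratio = 1e-3) {
  stopifnot(all(uptake_pct_wt >= 0))
  log10(pmax(uptake_pct_wt / 100, floor_ratio))
}

#' Map model-scale scores back to percent of wildtype
#'
#' @param score model-scale scores.
#' @return Percent-of-wildtype values.
#' @export
inverse_transform <- function(score) 100 * 10^score

#' Build an (untrained) substrate-specific effect model
#'
#' The network is a multi-input feed-forward regressor: one affine encoder
#' per feature block, concatenation, a dense trunk and a scalar output. The
#' SNV route expects the complete block set; the UV route is configured with
#' whatever blocks partial bundles carry (indels, missing structures or
#' embeddings).
#'
#' @param config a [model_config()].
#' @param route `"SNV"` or `"UV"`.
#' @param block_dims named integer vector giving the input width of each
#'   feature block the route accepts.
#' @return An `ssep_model`; its `n_params` field reports the parameter
#'   count.
#' @export
build_model <- function(config, route = c("SNV", "UV"), block_dims) {
  route <- match.arg(route)
  if (is.null(names(block_dims)) || any(!nzchar(names(block_dims))) ||
      any(block_dims < 1))
    stop("configuration error: block_dims must be a named vector of widths >= 1",
         call. = FALSE)
  params <- with_seed(config$seed,
    nn_init(as.list(block_dims), config$encoder_width, config$trunk_widths))
  structure(list(
    config = config, route = route,
    blocks = names(block_dims),
    block_dims = block_dims,
    params = params,
    n_params = nn_n_params(params),
    scaler = NULL,
    target_meta = list(scale = "log10_uptake_ratio", floor_ratio = 1e-3,
                       wildtype = 0),
    log = NULL, trained = FALSE
  ), class = "ssep_model")
}

#' @export
print.ssep_model <- function(x, ...) {
  cat(sprintf("<ssep_model> route=%s blocks={%s} params=%d %s\n",
              x$route, paste(x$blocks, collapse = ","), x$n_params,
              if (x$trained) "(trained)" else "(untrained)"))
  invisible(x)
}

.check_blocks <- function(model, X) {
  extra <- setdiff(names(X), model$blocks)
  if (length(extra))
    stop(sprintf("%s route was not configured for block(s): %s",
                 model$route, paste(extra, collapse = ", ")), call. = FALSE)
  missing <- setdiff(model$blocks, names(X))
  if (length(missing))
    stop("missing feature block(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  X[model$blocks]
}

.fit_scaler <- function(X) lapply(X, function(m) {
  s <- apply(m, 2, stats::sd)
  list(center = colMeans(m), scale = ifelse(s > 0, s, 1))
})

.apply_scaler <- function(X, scaler) {
  for (b in names(X))
    X[[b]] <- sweep(sweep(X[[b]], 2, scaler[[b]]$center), 2,
                    scaler[[b]]$scale, "/")
  X
}

#' Predict model-scale scores for a set of bundles
#'
#' @param object a trained `ssep_model`.
#' @param bundles list of [feature_bundle()] objects (or a prebuilt
#'   [bundle_matrix()] result).
#' @param ... unused.
#' @return Numeric vector of model-scale predictions.
#' @export
predict.ssep_model <- function(object, bundles, ...) {
  bm <- if (is.list(bundles) && !is.null(bundles$X)) bundles
        else bundle_matrix(bundles)
  X <- .check_blocks(object, bm$X)
  if (!is.null(object$scaler)) X <- .apply_scaler(X, object$scaler)
  nn_forward(object$params, X, object$config$activation)
}

#' Pretrain the model on labelled activity bundles
#'
#' Adam + mean-squared-error on model-scale targets, with an 85/15
#' train/held-out split (by default), early stopping on held-out MSE and
#' best-weight restoration. With `retrain_all = TRUE` the model is then
#' retrained on the entire pretraining set for the epoch count selected by
#' early stopping (the final-stage regimen).
#'
#' @param model an `ssep_model` from [build_model()].
#' @param bundles list of [feature_bundle()] objects.
#' @param targets model-scale targets, one per bundle.
#' @param split_fraction fraction used for training (default 0.85).
#' @param seed seed controlling the split, initial weights were seeded at
#'   [build_model()] time.
#' @param retrain_all retrain on all data after early stopping.
#' @return The trained model; `model$log` holds per-epoch losses and
#'   `model$val_idx` the held-out indices.
#' @export
pretrain <- function(model, bundles, targets, split_fraction = 0.85,
                     seed = model$config$seed, retrain_all = FALSE) {
  stopifnot(inherits(model, "ssep_model"))
  if (length(bundles) < 10L)
    stop("pretraining needs at least 10 labelled bundles", call. = FALSE)
  if (length(targets) != length(bundles) || any(!is.finite(targets)))
    stop("targets must be finite, one per bundle", call. = FALSE)
  bm <- bundle_matrix(bundles, blocks = model$blocks)
  X <- .check_blocks(model, bm$X)
  model$scaler <- .fit_scaler(X)
  X <- .apply_scaler(X, model$scaler)
  n <- length(targets)
  out <- with_seed(seed, {
    idx <- sample.int(n)
    n_tr <- max(2L, floor(split_fraction * n))
    tr <- idx[seq_len(n_tr)]
    va <- idx[-seq_len(n_tr)]
    Xtr <- lapply(X, function(m) m[tr, , drop = FALSE])
    Xva <- if (length(va)) lapply(X, function(m) m[va, , drop = FALSE]) else NULL
    fit <- nn_train(model$params, Xtr, targets[tr], model$config,
                    lr = model$config$learning_rate,
                    Xval = Xva, yval = if (length(va)) targets[va] else NULL)
    if (retrain_all) {
      params <- with_seed(child_seed(seed, 1),
        nn_init(as.list(model$block_dims), model$config$encoder_width,
                model$config$trunk_widths))
      fit2 <- nn_train(params, X, targets, model$config,
                       lr = model$config$learning_rate,
                       max_epochs = max(fit$best_epoch, 1L))
      fit2$val_idx <- va
      fit2$val_log <- fit$log
      fit2
    } else {
      fit$val_idx <- va
      fit
    }
  })
  model$params <- out$params
  model$opt_state <- out$state
  model$log <- out$log
  model$val_idx <- out$val_idx
  model$trained <- TRUE
  model
}

#' Fine-tune a pretrained model on normalised DMS scores
#'
#' Continues optimisation of all weights at the (lower) fine-tune learning
#' rate on deep-mutational-scanning bundles, whose ligand block is the
#' reporter substrate's. When evaluation data are supplied, held-out
#' Spearman rho is recorded before and after so the fine-tuning benefit is
#' measurable.
#'
#' @param model a pretrained `ssep_model`.
#' @param dms_bundles DMS feature bundles (reporter-substrate ligand block).
#' @param dms_targets normalised DMS scores on the model scale
#'   (see [normalize_dms()]).
#' @param eval_bundles,eval_targets optional held-out evaluation data for
#'   the before/after report.
#' @param seed seed for minibatch order.
#' @param epochs fine-tuning epochs (default 100).
#' @return The fine-tuned model; `model$fine_tune_report` holds
#'   `rho_before`/`rho_after` when evaluation data were given.
#' @export
fine_tune <- function(model, dms_bundles, dms_targets,
                      eval_bundles = NULL, eval_targets = NULL,
                      seed = model$config$seed, epochs = 100) {
  stopifnot(inherits(model, "ssep_model"), model$trained)
  if (length(dms_bundles) == 0L) {
    warning("empty DMS set: fine-tuning skipped", call. = FALSE)
    return(model)
  }
  report <- list()
  if (!is.null(eval_bundles))
    report$rho_before <- spearman(predict(model, eval_bundles), eval_targets)$rho
  bm <- bundle_matrix(dms_bundles, blocks = model$blocks)
  X <- .apply_scaler(.check_blocks(model, bm$X), model$scaler)
  out <- with_seed(seed, nn_train(
    model$params, X, dms_targets, model$config,
    lr = model$config$fine_tune_learning_rate,
    state = model$opt_state, max_epochs = epochs))
  model$params <- out$params
  model$opt_state <- out$state
  model$log <- rbind(model$log, out$log)
  if (!is.null(eval_bundles))
    report$rho_after <- spearman(predict(model, eval_bundles), eval_targets)$rho
  model$fine_tune_report <- report
  model
}

#' Grid-search hyperparameter selection on mean held-out Spearman rho
#'
#' Each candidate configuration is pretrained `n_repeats` times (one seed
#' per repeat); the mean held-out Spearman rho across repeats is the
#' selection criterion. Ties go to the smaller parameter count, then to the
#' earlier configuration in grid order.
#'
#' @param grid list of [model_config()] objects.
#' @param bundles,targets pretraining data as in [pretrain()].
#' @param block_dims named block widths as in [build_model()].
#' @param route model route.
#' @param n_repeats repeats per configuration (default 5).
#' @param seeds seeds for the repeats (default `0:(n_repeats-1)`).
#' @param split_fraction train fraction per repeat.
#' @return List with `best_config`, `best_index` and a `report` data.frame
#'   (one row per configuration: mean/sd rho, parameter count, failures).
#' @export
grid_search <- function(grid, bundles, targets, block_dims,
                        route = "SNV", n_repeats = 5,
                        seeds = seq_len(n_repeats) - 1, split_fraction = 0.85) {
  stopifnot(length(grid) >= 1, n_repeats >= 1)
  rows <- lapply(seq_along(grid), function(ci) {
    cfg <- grid[[ci]]
    rhos <- rep(NA_real_, length(seeds))
    errs <- character()
    npar <- NA_integer_
    for (si in seq_along(seeds)) {
      res <- tryCatch({
        cfg_i <- cfg
        cfg_i$seed <- child_seed(seeds[si], ci)
        m <- build_model(cfg_i, route, block_dims)
        npar <<- m$n_params
        m <- pretrain(m, bundles, targets, split_fraction = split_fraction,
                      seed = cfg_i$seed)
        va <- m$val_idx
        if (length(va) < 3L) stop("held-out split too small for rho")
        preds <- predict(m, bundles[va])
        spearman(preds, targets[va])$rho
      }, error = function(e) {
        errs <<- c(errs, conditionMessage(e))
        NA_real_
      })
      rhos[si] <- res
    }
    data.frame(config = ci, mean_rho = mean(rhos, na.rm = TRUE),
               sd_rho = stats::sd(rhos), n_params = npar,
               n_failed = sum(is.na(rhos)),
               error = if (length(errs)) errs[1] else NA_character_)
  })
  report <- do.call(rbind, rows)
  ok <- !is.nan(report$mean_rho) & report$n_failed < length(seeds)
  if (!any(ok)) {
    stop("grid search: all configurations failed\n",
         paste(sprintf("  config %d: %s", report$config, report$error),
               collapse = "\n"), call. = FALSE)
  }
  cand <- report[ok, , drop = FALSE]
  best <- cand[order(-cand$mean_rho, cand$n_params, cand$config), ][1, "config"]
  list(best_config = grid[[best]], best_index = best, report = report)
}

#' Integrate per-structure predictions into one SSEP score
#'
#' All bundles must belong to one (variant, substrate) pair. The route is
#' chosen by majority bundle completeness (full -> SNV, partial -> UV; ties
#' go to SNV), and the score is the unweighted mean of the per-structure
#' predictions of the chosen model.
#'
#' @param models list with trained models `snv` and/or `uv`.
#' @param bundles bundles for one variant-substrate pair (one per
#'   structure).
#' @return An `ssep_score` list: `variant`, `substrate`, `score`
#'   (model-scale log10 uptake ratio), `n_structures_averaged`, `route`.
#' @export
predict_pair <- function(models, bundles) {
  if (!length(bundles)) stop("empty bundle list", call. = FALSE)
  pair <- unique(t(vapply(bundles, function(b) c(b$variant, b$substrate),
                          character(2))))
  if (nrow(pair) != 1L)
    stop("bundles span more than one variant-substrate pair", call. = FALSE)
  compl <- vapply(bundles, `[[`, character(1), "completeness")
  route <- if (sum(compl == "full") >= sum(compl == "partial")) "SNV" else "UV"
  model <- if (route == "SNV") models$snv else models$uv
  if (is.null(model))
    stop(sprintf("no %s model supplied for a %s-routed pair", route, route),
         call. = FALSE)
  use <- if (route == "SNV" && any(compl == "full") && any(compl != "full"))
    bundles[compl == "full"] else bundles
  # subset each bundle to the route's configured blocks (a full bundle fed
  # to the UV route contributes only the blocks that route was trained on)
  preds <- vapply(use, function(b)
    predict(model, bundle_matrix(list(b), blocks = model$blocks)), numeric(1))
  structure(list(variant = pair[1, 1], substrate = pair[1, 2],
                 score = mean(preds),
                 n_structures_averaged = length(preds), route = route),
            class = "ssep_score")
}

#' @export
print.ssep_score <- function(x, ...) {
  cat(sprintf("<ssep_score> %s x %s: %.3f (route %s, %d structure%s)\n",
              x$variant, x$substrate, x$score, x$route,
              x$n_structures_averaged,
              if (x$n_structures_averaged == 1) "" else "s"))
  invisible(x)
}

#' Effective linear coefficients of a degenerate (affine) model
#'
#' For the no-hidden-layer, identity-activation architecture the model is an
#' affine map; this returns its intercept and slopes on the original
#' (unstandardised) feature scale, comparable to ordinary least squares.
#'
#' @param model a trained degenerate `ssep_model`.
#' @return Named numeric vector: `(intercept, <feature slopes>)`.
#' @export
linear_coefficients <- function(model) {
  stopifnot(inherits(model, "ssep_model"))
  if (model$config$encoder_width != 0 || length(model$config$trunk_widths) ||
      model$config$activation != "identity")
    stop("linear_coefficients is defined for the degenerate affine architecture",
         call. = FALSE)
  w <- drop(model$params$out$W)
  centers <- unlist(lapply(model$scaler, `[[`, "center"))
  scales <- unlist(lapply(model$scaler, `[[`, "scale"))
  slopes <- w / scales
  c(intercept = model$params$out$b - sum(centers * slopes), slopes)
}
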