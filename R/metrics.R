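## Evaluation statistics: Spearman, RMSE/rank error, activity binning,
## Jonckheere-Terpstra trend test, Kruskal-Wallis, ROC-AUC and the
## per-substrate benchmarking helpers.
##
## Small-sample p-values are exact (full enumeration of permutations /
## group assignments); larger samples use the standard approximations with
## tie corrections.

# all permutations of 1..n (n <= 9 guarded by callers)
.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)
    if (pos < n) block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                                sub[, pos:(n - 1L), drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

# enumerate all distinct assignments of indices 1..n into groups of the
# given sizes; calls fn(list of index vectors) for each
.for_each_assignment <- function(n, sizes, fn) {
  recurse <- function(remaining, sizes_left, acc) {
    if (!length(sizes_left)) { fn(acc); return(invisible(NULL)) }
    if (length(sizes_left) == 1L) {
      fn(c(acc, list(remaining))); return(invisible(NULL))
    }
    k <- sizes_left[1]
    # fix the smallest remaining index into the first group when group sizes
    # would otherwise double-count? (sizes may differ, so enumerate fully)
    picks <- utils::combn(remaining, k, simplify = FALSE)
    for (p in picks) recurse(setdiff(remaining, p), sizes_left[-1], c(acc, list(p)))
  }
  recurse(seq_len(n), sizes, list())
}

#' Spearman rank correlation with small-sample exact p-value
#'
#' Ties receive average ranks. The p-value is two-sided: exact by full
#' permutation enumeration for `n <= 8`, otherwise from the standard
#' t approximation `t = rho * sqrt((n-2)/(1-rho^2))`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return List with `rho`, `p`, `n`, `method`.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("spearman needs n >= 3", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("undefined Spearman rho: constant input vector", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8L) {
    perms <- .all_perms(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = min(p, 1), n = n, method = method)
}

#' Root-mean-square error on the model scale
#'
#' @param pred,obs numeric vectors of equal length.
#' @return RMSE.
#' @export
rmse <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  sqrt(mean((pred - obs)^2))
}

#' Per-pair normalised absolute rank error
#'
#' `|rank(pred_i) - rank(obs_i)| / n` with average ranks; 0 for perfectly
#' rank-concordant predictions and invariant to monotone transforms.
#'
#' @param pred,obs numeric vectors of equal length.
#' @return Numeric vector of per-pair rank errors in `[0, 1)`.
#' @export
rank_error <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  abs(rank(pred) - rank(obs)) / length(pred)
}

#' Bin percent-of-wildtype activity
#'
#' `"three_bin"` labels pairs decreased (`< 50`), neutral, or increased
#' (`> 200`); the boundary values themselves are neutral (strict
#' inequalities, the canonical convention; `inclusive = TRUE` switches to
#' `<= 50` / `>= 200`). Threshold schemes return the binary positive class:
#' reduced function (`uptake < threshold`) for thresholds 50 and 75,
#' gain of function (`uptake > threshold`) for 125 and 150.
#'
#' @param uptake_pct_wt percent-of-wildtype values.
#' @param scheme one of `"three_bin"`, `"threshold_50"`, `"threshold_75"`,
#'   `"threshold_125"`, `"threshold_150"`.
#' @param inclusive use inclusive boundaries for `three_bin`.
#' @return For `three_bin`, an ordered factor decreased < neutral <
#'   increased; for threshold schemes, a logical vector (positive class).
#' @export
bin_activity <- function(uptake_pct_wt,
                         scheme = c("three_bin", "threshold_50", "threshold_75",
                                    "threshold_125", "threshold_150"),
                         inclusive = FALSE) {
  scheme <- match.arg(scheme)
  u <- uptake_pct_wt
  if (scheme == "three_bin") {
    dec <- if (inclusive) u <= 50 else u < 50
    inc <- if (inclusive) u >= 200 else u > 200
    lab <- ifelse(dec, "decreased", ifelse(inc, "increased", "neutral"))
    return(factor(lab, levels = c("decreased", "neutral", "increased"),
                  ordered = TRUE))
  }
  thr <- as.numeric(sub("threshold_", "", scheme))
  if (thr <= 100) u < thr else u > thr
}

.jt_stat <- function(groups) {
  k <- length(groups)
  jt <- 0
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    xi <- groups[[i]]; xj <- groups[[j]]
    cmp <- outer(xi, xj, "<")
    tie <- outer(xi, xj, "==")
    jt <- jt + sum(cmp) + 0.5 * sum(tie)
  }
  jt
}

#' Jonckheere-Terpstra trend test across ordered groups
#'
#' The statistic is the sum over ordered group pairs of Mann-Whitney
#' counts (ties counted 1/2). The p-value is one-sided for an increasing
#' trend: exact by full enumeration of group assignments for total
#' `n <= 10`, otherwise a normal approximation with tie correction.
#'
#' @param groups list of numeric vectors in increasing bin order.
#' @param method `"auto"` (exact up to total n = 10, then normal),
#'   `"exact"`, or `"normal"`.
#' @return List with `JT`, `p`, `n`, `method`.
#' @export
jonckheere_test <- function(groups, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  groups <- groups[lengths(groups) > 0L]
  if (length(groups) < 2L)
    stop("Jonckheere test needs at least 2 non-empty ordered groups",
         call. = FALSE)
  sizes <- lengths(groups)
  N <- sum(sizes)
  jt <- .jt_stat(groups)
  if (method == "exact" || (method == "auto" && N <= 10L)) {
    pooled <- unlist(groups)
    count <- 0L; total <- 0L
    .for_each_assignment(N, sizes, function(assign) {
      stat <- .jt_stat(lapply(assign, function(ix) pooled[ix]))
      total <<- total + 1L
      if (stat >= jt - 1e-12) count <<- count + 1L
    })
    return(list(JT = jt, p = count / total, n = N, method = "exact permutation"))
  }
  mu <- (N^2 - sum(sizes^2)) / 4
  tj <- as.numeric(table(unlist(groups)))
  v1 <- (N * (N - 1) * (2 * N + 5) -
           sum(sizes * (sizes - 1) * (2 * sizes + 5)) -
           sum(tj * (tj - 1) * (2 * tj + 5))) / 72
  v2 <- sum(sizes * (sizes - 1) * (sizes - 2)) *
    sum(tj * (tj - 1) * (tj - 2)) / (36 * N * (N - 1) * (N - 2))
  v3 <- sum(sizes * (sizes - 1)) * sum(tj * (tj - 1)) / (8 * N * (N - 1))
  sdv <- sqrt(v1 + v2 + v3)
  if (sdv == 0) return(list(JT = jt, p = 1, n = N, method = "normal approximation"))
  z <- (jt - mu - 0.5) / sdv # continuity-corrected upper tail
  list(JT = jt, p = stats::pnorm(z, lower.tail = FALSE), n = N,
       method = "normal approximation")
}

.kw_stat <- function(groups) {
  # tie-corrected Kruskal-Wallis H, matching stats::kruskal.test
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  N <- length(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr > 0) H / corr else 0
}

#' Kruskal-Wallis rank test with small-sample exact p-value
#'
#' Tie-corrected H; the p-value comes from the chi-squared approximation
#' (k-1 df, via [stats::kruskal.test()]) except for total `n <= 10`, where
#' the full permutation distribution of H is enumerated.
#'
#' @param groups list of numeric vectors (>= 2 groups, each non-empty).
#' @param method `"auto"` (exact up to total n = 10, then chi-squared),
#'   `"exact"`, or `"chisq"`.
#' @return List with `H`, `p`, `df`, `n`, `method`.
#' @export
kruskal_wallis <- function(groups, method = c("auto", "exact", "chisq")) {
  method <- match.arg(method)
  if (length(groups) < 2L || any(lengths(groups) == 0L))
    stop("Kruskal-Wallis needs >= 2 non-empty groups", call. = FALSE)
  N <- sum(lengths(groups))
  if (N < 3L) stop("Kruskal-Wallis needs total n >= 3", call. = FALSE)
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L)
    return(list(H = 0, p = 1, df = length(groups) - 1L, n = N,
                method = "degenerate (all values identical)"))
  kt <- stats::kruskal.test(x, g)
  H <- unname(kt$statistic)
  if (method == "exact" || (method == "auto" && N <= 10L)) {
    sizes <- lengths(groups)
    count <- 0L; total <- 0L
    .for_each_assignment(N, sizes, function(assign) {
      stat <- .kw_stat(lapply(assign, function(ix) x[ix]))
      total <<- total + 1L
      if (stat >= H - 1e-12) count <<- count + 1L
    })
    return(list(H = H, p = count / total, df = length(groups) - 1L, n = N,
                method = "exact permutation"))
  }
  list(H = H, p = unname(kt$p.value), df = unname(kt$parameter), n = N,
       method = "chi-squared approximation")
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' `AUC = U / (n1 * n0)` with tied score pairs counted 1/2, computed via
#' average ranks.
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels logical or 0/1 vector; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("ROC-AUC undefined: one class absent", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.method_scores <- function(tab, keys) {
  # tab: data.frame with gene, variant, [substrate], score
  if ("substrate" %in% names(tab)) {
    i <- match(paste(keys$gene, keys$variant, keys$substrate, sep = "\r"),
               paste(tab$gene, tab$variant, tab$substrate, sep = "\r"))
  } else {
    i <- match(paste(keys$gene, keys$variant, sep = "\r"),
               paste(tab$gene, tab$variant, sep = "\r"))
  }
  tab$score[i]
}

#' Per-substrate benchmark of prediction methods against measured uptake
#'
#' For every substrate with at least `min_variants` measured variants, the
#' absolute Spearman correlation between each method's scores and the
#' observed uptake is computed; methods are then compared across substrates
#' with an omnibus Kruskal-Wallis test on their |rho| distributions.
#'
#' @param methods named list of score tables, each a data.frame with
#'   columns `gene`, `variant`, `score` and optionally `substrate`
#'   (substrate-specific methods).
#' @param table aggregated activity table.
#' @param min_variants minimum variants per substrate (default 10).
#' @return List with `per_substrate` (data.frame substrate/method/abs_rho/n),
#'   `medians` (named vector of per-method median |rho|), and `kruskal`
#'   (omnibus H and p across methods).
#' @export
per_substrate_benchmark <- function(methods, table, min_variants = 10) {
  stopifnot(length(methods) >= 2L)
  rows <- list()
  for (sub in unique(table$substrate)) {
    at <- table[table$substrate == sub, , drop = FALSE]
    if (length(unique(at$variant)) < min_variants) next
    for (m in names(methods)) {
      sc <- .method_scores(methods[[m]], at)
      ok <- is.finite(sc) & is.finite(at$uptake_pct_wt)
      if (sum(ok) < max(3, min_variants) ||
          length(unique(sc[ok])) < 2L || length(unique(at$uptake_pct_wt[ok])) < 2L)
        next
      rho <- spearman(sc[ok], at$uptake_pct_wt[ok])$rho
      rows[[length(rows) + 1L]] <- data.frame(
        substrate = sub, method = m, abs_rho = abs(rho), n = sum(ok))
    }
  }
  if (!length(rows))
    stop("no substrate passes the min_variants filter", call. = FALSE)
  per <- do.call(rbind, rows)
  groups <- split(per$abs_rho, per$method)
  kw <- if (length(groups) >= 2L && all(lengths(groups) > 0L))
    kruskal_wallis(groups) else list(H = NA_real_, p = NA_real_)
  list(per_substrate = per,
       medians = sort(vapply(groups, stats::median, numeric(1)),
                      decreasing = TRUE),
       kruskal = kw)
}

#' Per-substrate ROC-AUC summary across methods
#'
#' As [per_substrate_benchmark()], with per-substrate AUC in place of
#' |rho|: activities are binarised by the threshold scheme and each
#' method's scores (oriented as higher = more activity) are scored against
#' the positive class, flipping direction for reduced-function thresholds so
#' that an informative method always scores above 0.5. Methods with constant
#' scores on a substrate have undefined AUC there and are excluded with a
#' warning. Means and standard errors are taken across substrates.
#'
#' @param methods named list of score tables (see
#'   [per_substrate_benchmark()]).
#' @param table aggregated activity table.
#' @param scheme threshold scheme passed to [bin_activity()]
#'   (default `"threshold_50"`).
#' @param min_variants minimum variants per substrate (default 10).
#' @return List with `per_substrate` (substrate/method/auc/n) and `summary`
#'   (data.frame method/mean_auc/sem/n_substrates).
#' @export
per_substrate_auc_summary <- function(methods, table,
                                      scheme = "threshold_50",
                                      min_variants = 10) {
  stopifnot(length(methods) >= 1L)
  thr <- as.numeric(sub("threshold_", "", scheme))
  rows <- list()
  for (sub in unique(table$substrate)) {
    at <- table[table$substrate == sub, , drop = FALSE]
    if (length(unique(at$variant)) < min_variants) next
    pos <- bin_activity(at$uptake_pct_wt, scheme)
    if (!any(pos) || all(pos)) next
    for (m in names(methods)) {
      sc <- .method_scores(methods[[m]], at)
      ok <- is.finite(sc)
      if (sum(ok) < min_variants) next
      if (length(unique(sc[ok])) < 2L) {
        warning(sprintf("method '%s' has constant scores for substrate '%s'; AUC undefined, excluded",
                        m, sub), call. = FALSE)
        next
      }
      if (!any(pos[ok]) || all(pos[ok])) next
      oriented <- if (thr <= 100) -sc[ok] else sc[ok]
      rows[[length(rows) + 1L]] <- data.frame(
        substrate = sub, method = m,
        auc = roc_auc(oriented, pos[ok]), n = sum(ok))
    }
  }
  if (!length(rows))
    stop("no substrate passes the min_variants filter", call. = FALSE)
  per <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per, per$method), function(d)
    data.frame(method = d$method[1], mean_auc = mean(d$auc),
               sem = if (nrow(d) > 1)
                 stats::sd(d$auc) / sqrt(nrow(d)) else 0,
               n_substrates = nrow(d))))
  rownames(summ) <- NULL
  list(per_substrate = per, summary = summ[order(-summ$mean_auc), ])
}

#' Full evaluation report for predicted vs observed activities
#'
#' @param pred model-scale predictions.
#' @param obs_pct_wt observed percent-of-wildtype activities.
#' @param substrate optional substrate labels for per-substrate
#'   correlations.
#' @return An `eval_report` list: `spearman_rho`, `spearman_p`, `rmse`
#'   (model scale), `rank_error`, `per_substrate_rho`, `jonckheere` across
#'   three-bin activity groups.
#' @export
evaluate_predictions <- function(pred, obs_pct_wt, substrate = NULL) {
  obs <- target_transform(obs_pct_wt)
  sp <- spearman(pred, obs)
  bins <- bin_activity(obs_pct_wt, "three_bin")
  groups <- split(pred, bins)
  groups <- groups[lengths(groups) > 0L]
  jt <- if (length(groups) >= 2L) jonckheere_test(groups) else NULL
  per_sub <- NULL
  if (!is.null(substrate)) {
    per_sub <- vapply(split(seq_along(pred), substrate), function(ix) {
      if (length(ix) < 3L || length(unique(pred[ix])) < 2L ||
          length(unique(obs[ix])) < 2L) return(NA_real_)
      spearman(pred[ix], obs[ix])$rho
    }, numeric(1))
  }
  structure(list(spearman_rho = sp$rho, spearman_p = sp$p,
                 rmse = rmse(pred, obs), rank_error = rank_error(pred, obs),
                 per_substrate_rho = per_sub, jonckheere = jt,
                 bins = table(bins)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> rho=%.3f (p=%.3g), RMSE=%.3f, mean rank error=%.3f\n",
              x$spearman_rho, x$spearman_p, x$rmse, mean(x$rank_error)))
  if (!is.null(x$jonckheere))
    cat(sprintf("  trend across activity bins: JT=%.1f, p=%.3g\n",
                x$jonckheere$JT, x$jonckheere$p))
  invisible(x)
}
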