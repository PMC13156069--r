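## Descriptive feature-association workflow: collinearity pruning,
## Kruskal-Wallis association against activity groups, BH-FDR, top-k
## selection. This is an exploration of the labelled data, not a
## model-based attribution.

#' Prune collinear features by greedy scan
#'
#' Columns are scanned in schema order; a feature is dropped when its
#' absolute Spearman correlation with any already-kept feature exceeds the
#' threshold (the earlier column is kept). The kept set therefore depends
#' on column order, which is part of the contract.
#'
#' @param features numeric matrix or data.frame (observations x features).
#' @param rho_threshold absolute Spearman correlation above which the later
#'   feature is dropped (default 0.9).
#' @return List with `kept` (character vector) and `dropped` (data.frame
#'   `feature`, `correlated_with`, `abs_rho`).
#' @export
prune_collinear <- function(features, rho_threshold = 0.9) {
  m <- as.matrix(features)
  stopifnot(ncol(m) >= 2L)
  nm <- colnames(m)
  if (is.null(nm)) nm <- paste0("f", seq_len(ncol(m)))
  kept <- integer()
  log <- list()
  for (j in seq_len(ncol(m))) {
    hit <- NA_integer_; hit_rho <- NA_real_
    for (k in kept) {
      r <- suppressWarnings(stats::cor(m[, j], m[, k], method = "spearman"))
      if (is.finite(r) && abs(r) > rho_threshold) { hit <- k; hit_rho <- abs(r); break }
    }
    if (is.na(hit)) kept <- c(kept, j)
    else log[[length(log) + 1L]] <- data.frame(
      feature = nm[j], correlated_with = nm[hit], abs_rho = hit_rho)
  }
  list(kept = nm[kept],
       dropped = if (length(log)) do.call(rbind, log)
                 else data.frame(feature = character(),
                                 correlated_with = character(),
                                 abs_rho = numeric()))
}

#' Rank features by association with activity groups
#'
#' Each feature is tested across the activity groups (the three-bin
#' decreased/neutral/increased labels) with a Kruskal-Wallis test on raw
#' feature values; p-values are adjusted by Benjamini-Hochberg FDR and
#' features ranked by ascending q (ties broken by descending H). The top
#' `k` are flagged as selected.
#'
#' @param features numeric matrix or data.frame (observations x features).
#' @param labels activity group labels from [bin_activity()] (factor).
#' @param k number of features to select (default 4).
#' @return data.frame `feature`, `H`, `p`, `q`, `rank`, `selected`, ordered
#'   by rank.
#' @export
rank_features <- function(features, labels, k = 4) {
  m <- as.matrix(features)
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2L)
    stop("feature ranking needs >= 2 non-empty activity groups", call. = FALSE)
  nm <- colnames(m)
  if (is.null(nm)) nm <- paste0("f", seq_len(ncol(m)))
  res <- lapply(seq_len(ncol(m)), function(j) {
    kw <- kruskal_wallis(split(m[, j], labels))
    data.frame(feature = nm[j], H = kw$H, p = kw$p)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  ord <- order(out$q, -out$H, out$feature)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$selected <- out$rank <= k
  rownames(out) <- NULL
  out
}
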