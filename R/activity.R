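## Activity tables: parsing, aggregation, IO, DMS normalisation.

ACTIVITY_COLUMNS <- c("gene", "variant", "substrate", "smiles",
                      "uptake_pct_wt", "source")

.as_activity <- function(df) {
  class(df) <- c("ssep_activity", "data.frame")
  df
}

#' Aggregate replicate uptake measurements
#'
#' Collapses raw activity records to one row per (gene, variant, substrate)
#' key using the unweighted arithmetic mean of the replicate percent-of-
#' wildtype values; the replicate count is retained as `n_replicates`.
#' Activities are stored as percent of wildtype (100 = wildtype).
#'
#' @param records data.frame with columns `gene`, `variant`, `substrate`,
#'   `uptake_pct_wt` and optionally `smiles`, `source`.
#' @return An aggregated activity table (class `ssep_activity`), one row per
#'   key, sorted by key.
#' @export
aggregate_measurements <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    out <- data.frame(gene = character(), variant = character(),
                      substrate = character(), smiles = character(),
                      uptake_pct_wt = numeric(), source = character(),
                      n_replicates = integer())
    return(.as_activity(out))
  }
  need <- c("gene", "variant", "substrate", "uptake_pct_wt")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("activity records lack required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(!is.finite(records$uptake_pct_wt)) || any(records$uptake_pct_wt < 0))
    stop("uptake_pct_wt must be finite and >= 0", call. = FALSE)
  if (!"smiles" %in% names(records)) records$smiles <- NA_character_
  if (!"source" %in% names(records)) records$source <- NA_character_
  key <- interaction(records$gene, records$variant, records$substrate,
                     drop = TRUE, lex.order = TRUE, sep = "\r")
  idx <- split(seq_len(nrow(records)), key)
  rows <- lapply(idx, function(i) {
    r <- records[i, , drop = FALSE]
    smi <- r$smiles[!is.na(r$smiles)]
    data.frame(gene = r$gene[1], variant = r$variant[1],
               substrate = r$substrate[1],
               smiles = if (length(smi)) smi[1] else NA_character_,
               uptake_pct_wt = mean(r$uptake_pct_wt),
               source = paste(unique(r$source[!is.na(r$source)]),
                              collapse = ";"),
               n_replicates = length(i))
  })
  out <- do.call(rbind, rows)
  out$source[out$source == ""] <- NA_character_
  rownames(out) <- NULL
  .as_activity(out)
}

#' Read an activity table from delimited text
#'
#' Expects a header with at least `gene`, `variant`, `substrate`,
#' `uptake_pct_wt`; unknown extra columns are preserved. Tab- or
#' comma-delimited, inferred from the file extension (`.csv` means comma).
#'
#' @param path file path.
#' @param aggregated if `TRUE` (default) the file is taken to be already
#'   aggregated (one row per key); otherwise rows are passed through
#'   [aggregate_measurements()].
#' @return An `ssep_activity` data.frame.
#' @export
read_activity_table <- function(path, aggregated = TRUE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("gene", "variant", "substrate", "uptake_pct_wt")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("activity table schema error; missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!aggregated) return(aggregate_measurements(df))
  if (!"n_replicates" %in% names(df)) df$n_replicates <- 1L
  .as_activity(df)
}

#' Write an activity table as tab-delimited text
#'
#' Canonical tables round-trip byte-stably through
#' [read_activity_table()] / `write_activity_table()`.
#'
#' @param table an `ssep_activity` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_activity_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Normalise deep-mutational-scanning scores onto the model target scale
#'
#' Rank-quantile map: DMS raw scores are converted to mid-ranks, then mapped
#' onto the empirical distribution of the supplied pretraining targets
#' (model-scale log activities). The map is monotone in the raw score. If a
#' wildtype/synonymous raw score is supplied the output is shifted so that it
#' maps to 0, the wildtype anchor of the target scale.
#'
#' @param dms data.frame with columns `variant`, `score`, or a bare numeric
#'   vector of raw scores.
#' @param targets numeric vector of pretraining targets on the model scale
#'   defining the reference distribution.
#' @param wt_raw optional raw score of the wildtype-synonymous class used to
#'   anchor the normalised scale at 0.
#' @return data.frame with columns `variant`, `raw_score`, `normalized_score`.
#' @export
normalize_dms <- function(dms, targets, wt_raw = NULL) {
  if (is.data.frame(dms)) {
    variant <- dms$variant
    raw <- dms$score
  } else {
    raw <- as.numeric(dms)
    variant <- names(raw) %||% as.character(seq_along(raw))
  }
  if (length(unique(raw[is.finite(raw)])) < 2L)
    stop("degenerate DMS normalisation: fewer than 2 distinct raw scores",
         call. = FALSE)
  if (missing(targets) || length(targets) < 2L)
    stop("normalize_dms needs a reference target distribution (>= 2 values)",
         call. = FALSE)
  map1 <- function(x) {
    # mid-rank of x within the raw scores -> quantile of the target ECDF
    r <- sum(raw < x) + (sum(raw == x) + 1) / 2
    q <- (r - 0.5) / length(raw)
    q <- min(max(q, 0), 1)
    as.numeric(stats::quantile(targets, probs = q, type = 7, names = FALSE))
  }
  norm <- vapply(raw, map1, numeric(1))
  if (!is.null(wt_raw)) norm <- norm - map1(wt_raw)
  data.frame(variant = variant, raw_score = raw, normalized_score = norm)
}
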