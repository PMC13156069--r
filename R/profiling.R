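## Substrate-specificity profiling: per-variant span, SD, directionality,
## per-transporter summary fractions.

#' Profile a variant's activity across substrates
#'
#' Computes the within-variant variability statistics: span
#' (`max(%WT) - min(%WT)`), sample standard deviation, span ratio
#' (`max/min`), mixed directionality (some substrate strictly above and some
#' strictly below 100 %WT) and the high-variability flag (span at or above
#' the threshold, 50 %WT by default).
#'
#' @param values numeric vector of percent-of-wildtype activities (>= 0).
#' @param span_threshold span (in %WT units) at or above which the variant
#'   counts as highly variable; default 50.
#' @param variant optional variant label carried into the result.
#' @return A `variant_profile` list: `n_substrates`, `values`, `median`,
#'   `sd`, `span`, `span_ratio`, `mixed_direction`, `high_variability`.
#' @export
profile_variant <- function(values, span_threshold = 50, variant = NA_character_) {
  values <- as.numeric(values)
  if (length(values) < 1L || any(!is.finite(values)) || any(values < 0))
    stop("values must be finite, non-negative and non-empty", call. = FALSE)
  span <- max(values) - min(values)
  structure(list(
    variant = variant,
    n_substrates = length(values),
    values = values,
    median = stats::median(values),
    sd = if (length(values) > 1L) stats::sd(values) else 0,
    span = span,
    span_ratio = if (min(values) > 0) max(values) / min(values) else NA_real_,
    mixed_direction = mixed_direction(values),
    high_variability = span >= span_threshold
  ), class = "variant_profile")
}

#' @export
print.variant_profile <- function(x, ...) {
  cat(sprintf("<variant_profile> %s: n=%d, span=%.1f %%WT, ratio=%s, mixed=%s, high_var=%s\n",
              x$variant, x$n_substrates, x$span,
              if (is.na(x$span_ratio)) "NA" else sprintf("%.2f", x$span_ratio),
              x$mixed_direction, x$high_variability))
  invisible(x)
}

#' Does a variant show mixed directionality across substrates?
#'
#' TRUE iff some activity is strictly above 100 %WT and some strictly below;
#' values exactly at 100 count as neither direction.
#'
#' @param values numeric vector of percent-of-wildtype activities.
#' @return logical scalar.
#' @export
mixed_direction <- function(values) {
  any(values > 100) && any(values < 100)
}

#' Top-k variants by substrate-dependent span ratio
#'
#' Orders profiles by span ratio (`max/min` uptake), breaking ties by larger
#' absolute span and then by variant label. Profiles containing a zero
#' activity have an undefined ratio and are excluded with a warning.
#'
#' @param profiles list of [profile_variant()] results.
#' @param k number of variants to return (default 3).
#' @return Character vector of variant labels, highest ratio first.
#' @export
top_span_variants <- function(profiles, k = 3) {
  ok <- vapply(profiles, function(p) !is.na(p$span_ratio), logical(1))
  if (any(!ok)) {
    bad <- vapply(profiles[!ok], function(p) as.character(p$variant), character(1))
    warning("excluding variant(s) with zero activity (span ratio undefined): ",
            paste(bad, collapse = ", "), call. = FALSE)
  }
  profiles <- profiles[ok]
  if (!length(profiles)) return(character())
  ratio <- vapply(profiles, `[[`, numeric(1), "span_ratio")
  span <- vapply(profiles, `[[`, numeric(1), "span")
  lab <- vapply(profiles, function(p) as.character(p$variant), character(1))
  ord <- order(-ratio, -span, lab)
  lab[ord][seq_len(min(k, length(ord)))]
}

#' Summarise substrate-specific variability for one transporter
#'
#' Restricts the table to variants measured on at least two substrates and
#' reports the fraction with high variability (span >= threshold) and the
#' fraction with mixed directionality, together with per-variant profiles
#' ordered by median uptake.
#'
#' @param table aggregated activity table ([aggregate_measurements()]).
#' @param gene gene symbol to summarise.
#' @param span_threshold high-variability span threshold, default 50 %WT.
#' @return A `transporter_summary` list: `gene`, `n_variants_profiled`,
#'   `n_high_variability`, `n_mixed_direction`, `pct_high_variability`,
#'   `pct_mixed_direction`, `sd_values`, `profiles` (ordered by median
#'   uptake).
#' @export
summarize_transporter <- function(table, gene, span_threshold = 50) {
  sub <- table[table$gene == gene, , drop = FALSE]
  by_var <- split(sub$uptake_pct_wt, sub$variant)
  by_var <- by_var[vapply(by_var, length, integer(1)) >= 2L]
  profiles <- lapply(names(by_var), function(v)
    profile_variant(by_var[[v]], span_threshold = span_threshold, variant = v))
  n <- length(profiles)
  n_high <- sum(vapply(profiles, `[[`, logical(1), "high_variability"))
  n_mixed <- sum(vapply(profiles, `[[`, logical(1), "mixed_direction"))
  med <- vapply(profiles, `[[`, numeric(1), "median")
  profiles <- profiles[order(med)]
  structure(list(
    gene = gene,
    n_variants_profiled = n,
    n_high_variability = n_high,
    n_mixed_direction = n_mixed,
    pct_high_variability = if (n) 100 * n_high / n else NA_real_,
    pct_mixed_direction = if (n) 100 * n_mixed / n else NA_real_,
    sd_values = vapply(profiles, `[[`, numeric(1), "sd"),
    profiles = profiles
  ), class = "transporter_summary")
}

#' @export
print.transporter_summary <- function(x, ...) {
  cat(sprintf("<transporter_summary> %s: %d variants (>=2 substrates)\n",
              x$gene, x$n_variants_profiled))
  if (x$n_variants_profiled) {
    cat(sprintf("  high variability: %d (%s%%)\n", x$n_high_variability,
                round_half_up(x$pct_high_variability)))
    cat(sprintf("  mixed direction : %d (%s%%)\n", x$n_mixed_direction,
                round_half_up(x$pct_mixed_direction)))
  }
  invisible(x)
}

#' Round half away from zero to integer (display convention for percentages)
#'
#' @param x numeric.
#' @return numeric with 0 decimal places, halves rounded up.
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Presentation transform for uptake ratios
#'
#' `log10(1 + x)`; used only for display, never applied to stored data.
#'
#' @param x percent-of-wildtype values.
#' @return transformed values.
#' @export
log1p10 <- function(x) log10(1 + x)
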