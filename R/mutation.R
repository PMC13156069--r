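## Residue-level mutation descriptors.

.blosum62 <- function() {
  if (is.null(.ssep_env$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .ssep_env$BLOSUM62 <- e$BLOSUM62
  }
  .ssep_env$BLOSUM62
}

#' Residue-level physicochemical descriptors of a substitution or deletion
#'
#' Deltas are mutant minus wildtype on published scales: Kyte-Doolittle
#' hydropathy, Zamyatnin residue volume (A^3), net side-chain charge at
#' pH 7, plus the BLOSUM62 log-odds substitution score. For a single-residue
#' deletion (`alt = "del"`), `is_indel` is set and the deltas follow the
#' wildtype-removal convention: minus the wildtype property, with the
#' BLOSUM62 stop/gap column as substitution score.
#'
#' @param wt_aa wildtype residue, one-letter code.
#' @param alt_aa alternate residue, one-letter code, or `"del"`.
#' @return A `mutation_descriptors` list: `delta_hydropathy`, `delta_volume`,
#'   `delta_charge`, `substitution_score`, `is_indel`.
#' @export
mutation_descriptors <- function(wt_aa, alt_aa) {
  if (!wt_aa %in% .AA1)
    stop(sprintf("unknown amino-acid code '%s'", wt_aa), call. = FALSE)
  if (identical(alt_aa, "del")) {
    out <- list(delta_hydropathy = -.KD[[wt_aa]],
                delta_volume = -.AA_VOLUME[[wt_aa]],
                delta_charge = -.AA_CHARGE[[wt_aa]],
                substitution_score = unname(.blosum62()[wt_aa, "*"]),
                is_indel = TRUE)
    return(structure(out, class = "mutation_descriptors"))
  }
  if (!alt_aa %in% .AA1)
    stop(sprintf("unknown amino-acid code '%s'", alt_aa), call. = FALSE)
  structure(list(
    delta_hydropathy = .KD[[alt_aa]] - .KD[[wt_aa]],
    delta_volume = .AA_VOLUME[[alt_aa]] - .AA_VOLUME[[wt_aa]],
    delta_charge = .AA_CHARGE[[alt_aa]] - .AA_CHARGE[[wt_aa]],
    substitution_score = unname(.blosum62()[wt_aa, alt_aa]),
    is_indel = FALSE
  ), class = "mutation_descriptors")
}

#' Mutation descriptors for a parsed variant
#'
#' @param v a [variant_spec()].
#' @return [mutation_descriptors()] for the variant's substitution/deletion.
#' @export
variant_mutation_descriptors <- function(v) {
  if (v$kind == "missense") mutation_descriptors(v$ref_aa, v$alt_aa)
  else if (v$kind == "single_residue_deletion") mutation_descriptors(v$ref_aa, "del")
  else stop("mutation descriptors are defined for missense and single-residue deletions",
            call. = FALSE)
}
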