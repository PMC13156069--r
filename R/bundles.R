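## Blocked feature bundles per variant-substrate(-structure) triple.

BLOCK_NAMES <- c("embedding", "insilico", "mutation", "ligand", "interaction")

#' Construct a feature bundle
#'
#' @param variant variant label or [variant_spec()].
#' @param substrate substrate name.
#' @param blocks named list of numeric vectors; recognised blocks are
#'   `embedding`, `insilico`, `mutation`, `ligand`, `interaction`.
#' @param structure_id optional structure template identifier.
#' @return A `feature_bundle` with a `completeness` field: `"full"` iff
#'   every block (including at least one interaction block) is present and
#'   finite, else `"partial"`.
#' @export
feature_bundle <- function(variant, substrate, blocks, structure_id = NA_character_) {
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  ok <- vapply(BLOCK_NAMES, function(b)
    b %in% names(blocks) && length(blocks[[b]]) > 0 &&
      all(is.finite(as.numeric(blocks[[b]]))), logical(1))
  structure(list(
    variant = if (inherits(variant, "variant_spec")) variant$label else variant,
    substrate = substrate,
    structure_id = structure_id,
    blocks = lapply(blocks, as.numeric),
    completeness = if (all(ok)) "full" else "partial"
  ), class = "feature_bundle")
}

#' @export
print.feature_bundle <- function(x, ...) {
  cat(sprintf("<feature_bundle> %s x %s [%s]%s: blocks {%s}\n",
              x$variant, x$substrate, x$completeness,
              if (!is.na(x$structure_id)) paste0(" @", x$structure_id) else "",
              paste(sprintf("%s:%d", names(x$blocks), lengths(x$blocks)),
                    collapse = ", ")))
  invisible(x)
}

.num_block <- function(x) {
  if (inherits(x, "mutation_descriptors"))
    c(delta_hydropathy = x$delta_hydropathy, delta_volume = x$delta_volume,
      delta_charge = x$delta_charge, substitution_score = x$substitution_score,
      is_indel = as.numeric(x$is_indel))
  else if (inherits(x, "ligand_descriptors"))
    c(molecular_weight = x$molecular_weight, shape_index = x$shape_index,
      small_ring_count = x$small_ring_count,
      symmetric_atom_count = x$symmetric_atom_count,
      heavy_atom_count = x$heavy_atom_count)
  else if (inherits(x, "interaction_features"))
    c(min_heavy_atom_distance = x$min_heavy_atom_distance,
      contact_count = x$contact_count,
      in_binding_site = as.numeric(x$in_binding_site))
  else as.numeric(x)
}

#' Assemble feature bundles for one variant-substrate pair
#'
#' Builds one bundle per available structure template (or a single
#' structure-free bundle when none are supplied) from: the embedding
#' provider applied to the mutant sequence, the in-silico predictor score
#' table, residue-level mutation descriptors, ligand descriptors from the
#' substrate SMILES, and protein-ligand interaction geometry. Any failing or
#' absent optional resource degrades the bundle to `"partial"` (the UV model
#' route); a missing ligand string is a hard error because substrate
#' specificity is then unrepresentable.
#'
#' @param variant a [variant_spec()] or parseable label.
#' @param substrate substrate name.
#' @param resources list with elements `ligand` (SMILES string, required),
#'   `embedding` ([embedding_provider()], optional), `sequence` (wildtype
#'   sequence, required when `embedding` is given), `insilico` (named
#'   numeric vector of predictor scores for this variant, optional),
#'   `structures` (list of [read_structure()] results, optional),
#'   `offset` (variant-to-structure residue numbering offset, default 0).
#' @return List of [feature_bundle()] objects, one per structure template.
#' @export
assemble <- function(variant, substrate, resources) {
  if (is.character(variant)) variant <- parse_variant(variant)
  if (is.null(resources$ligand))
    stop("assemble: missing ligand string; substrate-specific features are impossible",
         call. = FALSE)
  lig <- .num_block(ligand_descriptors(resources$ligand))
  mut <- .num_block(variant_mutation_descriptors(variant))
  emb <- NULL
  if (!is.null(resources$embedding) && !is.null(resources$sequence)) {
    emb <- tryCatch(
      embed_sequence(resources$embedding, apply_variant(resources$sequence, variant)),
      error = function(e) {
        message("embedding unavailable for ", variant$label, ": ",
                conditionMessage(e))
        NULL
      })
  }
  ins <- resources$insilico
  if (!is.null(ins)) ins <- as.numeric(ins)
  offset <- resources$offset %||% 0
  base_blocks <- list(embedding = emb, insilico = ins, mutation = mut, ligand = lig)
  structures <- resources$structures
  if (is.null(structures) || !length(structures))
    return(list(feature_bundle(variant, substrate, base_blocks)))
  lapply(structures, function(s) {
    inter <- tryCatch(
      .num_block(interaction_features(s, variant$position, offset = offset)),
      error = function(e) {
        message("interaction features unavailable (", s$structure_id, "): ",
                conditionMessage(e))
        NULL
      })
    feature_bundle(variant, substrate, c(base_blocks, list(interaction = inter)),
                   structure_id = s$structure_id)
  })
}

#' Remove feature blocks from bundles (ablation)
#'
#' @param bundles list of [feature_bundle()] objects.
#' @param drop character vector of block names to remove.
#' @return Bundles without the dropped blocks (completeness re-evaluated).
#' @export
ablate_blocks <- function(bundles, drop) {
  lapply(bundles, function(b)
    feature_bundle(b$variant, b$substrate,
                   b$blocks[setdiff(names(b$blocks), drop)],
                   structure_id = b$structure_id))
}

#' Stack bundles into per-block design matrices
#'
#' @param bundles list of [feature_bundle()] objects.
#' @param blocks block names to use; defaults to the blocks of the first
#'   bundle. Every bundle must carry all requested blocks with matching
#'   lengths.
#' @return List with `X` (named list of n-by-p matrices) and `meta`
#'   (data.frame of variant, substrate, structure_id, completeness).
#' @export
bundle_matrix <- function(bundles, blocks = NULL) {
  stopifnot(length(bundles) > 0)
  if (is.null(blocks)) blocks <- names(bundles[[1]]$blocks)
  X <- lapply(blocks, function(bn) {
    rows <- lapply(bundles, function(b) {
      if (is.null(b$blocks[[bn]]))
        stop(sprintf("bundle %s x %s lacks block '%s'",
                     b$variant, b$substrate, bn), call. = FALSE)
      b$blocks[[bn]]
    })
    do.call(rbind, rows)
  })
  names(X) <- blocks
  meta <- data.frame(
    variant = vapply(bundles, `[[`, character(1), "variant"),
    substrate = vapply(bundles, `[[`, character(1), "substrate"),
    structure_id = vapply(bundles, `[[`, character(1), "structure_id"),
    completeness = vapply(bundles, `[[`, character(1), "completeness"),
    stringsAsFactors = FALSE)
  list(X = X, meta = meta)
}
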