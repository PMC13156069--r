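## Ligand physicochemical descriptors from SMILES.
##
## Molecular graphs are parsed with ChemmineR/OpenBabel; the descriptors
## themselves (kappa shape index, topological symmetry count, small-ring
## count over an SSSR) are computed here on the heavy-atom graph.

# memoise parsed molecules: OpenBabel parsing dominates runtime otherwise
.mol_cache <- new.env(parent = emptyenv())

.formula_heavy_atoms <- function(formula) {
  # element counts from a Hill-notation formula, hydrogens excluded
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  elems <- sub("[0-9]*$", "", toks)
  counts <- as.integer(sub("^[A-Za-z]+", "", toks))
  counts[is.na(counts)] <- 1L
  keep <- elems != "H"
  rep(elems[keep], counts[keep])
}

.parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!is.null(.mol_cache[[smiles]])) return(.mol_cache[[smiles]])
  props <- tryCatch(
    suppressWarnings(ChemmineOB::forEachMol("SMILES", smiles,
                                            ChemmineOB::prop_OB))[[1]],
    error = function(e) NULL)
  if (is.null(props) || !is.finite(props$MW[1]) || props$MW[1] <= 0 ||
      !nzchar(props$formula[1]))
    stop(sprintf("cannot parse ligand line notation '%s'", smiles),
         call. = FALSE)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "mol"))),
    error = function(e) NULL)
  ab <- if (is.null(sdf)) NULL else tryCatch(ChemmineR::atomblock(sdf[[1]]),
                                             error = function(e) NULL)
  graph_ok <- !is.null(ab) && nrow(ab) > 0L &&
    !identical(rownames(ab), "0") && ncol(ab) > 2L
  if (graph_ok) {
    bb <- ChemmineR::bondblock(sdf[[1]])
    elem <- sub("_.*$", "", rownames(ab))
    heavy <- which(elem != "H")
    idx <- match(seq_along(elem), heavy) # old -> heavy index (NA for H)
    edges <- NULL
    if (!is.null(bb) && nrow(bb) > 0L && ncol(bb) >= 3L &&
        any(bb[, 1] >= 1 & bb[, 2] >= 1)) {
      bb <- bb[bb[, 1] >= 1 & bb[, 2] >= 1, , drop = FALSE]
      a1 <- idx[bb[, 1]]; a2 <- idx[bb[, 2]]
      keep <- !is.na(a1) & !is.na(a2)
      edges <- cbind(a1[keep], a2[keep], bb[keep, 3])
      if (!nrow(edges)) edges <- NULL
    }
    mol <- list(sdf = sdf, mw = props$MW[1], elem = elem[heavy],
                n_heavy = length(heavy), edges = edges, old2heavy = idx)
  } else {
    # bond-free molecules (e.g. methane) defeat the SDF round-trip;
    # reconstruct the trivial graph from the molecular formula
    elems <- .formula_heavy_atoms(props$formula[1])
    mol <- list(sdf = NULL, mw = props$MW[1], elem = elems,
                n_heavy = length(elems), edges = NULL,
                old2heavy = seq_along(elems))
  }
  .mol_cache[[smiles]] <- mol
  mol
}

.adjacency_list <- function(mol) {
  adj <- vector("list", mol$n_heavy)
  if (!is.null(mol$edges) && nrow(mol$edges))
    for (k in seq_len(nrow(mol$edges))) {
      i <- mol$edges[k, 1]; j <- mol$edges[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  adj
}

# Kier second kappa shape index on the heavy-atom graph:
#   kappa2 = (A - 1) (A - 2)^2 / P2^2
# with A heavy atoms and P2 the number of 2-bond paths.
.kappa2 <- function(mol) {
  A <- mol$n_heavy
  if (A < 3L) return(0)
  deg <- lengths(.adjacency_list(mol))
  p2 <- sum(choose(deg, 2))
  if (p2 == 0) return(0)
  (A - 1) * (A - 2)^2 / p2^2
}

# Canonical topological ranks by iterative neighbourhood refinement
# (Morgan-style): initial invariant = element + degree + bond-order sum,
# refined by sorted neighbour ranks until the partition is stable.
.topo_ranks <- function(mol) {
  adj <- .adjacency_list(mol)
  n <- mol$n_heavy
  if (n == 0L) return(integer())
  bosum <- numeric(n)
  if (!is.null(mol$edges) && nrow(mol$edges))
    for (k in seq_len(nrow(mol$edges))) {
      bosum[mol$edges[k, 1]] <- bosum[mol$edges[k, 1]] + mol$edges[k, 3]
      bosum[mol$edges[k, 2]] <- bosum[mol$edges[k, 2]] + mol$edges[k, 3]
    }
  key <- paste(mol$elem, lengths(adj), bosum)
  rank <- match(key, sort(unique(key)))
  repeat {
    key <- vapply(seq_len(n), function(i)
      paste(rank[i], paste(sort(rank[adj[[i]]]), collapse = ","), sep = "|"),
      character(1))
    new_rank <- match(key, sort(unique(key)))
    if (length(unique(new_rank)) == length(unique(rank))) return(new_rank)
    rank <- new_rank
  }
}

# SSSR by greedy GF(2)-independent selection of perceived rings,
# smallest first, up to the cyclomatic number of the heavy-atom graph.
.sssr_sizes <- function(mol) {
  n_edges <- if (is.null(mol$edges)) 0L else nrow(mol$edges)
  if (n_edges == 0L || mol$n_heavy == 0L || is.null(mol$sdf)) return(integer())
  # connected components for the cyclomatic number
  adj <- .adjacency_list(mol)
  comp <- integer(mol$n_heavy); cc <- 0L
  for (s in seq_len(mol$n_heavy)) if (comp[s] == 0L) {
    cc <- cc + 1L; queue <- s; comp[s] <- cc
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]][comp[adj[[v]]] == 0L]
      comp[nb] <- cc; queue <- c(queue, nb)
    }
  }
  n_sssr <- n_edges - mol$n_heavy + cc
  if (n_sssr <= 0L) return(integer())
  all_rings <- tryCatch(ChemmineR::rings(mol$sdf[[1]], type = "all"),
                        error = function(e) list())
  if (!length(all_rings)) return(integer())
  sizes <- lengths(all_rings)
  ord <- order(sizes)
  edge_key <- function(i, j) paste(min(i, j), max(i, j))
  all_keys <- apply(mol$edges, 1, function(e) edge_key(e[1], e[2]))
  # build per-ring GF(2) edge-incidence vectors (ring atom order is cyclic)
  vecs <- lapply(all_rings, function(r) {
    a <- mol$old2heavy[as.integer(sub("^[A-Za-z]+_", "", r))]
    ks <- vapply(seq_along(a), function(t)
      edge_key(a[t], a[if (t == length(a)) 1L else t + 1L]), character(1))
    as.logical(all_keys %in% ks)
  })
  chosen <- integer()
  basis <- list()
  for (i in ord) {
    v <- vecs[[i]]
    for (b in basis) if (v[b$pivot]) v <- xor(v, b$vec)
    if (any(v)) {
      basis[[length(basis) + 1L]] <- list(vec = v, pivot = which(v)[1])
      chosen <- c(chosen, i)
      if (length(chosen) == n_sssr) break
    }
  }
  sizes[chosen]
}

#' Compute ligand physicochemical descriptors from a SMILES string
#'
#' Descriptors: molecular weight (g/mol, implicit hydrogens included), shape
#' index (Kier second kappa, from heavy-atom graph path counts; the exact
#' shape descriptor used upstream is not published, so this documented
#' stand-in is used), small-ring count (rings of size <= 6 in a
#' smallest-set-of-smallest-rings), and symmetric atom count (heavy atoms
#' whose canonical topological rank is shared with at least one other atom).
#' All descriptors are deterministic and invariant to atom-order permutation
#' of the input.
#'
#' @param smiles ligand structure in SMILES line notation.
#' @return A `ligand_descriptors` list: `molecular_weight`, `shape_index`,
#'   `small_ring_count`, `symmetric_atom_count`, `heavy_atom_count`.
#' @export
ligand_descriptors <- function(smiles) {
  mol <- .parse_smiles(smiles)
  mw <- mol$mw
  ranks <- .topo_ranks(mol)
  class_sizes <- table(ranks)
  sym <- sum(ranks %in% as.integer(names(class_sizes)[class_sizes >= 2L]))
  sizes <- .sssr_sizes(mol)
  structure(list(
    molecular_weight = mw,
    shape_index = .kappa2(mol),
    small_ring_count = sum(sizes <= 6L),
    symmetric_atom_count = as.integer(sym),
    heavy_atom_count = mol$n_heavy
  ), class = "ligand_descriptors")
}

#' @export
print.ligand_descriptors <- function(x, ...) {
  cat(sprintf("<ligand_descriptors> MW=%.2f kappa2=%.2f small_rings=%d sym_atoms=%d heavy=%d\n",
              x$molecular_weight, x$shape_index, x$small_ring_count,
              x$symmetric_atom_count, x$heavy_atom_count))
  invisible(x)
}
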