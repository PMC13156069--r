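## Sequence embedding provider contract.
##
## A provider is a list(name, dim, embed) whose `embed` function maps an
## amino-acid sequence to a fixed-length numeric vector, deterministically.
## Real protein-language-model embeddings are consumed through this contract
## from precomputed tables; the bundled fallback provider makes the whole
## pipeline runnable offline.

#' Construct an embedding provider
#'
#' @param name provider name.
#' @param dim output vector length.
#' @param embed function(sequence) -> numeric vector of length `dim`;
#'   must be deterministic for a given sequence.
#' @return An `embedding_provider`.
#' @export
embedding_provider <- function(name, dim, embed) {
  stopifnot(is.function(embed), dim >= 1)
  structure(list(name = name, dim = as.integer(dim), embed = embed),
            class = "embedding_provider")
}

#' Embed a protein sequence through a provider
#'
#' Validates the provider contract: fixed declared length, finite values,
#' determinism by construction.
#'
#' @param provider an [embedding_provider()].
#' @param sequence amino-acid sequence string (non-empty).
#' @return Numeric vector of length `provider$dim`.
#' @export
embed_sequence <- function(provider, sequence) {
  if (!inherits(provider, "embedding_provider"))
    stop("not an embedding_provider", call. = FALSE)
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a non-empty string", call. = FALSE)
  v <- provider$embed(sequence)
  if (length(v) != provider$dim || any(!is.finite(v)))
    stop(sprintf("provider '%s' violated its contract (length %d, declared %d)",
                 provider$name, length(v), provider$dim), call. = FALSE)
  as.numeric(v)
}

#' Offline fallback embedding provider
#'
#' A deterministic hash projection of overlapping 3-mer counts: each 3-mer
#' is mapped by a fixed polynomial hash to one coordinate and a sign, and
#' the signed counts are normalised by sequence length. Requires no model
#' download, is sensitive to single-residue changes, and satisfies the
#' provider contract exactly (bit-identical output for identical input).
#'
#' @param dim embedding dimension (default 64).
#' @return An [embedding_provider()].
#' @export
fallback_embedding_provider <- function(dim = 64) {
  dim <- as.integer(dim)
  embed <- function(sequence) {
    aa <- utf8ToInt(sequence)
    n <- length(aa)
    v <- numeric(dim)
    if (n < 3L) {
      # short sequences: hash the whole string once
      h <- sum(aa * 31^(seq_len(n) - 1)) %% (2 * dim)
      v[(h %% dim) + 1] <- if (h >= dim) -1 else 1
      return(v / max(n, 1))
    }
    for (i in seq_len(n - 2L)) {
      h <- (aa[i] * 961 + aa[i + 1] * 31 + aa[i + 2]) %% (2 * dim)
      j <- (h %% dim) + 1
      v[j] <- v[j] + (if (h >= dim) -1 else 1)
    }
    v / n
  }
  embedding_provider(name = sprintf("kmer-hash-%d", dim), dim = dim,
                     embed = embed)
}

#' Embedding provider backed by a precomputed table
#'
#' Wraps a table of precomputed embeddings (e.g. exported from a protein
#' language model) keyed by sequence; sequences absent from the table raise
#' an error, which [assemble()] downgrades to a partial bundle.
#'
#' @param table data.frame whose first column is the sequence key and whose
#'   remaining numeric columns are the embedding coordinates.
#' @param name provider name.
#' @return An [embedding_provider()].
#' @export
table_embedding_provider <- function(table, name = "precomputed") {
  keys <- as.character(table[[1]])
  mat <- as.matrix(table[, -1, drop = FALSE])
  embedding_provider(name = name, dim = ncol(mat), embed = function(sequence) {
    i <- match(sequence, keys)
    if (is.na(i))
      stop(sprintf("no precomputed embedding for sequence of length %d",
                   nchar(sequence)), call. = FALSE)
    as.numeric(mat[i, ])
  })
}
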