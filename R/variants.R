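## Protein variant labels and residue-level lookup tables.

# one- and three-letter amino-acid codes
.AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
.AA3 <- c("Ala","Arg","Asn","Asp","Cys","Gln","Glu","Gly","His","Ile",
          "Leu","Lys","Met","Phe","Pro","Ser","Thr","Trp","Tyr","Val")

# Kyte-Doolittle hydropathy
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
         G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
         P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# Zamyatnin residue volumes (A^3)
.AA_VOLUME <- c(A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
                Q = 143.8, E = 138.4, G = 60.1, H = 153.2, I = 166.7,
                L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
                S = 89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0)

# net side-chain charge at pH 7; His carries a small positive fraction
.AA_CHARGE <- c(A = 0, R = 1, N = 0, D = -1, C = 0, Q = 0, E = -1, G = 0,
                H = 0.1, I = 0, L = 0, K = 1, M = 0, F = 0, P = 0, S = 0,
                T = 0, W = 0, Y = 0, V = 0)

#' Construct a variant specification
#'
#' @param gene gene symbol.
#' @param kind one of `"missense"`, `"single_residue_deletion"`,
#'   `"other_indel"`.
#' @param position 1-based residue index.
#' @param ref_aa reference residue, one-letter code.
#' @param alt_aa alternate residue, one-letter code (missense only).
#' @return A `variant_spec` object with a canonical `label`.
#' @export
variant_spec <- function(gene = NA_character_, kind, position,
                         ref_aa = NA_character_, alt_aa = NA_character_) {
  kind <- match.arg(kind, c("missense", "single_residue_deletion", "other_indel"))
  position <- as.integer(position)
  if (is.na(position) || position < 1L)
    stop("variant position must be a positive integer", call. = FALSE)
  if (kind == "missense") {
    if (!(ref_aa %in% .AA1) || !(alt_aa %in% .AA1))
      stop("unknown amino-acid code in missense variant", call. = FALSE)
    if (ref_aa == alt_aa)
      stop("missense variant must change the residue (ref_aa != alt_aa)",
           call. = FALSE)
  } else if (kind == "single_residue_deletion") {
    if (!(ref_aa %in% .AA1))
      stop("unknown amino-acid code in deletion variant", call. = FALSE)
    alt_aa <- NA_character_
  }
  v <- structure(
    list(gene = gene, kind = kind, position = position,
         ref_aa = ref_aa, alt_aa = alt_aa),
    class = "variant_spec")
  v$label <- format_variant(v)
  v
}

#' Format a variant specification as a canonical protein-level label
#'
#' @param v a `variant_spec`.
#' @param ... unused.
#' @return A string such as `"p.F244A"` or `"p.M420del"`.
#' @export
format_variant <- function(v, ...) {
  switch(v$kind,
    missense = sprintf("p.%s%d%s", v$ref_aa, v$position, v$alt_aa),
    single_residue_deletion = sprintf("p.%s%ddel", v$ref_aa, v$position),
    other_indel = v$label %||% sprintf("p.%d_indel", v$position))
}

#' @export
format.variant_spec <- function(x, ...) format_variant(x)

#' @export
print.variant_spec <- function(x, ...) {
  cat(sprintf("<variant_spec> %s%s (%s)\n",
              if (!is.na(x$gene)) paste0(x$gene, " ") else "",
              x$label, x$kind))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.canon_aa <- function(token, label) {
  if (token %in% .AA1) return(token)
  hit <- match(token, .AA3)
  if (!is.na(hit)) return(.AA1[hit])
  stop(sprintf("malformed variant label '%s': unknown amino-acid token '%s'",
               label, token), call. = FALSE)
}

#' Parse a protein-level variant label
#'
#' Accepts canonical HGVS-like protein labels with one- or three-letter
#' amino-acid codes, e.g. `"p.F244A"`, `"p.Phe244Ala"`, `"p.M420del"`.
#' Three-letter input is canonicalised to one-letter form; `parse_variant`
#' and [format_variant()] round-trip.
#'
#' @param label variant label string; the leading `"p."` is optional.
#' @param gene optional gene symbol carried into the result.
#' @return A [variant_spec()].
#' @export
parse_variant <- function(label, gene = NA_character_) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("variant label must be a non-empty string", call. = FALSE)
  body <- sub("^p\\.", "", label)
  m <- regmatches(body, regexec("^([A-Za-z]{1,3})([0-9]+)del$", body))[[1]]
  if (length(m) == 3L) {
    ref <- .canon_aa(m[2], label)
    return(variant_spec(gene, "single_residue_deletion",
                        as.integer(m[3]), ref_aa = ref))
  }
  m <- regmatches(body, regexec("^([A-Za-z]{1,3})([0-9]+)([A-Za-z]{1,3})$",
                                body))[[1]]
  if (length(m) == 4L) {
    ref <- .canon_aa(m[2], label)
    alt <- .canon_aa(m[4], label)
    return(variant_spec(gene, "missense", as.integer(m[3]),
                        ref_aa = ref, alt_aa = alt))
  }
  # diagnose the offending token for common malformations
  if (grepl("^[0-9]", body))
    stop(sprintf("malformed variant label '%s': missing reference residue before position",
                 label), call. = FALSE)
  stop(sprintf("malformed variant label '%s': token '%s' is not <ref><pos><alt> or <ref><pos>del",
               label, body), call. = FALSE)
}

#' Apply a variant to a wildtype protein sequence
#'
#' @param sequence wildtype amino-acid sequence (string).
#' @param v a [variant_spec()].
#' @return The mutant sequence string.
#' @export
apply_variant <- function(sequence, v) {
  aa <- strsplit(sequence, "")[[1]]
  if (v$position > length(aa))
    stop(sprintf("variant position %d beyond sequence length %d",
                 v$position, length(aa)), call. = FALSE)
  if (!is.na(v$ref_aa) && aa[v$position] != v$ref_aa)
    stop(sprintf("reference mismatch at %d: sequence has %s, variant %s expects %s",
                 v$position, aa[v$position], v$label, v$ref_aa), call. = FALSE)
  if (v$kind == "missense") {
    aa[v$position] <- v$alt_aa
  } else if (v$kind == "single_residue_deletion") {
    aa <- aa[-v$position]
  } else {
    stop("cannot apply an unspecified indel to a sequence", call. = FALSE)
  }
  paste(aa, collapse = "")
}
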