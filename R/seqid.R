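#' Configuration for percent sequence identity
#'
#' Settings for the pairwise alignment behind the SeqID measure:
#' deterministic Smith-Waterman local alignment with BLOSUM62 and the BLAST
#' protein gap defaults (open 11, extend 1). Global (Needleman-Wunsch) mode
#' is available for sensitivity checks.
#'
#' @param mode `"local"` (default) or `"global"`.
#' @param substitution_matrix name of a \pkg{Biostrings} score matrix.
#' @param gap_open,gap_extend non-negative gap penalties.
#' @param chain_weights numeric length-2 `(w_alpha, w_beta)` or a string
#'   `"(wa:wb)"`; weights for averaging the per-chain identities.
#' @return an object of class `"seqid_config"`.
#' @examples
#' seqid_config(chain_weights = "(0:1)")
#' @export
seqid_config <- function(mode = c("local", "global"),
                         substitution_matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1,
                         chain_weights = c(1, 1)) {
  mode <- match.arg(mode)
  if (is.character(chain_weights))
    chain_weights <- parse_chain_weights(chain_weights)
  stopifnot(is.numeric(chain_weights), length(chain_weights) == 2L)
  if (any(chain_weights < 0) || all(chain_weights == 0))
    stop("chain weights must be non-negative with at least one positive",
         call. = FALSE)
  if (gap_open < 0 || gap_extend < 0)
    stop("gap penalties must be non-negative", call. = FALSE)
  structure(list(mode = mode,
                 substitution_matrix = substitution_matrix,
                 gap_open = gap_open,
                 gap_extend = gap_extend,
                 chain_weights = setNames(as.numeric(chain_weights),
                                          c("alpha", "beta"))),
            class = "seqid_config")
}

#' Percent identity between two chain sequences
#'
#' Aligns each sequence in `x` against `y` and reports
#' `100 * identical aligned residue pairs / min(|x|, |y|)`. Gap columns
#' never count as identities; the min-length normalization means a sequence
#' contained in a longer one scores 100. Each pair is aligned in a
#' canonical (lexicographic) argument order, so the identity is exactly
#' symmetric even when several co-optimal alignments exist.
#'
#' @param x character vector of amino-acid sequences (queries).
#' @param y a single amino-acid sequence.
#' @param config a [seqid_config()].
#' @return numeric vector of identities in `[0, 100]`, one per element of
#'   `x`.
#' @examples
#' chain_identity("AAAA", "AAAC")   # 75
#' chain_identity("AAAA", "AAAAAA") # 100
#' @export
chain_identity <- function(x, y, config = seqid_config()) {
  stopifnot(inherits(config, "seqid_config"),
            is.character(x), is.character(y), length(y) == 1L)
  if (any(!nzchar(x)) || !nzchar(y) || anyNA(x) || is.na(y))
    stop("chain sequences must be non-empty", call. = FALSE)
  type <- if (config$mode == "local") "local" else "global"
  # canonical argument order: traceback tie-breaks then cannot introduce
  # asymmetry between identity(a, b) and identity(b, a)
  flip <- x > y
  pat <- ifelse(flip, y, x)
  sub <- ifelse(flip, x, y)
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(pat),
    subject = Biostrings::AAStringSet(sub),
    type = type,
    substitutionMatrix = config$substitution_matrix,
    gapOpening = config$gap_open,
    gapExtension = config$gap_extend)
  100 * Biostrings::nmatch(al) / pmin(nchar(x), nchar(y))
}

#' Weighted paired-chain percent identity between two TCRs
#'
#' The SeqID of a TCR pair: the per-chain identities from
#' [chain_identity()] averaged with the configured chain weights
#' (normalized to sum 1). The default `(1:1)` gives the plain alpha/beta
#' average used by the hold-out filter and the redundancy clustering.
#'
#' @param a,b single rows of a repertoire (see [read_repertoire()]), each
#'   carrying the full-length chains required by the nonzero weights.
#' @param config a [seqid_config()].
#' @return a single identity in `[0, 100]`.
#' @export
paired_identity <- function(a, b, config = seqid_config()) {
  stopifnot(is.data.frame(a), nrow(a) == 1L, is.data.frame(b), nrow(b) == 1L)
  w <- config$chain_weights / sum(config$chain_weights)
  need <- names(w)[w > 0]
  ids <- c(alpha = NA_real_, beta = NA_real_)
  for (chain in need) {
    col <- if (chain == "alpha") "alpha_seq" else "beta_seq"
    sa <- if (is.null(a[[col]])) NA_character_ else a[[col]]
    sb <- if (is.null(b[[col]])) NA_character_ else b[[col]]
    if (is.na(sa) || !nzchar(sa) || is.na(sb) || !nzchar(sb)) {
      bad_id <- if (is.na(sa) || !nzchar(sa)) a$id else b$id
      stop("record ", sQuote(bad_id), " lacks the full-length ", chain,
           " chain required by the chain weights", call. = FALSE)
    }
    ids[chain] <- chain_identity(sa, sb, config)
  }
  sum(w[need] * ids[need])
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Pairwise paired-chain identity matrix for a repertoire
#'
#' Computes the symmetric matrix of weighted paired-chain identities among
#' all records of a repertoire. Duplicate chains are collapsed before
#' alignment.
#'
#' @param repertoire a repertoire with `alpha_seq`/`beta_seq` columns (as
#'   required by the nonzero chain weights).
#' @param config a [seqid_config()].
#' @return an `n` x `n` numeric matrix with dimnames `repertoire$id` and
#'   100 on the diagonal.
#' @export
repertoire_identity_matrix <- function(repertoire, config = seqid_config()) {
  stopifnot(is.data.frame(repertoire), nrow(repertoire) >= 1L)
  w <- config$chain_weights / sum(config$chain_weights)
  n <- nrow(repertoire)
  out <- matrix(0, n, n, dimnames = list(repertoire$id, repertoire$id))
  for (chain in names(w)[w > 0]) {
    col <- if (chain == "alpha") "alpha_seq" else "beta_seq"
    seqs <- repertoire[[col]]
    if (is.null(seqs) || anyNA(seqs) || any(!nzchar(seqs)))
      stop("repertoire lacks full-length ", chain,
           " chains required by the chain weights", call. = FALSE)
    out <- out + w[[chain]] * chain_identity_matrix(seqs, config)
  }
  out
}

# Symmetric identity matrix for one chain; unique sequences aligned once.
chain_identity_matrix <- function(seqs, config) {
  useqs <- unique(seqs)
  m <- length(useqs)
  um <- matrix(100, m, m)
  if (m > 1) {
    for (j in 2:m) {
      ids <- chain_identity(useqs[seq_len(j - 1L)], useqs[j], config)
      um[seq_len(j - 1L), j] <- ids
      um[j, seq_len(j - 1L)] <- ids
    }
  }
  idx <- match(seqs, useqs)
  um[idx, idx, drop = FALSE]
}
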