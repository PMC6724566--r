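#' Reconstruct a full-length chain from V, CDR3 and J segments
#'
#' Splices a germline V segment, a CDR3 junction and a germline J segment
#' into one chain by overlap matching: the first `overlap` residues of the
#' CDR3 are located in the V sequence (rightmost exact occurrence) and the
#' last `overlap` residues in the J sequence (leftmost exact occurrence),
#' and the three pieces are joined without duplicating the overlaps. A
#' mismatch-tolerant mode allowing up to `max_mismatch` substitutions in
#' each overlap is available.
#'
#' @param v_seq,j_seq germline V / J amino-acid sequences.
#' @param cdr3 CDR3 junction sequence, length at least `overlap`.
#' @param overlap overlap length in residues (default 4).
#' @param max_mismatch allowed mismatches per overlap (default 0, exact).
#' @return the full-length chain string.
#' @examples
#' reconstruct_chain("MKTWCASS", "CASSLGETQYF", "ETQYFGPG")
#' @export
reconstruct_chain <- function(v_seq, cdr3, j_seq, overlap = 4L,
                              max_mismatch = 0L) {
  stopifnot(overlap >= 1L)
  if (nchar(cdr3) < overlap)
    stop("CDR3 ", sQuote(cdr3), " shorter than the overlap length ",
         overlap, call. = FALSE)
  v_pos <- find_overlap(v_seq, substr(cdr3, 1L, overlap),
                        max_mismatch, last = TRUE)
  if (is.na(v_pos))
    stop("no V/CDR3 overlap: V ", sQuote(v_seq), " does not end in ",
         sQuote(substr(cdr3, 1L, overlap)), call. = FALSE)
  j_pos <- find_overlap(j_seq, substr(cdr3, nchar(cdr3) - overlap + 1L,
                                      nchar(cdr3)),
                        max_mismatch, last = FALSE)
  if (is.na(j_pos))
    stop("no CDR3/J overlap: J ", sQuote(j_seq), " does not start with ",
         sQuote(substr(cdr3, nchar(cdr3) - overlap + 1L, nchar(cdr3))),
         call. = FALSE)
  paste0(substr(v_seq, 1L, v_pos - 1L), cdr3,
         substr(j_seq, j_pos + overlap, nchar(j_seq)))
}

# Start position of the (last/first) occurrence of `probe` in `seq` with at
# most max_mismatch substitutions; NA when absent.
find_overlap <- function(seq, probe, max_mismatch, last) {
  k <- nchar(probe)
  n <- nchar(seq)
  if (n < k) return(NA_integer_)
  starts <- seq_len(n - k + 1L)
  if (last) starts <- rev(starts)
  pc <- strsplit(probe, "")[[1]]
  sc <- strsplit(seq, "")[[1]]
  for (i in starts) {
    if (sum(sc[i:(i + k - 1L)] != pc) <= max_mismatch) return(i)
  }
  NA_integer_
}

#' Reconstruct full-length chains for a whole repertoire
#'
#' Fills `alpha_seq` and `beta_seq` from germline V/J sequences and the
#' CDR3 junctions via [reconstruct_chain()]. Records whose gene names are
#' absent from the germline set or whose overlaps fail are dropped and
#' counted.
#'
#' @param repertoire a `tcr_repertoire` (see [read_repertoire()]).
#' @param germline named character vector of germline amino-acid sequences
#'   (see [read_germline()]); names must cover the repertoire's V/J genes.
#' @param overlap,max_mismatch passed to [reconstruct_chain()].
#' @param quiet suppress the per-stage message.
#' @return the repertoire with chains filled, attribute `n_failed` counting
#'   dropped records.
#' @export
reconstruct_repertoire <- function(repertoire, germline, overlap = 4L,
                                   max_mismatch = 0L, quiet = FALSE) {
  stopifnot(is.data.frame(repertoire))
  keep <- logical(nrow(repertoire))
  alpha <- beta <- rep(NA_character_, nrow(repertoire))
  for (i in seq_len(nrow(repertoire))) {
    r <- repertoire[i, ]
    genes <- c(r$va, r$ja, r$vb, r$jb)
    if (any(!genes %in% names(germline))) next
    res <- tryCatch({
      a <- reconstruct_chain(germline[[r$va]], r$cdr3a, germline[[r$ja]],
                             overlap, max_mismatch)
      b <- reconstruct_chain(germline[[r$vb]], r$cdr3b, germline[[r$jb]],
                             overlap, max_mismatch)
      list(a = a, b = b)
    }, error = function(e) NULL)
    if (!is.null(res)) {
      alpha[i] <- res$a
      beta[i] <- res$b
      keep[i] <- TRUE
    }
  }
  out <- repertoire
  out$alpha_seq <- alpha
  out$beta_seq <- beta
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!quiet)
    message(sprintf("reconstruct_repertoire: %d record(s) kept, %d dropped",
                    nrow(out), sum(!keep)))
  structure(as_tcr_repertoire(out), n_failed = sum(!keep))
}

#' Remove cross-reactive TCRs
#'
#' Drops every record whose exact chain pair (full alpha and beta
#' sequences) is assigned to more than one distinct pMHC label; no
#' representative is kept. Records lacking full-length chains are grouped
#' by their CDR3 pair plus gene names instead.
#'
#' @param repertoire a labeled `tcr_repertoire`.
#' @param quiet suppress the per-stage message.
#' @return the filtered repertoire with attribute `n_removed`.
#' @export
remove_cross_reactive <- function(repertoire, quiet = FALSE) {
  stopifnot(is.data.frame(repertoire))
  if (nrow(repertoire) == 0L)
    return(structure(repertoire, n_removed = 0L))
  has_chains <- !is.na(repertoire$alpha_seq) & !is.na(repertoire$beta_seq)
  key <- ifelse(has_chains,
                paste(repertoire$alpha_seq, repertoire$beta_seq, sep = "\r"),
                paste(repertoire$cdr3a, repertoire$cdr3b, repertoire$va,
                      repertoire$ja, repertoire$vb, repertoire$jb,
                      sep = "\r"))
  lab <- tcr_labels(repertoire)
  n_labels <- tapply(lab, key, function(x) length(unique(x[!is.na(x)])))
  cross <- names(n_labels)[n_labels > 1]
  keep <- !(key %in% cross)
  out <- repertoire[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!quiet)
    message(sprintf("remove_cross_reactive: removed %d record(s)",
                    sum(!keep)))
  structure(as_tcr_repertoire(out), n_removed = sum(!keep))
}

#' Reduce repertoire redundancy by identity clustering
#'
#' Single-linkage clusters records whose weighted paired-chain identity
#' meets the threshold, and keeps one centroid per cluster: the member with
#' the highest mean identity to the other members (ties broken by the
#' lexicographically smallest id). Survivors are returned in input order.
#'
#' @param repertoire a `tcr_repertoire` with full-length chains.
#' @param threshold identity threshold in percent (default 99).
#' @param config a [seqid_config()] (chain weights `(1:1)` give the plain
#'   alpha/beta average).
#' @param identity optional precomputed matrix from
#'   [repertoire_identity_matrix()].
#' @param quiet suppress the per-stage message.
#' @return the reduced repertoire with attribute `n_removed`.
#' @export
reduce_redundancy <- function(repertoire, threshold = 99,
                              config = seqid_config(), identity = NULL,
                              quiet = FALSE) {
  stopifnot(is.data.frame(repertoire), threshold > 0, threshold <= 100)
  n <- nrow(repertoire)
  if (n <= 1L) return(structure(repertoire, n_removed = 0L))
  if (is.null(identity))
    identity <- repertoire_identity_matrix(repertoire, config)
  adj <- identity >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  keep <- logical(n)
  for (cl in unique(comp)) {
    members <- which(comp == cl)
    if (length(members) == 1L) {
      keep[members] <- TRUE
      next
    }
    mean_id <- vapply(members, function(i)
      mean(identity[i, setdiff(members, i)]), numeric(1))
    best <- members[order(-mean_id, repertoire$id[members])][1]
    keep[best] <- TRUE
  }
  out <- repertoire[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!quiet)
    message(sprintf("reduce_redundancy: %d cluster(s), removed %d record(s)",
                    length(unique(comp)), sum(!keep)))
  structure(as_tcr_repertoire(out), n_removed = sum(!keep))
}

#' Build a benchmark database from a raw repertoire
#'
#' Runs the full benchmark construction: full-length chain reconstruction
#' from germline segments, cross-reactivity removal, and redundancy
#' reduction at the identity threshold, logging per-stage counts.
#'
#' @inheritParams reconstruct_repertoire
#' @inheritParams reduce_redundancy
#' @return the cleaned `tcr_repertoire` with full-length chains.
#' @export
build_database <- function(repertoire, germline, overlap = 4L,
                           threshold = 99, config = seqid_config(),
                           quiet = FALSE) {
  rec <- reconstruct_repertoire(repertoire, germline, overlap = overlap,
                                quiet = quiet)
  ncr <- remove_cross_reactive(rec, quiet = quiet)
  reduce_redundancy(ncr, threshold = threshold, config = config,
                    quiet = quiet)
}
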