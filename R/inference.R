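#' Maximum sequence identity hold-out filter
#'
#' Removes database entries more similar to the query than the cutoff:
#' entries whose weighted paired-chain identity with the query is strictly
#' greater than `max_seqid` percent are dropped, entries exactly at the
#' cutoff are retained. This is the hold-out used to probe prediction
#' performance when no highly similar TCR is available.
#'
#' @param query a single-row `tcr_repertoire`.
#' @param db a `tcr_repertoire` with full-length chains.
#' @param max_seqid identity cutoff in percent, in `(0, 100]`.
#' @param config a [seqid_config()]; its chain weights define the identity
#'   average (default the plain alpha/beta mean).
#' @return the retained subset of `db` (possibly zero rows) with attribute
#'   `n_removed`.
#' @export
filter_database <- function(query, db, max_seqid, config = seqid_config()) {
  stopifnot(is.data.frame(query), nrow(query) == 1L, is.data.frame(db))
  if (!is.numeric(max_seqid) || max_seqid <= 0 || max_seqid > 100)
    stop("max_seqid must lie in (0, 100]", call. = FALSE)
  ids <- cross_identity_matrix(query, db, config)[1, ]
  keep <- ids <= max_seqid
  out <- db[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(as_tcr_repertoire(out), n_removed = sum(!keep))
}

#' TCR specificity annotator
#'
#' Wraps a reference database of TCRs with known pMHC targets, a similarity
#' model and a maximum-sequence-identity hold-out into a nearest-neighbor
#' classifier. [predict()] scores each query against the retained database
#' entries and assigns the top-ranked (lowest dissimilarity) entry's label.
#'
#' @param db a labeled `tcr_repertoire` (the reference database). Records
#'   must carry the loops/chains the model needs; full-length chains are
#'   required whenever `max_seqid < 100`.
#' @param model a [similarity_model()] or specification string such as
#'   `"CDR(1:1:4-1:1:4)"`.
#' @param max_seqid hold-out cutoff in percent; entries with identity to
#'   the query strictly above it are excluded per query. `100` disables the
#'   filter.
#' @param structures named `tcr_structure` list for structure-based models.
#' @param kernel residue matrix from [blosum62_kernel_matrix()].
#' @param seqid a [seqid_config()] for the identity filter.
#' @param rmsd_cap cap for undefined loop RMSDs, Angstrom.
#' @return an object of class `"tcr_annotator"`.
#' @examples
#' \donttest{
#' synth <- generate_repertoire(synth_config(n_epitopes = 3,
#'                                           tcrs_per_epitope = 4, seed = 7))
#' ann <- tcr_annotator(synth$repertoire, model = "CDR(1:1:1-1:1:1)")
#' pred <- predict(ann, newdata = synth$repertoire[1:2, ])
#' pred$peptide
#' }
#' @export
tcr_annotator <- function(db, model = "CDR(1:1:4-1:1:4)", max_seqid = 99,
                          structures = NULL,
                          kernel = blosum62_kernel_matrix(),
                          seqid = seqid_config(), rmsd_cap = 10) {
  stopifnot(is.data.frame(db), nrow(db) >= 1L)
  if (!is.numeric(max_seqid) || max_seqid <= 0 || max_seqid > 100)
    stop("max_seqid must lie in (0, 100]", call. = FALSE)
  labels <- tcr_labels(db)
  if (anyNA(labels))
    stop("all database records must carry a pMHC label", call. = FALSE)
  structure(list(db = db, model = as_similarity_model(model),
                 max_seqid = max_seqid, structures = structures,
                 kernel = kernel, seqid = seqid, rmsd_cap = rmsd_cap),
            class = "tcr_annotator")
}

#' @export
print.tcr_annotator <- function(x, ...) {
  cat("TCR specificity annotator\n")
  cat(sprintf("  database: %d TCR(s), %d pMHC label(s)\n", nrow(x$db),
              length(unique(tcr_labels(x$db)))))
  cat(sprintf("  model: %s\n", format(x$model)))
  cat(sprintf("  Max SeqID hold-out: %g%%\n", x$max_seqid))
  invisible(x)
}

#' @export
summary.tcr_annotator <- function(object, ...) {
  lab <- tcr_labels(object$db)
  out <- list(model = format(object$model), max_seqid = object$max_seqid,
              n_db = nrow(object$db),
              label_counts = sort(table(lab), decreasing = TRUE))
  class(out) <- "summary.tcr_annotator"
  out
}

#' @export
print.summary.tcr_annotator <- function(x, ...) {
  cat(sprintf("TCR annotator: model %s, Max SeqID %g%%, database of %d\n",
              x$model, x$max_seqid, x$n_db))
  cat("pMHC label counts:\n")
  print(x$label_counts)
  invisible(x)
}

#' Predict pMHC targets for query TCRs
#'
#' Applies the hold-out filter per query, scores the retained entries under
#' the annotator's model, and assigns the label of the top-ranked entry.
#' Score ties are broken by database order, then lexicographic id, with a
#' warning. A query whose filtered database is empty yields an abstention
#' (all-`NA` label, `abstained = TRUE`) rather than a forced prediction.
#'
#' @param object a [tcr_annotator()].
#' @param newdata `tcr_repertoire` of query TCRs.
#' @param structures named `tcr_structure` list for the queries
#'   (structure-based models); defaults to the annotator's own store.
#' @param exclude_self drop a database entry with the same id as the query
#'   (leave-one-out convention).
#' @param ... unused.
#' @return a data frame with one row per query: `query_id`, predicted
#'   `peptide` and `mhc`, `best_hit`, `score`, `n_candidates`, `abstained`.
#' @export
predict.tcr_annotator <- function(object, newdata, structures = NULL,
                                  exclude_self = FALSE, ...) {
  db <- object$db
  if (is.null(structures)) structures <- object$structures
  scores <- score_matrix(newdata, db, object$model, kernel = object$kernel,
                         seqid = object$seqid,
                         structures_query = structures,
                         structures_db = object$structures,
                         rmsd_cap = object$rmsd_cap)
  allowed <- matrix(TRUE, nrow(newdata), nrow(db))
  if (object$max_seqid < 100)
    allowed <- cross_identity_matrix(newdata, db, object$seqid) <=
      object$max_seqid
  if (exclude_self)
    allowed <- allowed & outer(newdata$id, db$id, `!=`)
  assemble_predictions(newdata, db, scores, allowed)
}

# Shared top-1 assignment given a score matrix and a logical candidate mask.
assemble_predictions <- function(query, db, scores, allowed) {
  n <- nrow(query)
  labels_pep <- db$epitope
  labels_mhc <- db$mhc
  out <- data.frame(query_id = query$id,
                    peptide = NA_character_, mhc = NA_character_,
                    best_hit = NA_character_, score = NA_real_,
                    n_candidates = integer(n), abstained = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    cand <- which(allowed[i, ])
    out$n_candidates[i] <- length(cand)
    if (!length(cand)) {
      out$abstained[i] <- TRUE
      next
    }
    s <- scores[i, cand]
    best <- which(s == min(s))
    if (length(best) > 1L) {
      tied <- cand[best]
      # database order first; ids only disambiguate equal positions
      best <- best[order(tied, db$id[tied])][1]
      warning("score tie for query ", sQuote(query$id[i]),
              "; first database entry kept", call. = FALSE)
    }
    j <- cand[best]
    out$peptide[i] <- labels_pep[j]
    out$mhc[i] <- labels_mhc[j]
    out$best_hit[i] <- db$id[j]
    out$score[i] <- scores[i, j]
  }
  out
}

#' Leave-one-out predictions over a labeled repertoire
#'
#' Treats each record in turn as the query against the remaining records,
#' applying the hold-out filter, and returns the assembled predictions.
#' Score and identity matrices are computed once, so this is the efficient
#' path for benchmark curves.
#'
#' @param repertoire a labeled `tcr_repertoire`.
#' @inheritParams tcr_annotator
#' @param scores,identity optional precomputed matrices (from
#'   [score_matrix()] and [repertoire_identity_matrix()]) to reuse across
#'   thresholds.
#' @return a predictions data frame as in [predict.tcr_annotator()].
#' @export
loo_predict <- function(repertoire, model = "CDR(1:1:4-1:1:4)",
                        max_seqid = 99, structures = NULL,
                        kernel = blosum62_kernel_matrix(),
                        seqid = seqid_config(), rmsd_cap = 10,
                        scores = NULL, identity = NULL) {
  stopifnot(is.data.frame(repertoire), nrow(repertoire) >= 2L)
  if (is.null(scores))
    scores <- score_matrix(repertoire, repertoire, model, kernel = kernel,
                           seqid = seqid, structures_query = structures,
                           rmsd_cap = rmsd_cap)
  allowed <- matrix(TRUE, nrow(repertoire), nrow(repertoire))
  if (max_seqid < 100) {
    if (is.null(identity))
      identity <- repertoire_identity_matrix(repertoire, seqid)
    allowed <- identity <= max_seqid
  }
  diag(allowed) <- FALSE
  assemble_predictions(repertoire, repertoire, scores, allowed)
}
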