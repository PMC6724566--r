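#' Adjusted Rand Index between two labelings
#'
#' Chance-corrected agreement between the partition induced by the true
#' labels and the one induced by the predictions, computed from the
#' pair-counting contingency table (Hubert-Arabie form):
#' `ARI = (sum_ij C(n_ij,2) - E) / (0.5 [sum_i C(a_i,2) + sum_j C(b_j,2)] - E)`
#' with `E = sum_i C(a_i,2) sum_j C(b_j,2) / C(n,2)`. Perfect agreement
#' gives 1, random labelings give values near 0. When both partitions are
#' trivial and identical (denominator 0) the value is 1 by convention.
#'
#' @param true,predicted equal-length non-empty label vectors.
#' @return a single number in `[-1, 1]`.
#' @examples
#' adjusted_rand_index(c("a", "a", "b", "b"), c("x", "x", "y", "y"))  # 1
#' @export
adjusted_rand_index <- function(true, predicted) {
  if (length(true) != length(predicted))
    stop("label vectors must have equal length", call. = FALSE)
  if (!length(true))
    stop("label vectors must be non-empty", call. = FALSE)
  if (anyNA(true) || anyNA(predicted))
    stop("labels must not contain NA", call. = FALSE)
  n <- length(true)
  if (n < 2) {
    message("degenerate partitions (denominator 0); ARI = 1 by convention")
    return(1)
  }
  tab <- table(true, predicted)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  expected <- sum_a * sum_b / total
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) {
    message("degenerate partitions (denominator 0); ARI = 1 by convention")
    return(1)
  }
  (sum_ij - expected) / denom
}

#' Score predictions against the truth
#'
#' Builds the confusion matrix, accuracy, Adjusted Rand Index and a
#' bootstrap percentile interval for the ARI by resampling the final
#' `(true, predicted)` outcome pairs with replacement. Abstentions
#' (`NA` predictions) are excluded from the confusion matrix and the ARI
#' and reported separately; `strict = TRUE` additionally counts them as
#' errors in the accuracy.
#'
#' @param true character vector of true labels.
#' @param predicted character vector of predicted labels, `NA` marking
#'   abstentions.
#' @param n_boot number of bootstrap iterations (default 1000).
#' @param seed optional integer seed for the bootstrap resampling; recorded
#'   in the report. The global RNG state is restored afterwards.
#' @param strict count abstentions as errors in the accuracy.
#' @return an object of class `"tcr_evaluation"`: a list with `confusion`,
#'   `accuracy`, `ari`, `boot` (`n_boot`, `point`, `lower`, `upper`),
#'   `n_predictions`, `n_abstained`, `seed`.
#' @export
evaluate_predictions <- function(true, predicted, n_boot = 1000,
                                 seed = NULL, strict = FALSE) {
  if (length(true) != length(predicted))
    stop("label vectors must have equal length", call. = FALSE)
  if (anyNA(true))
    stop("every prediction needs a truth label", call. = FALSE)
  if (n_boot < 1) stop("n_boot must be at least 1", call. = FALSE)
  used <- !is.na(predicted)
  if (!any(used))
    stop("no usable predictions (all abstained)", call. = FALSE)
  t_u <- true[used]
  p_u <- predicted[used]
  confusion <- table(true = t_u, predicted = p_u)
  correct <- sum(t_u == p_u)
  accuracy <- if (strict) correct / length(true) else correct / length(t_u)
  ari <- adjusted_rand_index(t_u, p_u)
  boot_vals <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(t_u), replace = TRUE)
      suppressMessages(adjusted_rand_index(t_u[idx], p_u[idx]))
    }, numeric(1))
  })
  qs <- quantile(boot_vals, c(0.025, 0.975), names = FALSE, type = 7)
  structure(list(confusion = confusion, accuracy = accuracy, ari = ari,
                 boot = list(n_boot = n_boot, point = ari,
                             lower = qs[1], upper = qs[2]),
                 n_predictions = length(t_u),
                 n_abstained = sum(!used),
                 seed = seed),
            class = "tcr_evaluation")
}

# Run `expr` under a temporary seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.tcr_evaluation <- function(x, ...) {
  cat("TCR prediction evaluation\n")
  cat(sprintf("  predictions: %d (+%d abstained)\n", x$n_predictions,
              x$n_abstained))
  cat(sprintf("  accuracy: %.3f\n", x$accuracy))
  cat(sprintf("  ARI: %.3f  [%.3f, %.3f] (bootstrap, %d iterations)\n",
              x$ari, x$boot$lower, x$boot$upper, x$boot$n_boot))
  invisible(x)
}

#' Hold-out benchmark curve
#'
#' Leave-one-out evaluation of a similarity model over a grid of maximum
#' sequence identity thresholds: for each threshold, every record is
#' predicted from the remaining records after the hold-out filter, and the
#' outcome is scored with [evaluate_predictions()]. Score and identity
#' matrices are computed once and reused across thresholds.
#'
#' @param repertoire a labeled `tcr_repertoire` with full-length chains.
#' @param model a [similarity_model()] or specification string.
#' @param thresholds identity cutoffs in percent (default `70:99`).
#' @param n_boot bootstrap iterations per threshold.
#' @param structures named `tcr_structure` list for structure-based models.
#' @param kernel,seqid,rmsd_cap passed to [score_matrix()].
#' @param seed optional integer seed for the bootstrap.
#' @param granularity `"pmhc"` scores the full (peptide, MHC) label,
#'   `"peptide"` the peptide only (for single-allele benchmarks).
#' @return a data frame with one row per threshold: `threshold`, `n`,
#'   `n_abstained`, `accuracy`, `ari`, `ari_lower`, `ari_upper`.
#' @export
benchmark_curve <- function(repertoire, model, thresholds = 70:99,
                            n_boot = 1000, structures = NULL,
                            kernel = blosum62_kernel_matrix(),
                            seqid = seqid_config(), rmsd_cap = 10,
                            seed = NULL,
                            granularity = c("pmhc", "peptide")) {
  granularity <- match.arg(granularity)
  if (any(thresholds <= 0 | thresholds > 100))
    stop("thresholds must lie in (0, 100]", call. = FALSE)
  truth <- tcr_labels(repertoire, granularity)
  if (anyNA(truth))
    stop("all records must carry a pMHC label", call. = FALSE)
  scores <- score_matrix(repertoire, repertoire, model, kernel = kernel,
                         seqid = seqid, structures_query = structures,
                         rmsd_cap = rmsd_cap)
  identity <- if (any(thresholds < 100))
    repertoire_identity_matrix(repertoire, seqid) else NULL
  rows <- lapply(thresholds, function(thr) {
    pred <- loo_predict(repertoire, model, max_seqid = thr,
                        scores = scores, identity = identity,
                        kernel = kernel, seqid = seqid)
    plab <- if (granularity == "pmhc")
      ifelse(is.na(pred$peptide), NA, paste(pred$peptide, pred$mhc,
                                            sep = "|"))
    else pred$peptide
    ev <- evaluate_predictions(truth, plab, n_boot = n_boot, seed = seed)
    data.frame(threshold = thr, n = ev$n_predictions,
               n_abstained = ev$n_abstained, accuracy = ev$accuracy,
               ari = ev$ari, ari_lower = ev$boot$lower,
               ari_upper = ev$boot$upper)
  })
  do.call(rbind, rows)
}
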