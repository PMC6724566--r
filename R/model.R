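#' Similarity models for TCR target inference
#'
#' Builds a scoring model from the field notation used to label benchmark
#' figures:
#'
#' * `"CDR(a1:a2:a3-b1:b2:b3)"` — weighted k-mer kernel similarity over the
#'   six CDR loops;
#' * `"SeqID(wa:wb)"` — weighted whole-chain percent identity;
#' * `"RMSD(a1:a2:a3-b1:b2:b3)"` — weighted mutual-nearest Ca loop RMSD;
#' * `"CDR+RMSD:W=x"` — the linear combination
#'   `W * [1 - CDR(1:1:4-1:1:4)] + (1 - W) * RMSD(1:1:1-1:1:1) / rmsd_scale`.
#'
#' All models are oriented as dissimilarities: lower scores mean more
#' similar TCRs, and every model scores a TCR against itself as 0 (the RMSD
#' model exactly, by rigid-motion invariance).
#'
#' @param spec a model specification string as above. Alternatively supply
#'   `kind` and the relevant parameters directly.
#' @param kind one of `"cdr_kernel"`, `"seqid"`, `"rmsd"`, `"combined"`.
#' @param scheme loop weight scheme for `cdr_kernel` / `rmsd`.
#' @param chain_weights chain weight pair for `seqid`.
#' @param W combination weight in `[0, 1]` for `combined`.
#' @param cdr_scheme,rmsd_scheme loop schemes used inside the combined
#'   model (defaults `(1:1:4-1:1:4)` and flat, respectively).
#' @param rmsd_scale positive divisor normalizing the RMSD term of the
#'   combined model (default 5.0 Angstrom).
#' @return an object of class `"similarity_model"`.
#' @examples
#' similarity_model("CDR(1:1:4-1:1:4)")
#' similarity_model("CDR+RMSD:W=0.9")
#' @export
similarity_model <- function(spec = NULL, kind = NULL, scheme = NULL,
                             chain_weights = c(1, 1), W = 0.9,
                             cdr_scheme = "(1:1:4-1:1:4)",
                             rmsd_scheme = "(1:1:1-1:1:1)",
                             rmsd_scale = 5.0) {
  if (!is.null(spec)) {
    stopifnot(is.character(spec), length(spec) == 1L)
    s <- trimws(spec)
    if (grepl("^CDR\\+RMSD", s)) {
      m <- regmatches(s, regexec("^CDR\\+RMSD:W=([0-9.eE+-]+)$", s))[[1]]
      if (length(m) != 2L)
        stop("cannot parse model spec ", sQuote(spec),
             "; accepted grammar: CDR(a:b:c-d:e:f), SeqID(a:b), ",
             "RMSD(a:b:c-d:e:f), CDR+RMSD:W=x", call. = FALSE)
      kind <- "combined"
      W <- as.numeric(m[2])
    } else if (grepl("^CDR\\(", s)) {
      kind <- "cdr_kernel"
      scheme <- sub("^CDR", "", s)
    } else if (grepl("^RMSD\\(", s)) {
      kind <- "rmsd"
      scheme <- sub("^RMSD", "", s)
    } else if (grepl("^SeqID\\(", s)) {
      kind <- "seqid"
      chain_weights <- parse_chain_weights(sub("^SeqID", "", s))
    } else {
      stop("cannot parse model spec ", sQuote(spec),
           "; accepted grammar: CDR(a:b:c-d:e:f), SeqID(a:b), ",
           "RMSD(a:b:c-d:e:f), CDR+RMSD:W=x", call. = FALSE)
    }
  }
  kind <- match.arg(kind, c("cdr_kernel", "seqid", "rmsd", "combined"))
  if (kind %in% c("cdr_kernel", "rmsd")) {
    if (is.null(scheme))
      scheme <- if (kind == "rmsd") "(1:1:1-1:1:1)" else "(1:1:4-1:1:4)"
    scheme <- as_weight_scheme(scheme)
  }
  if (kind == "seqid") {
    if (is.character(chain_weights))
      chain_weights <- parse_chain_weights(chain_weights)
    stopifnot(length(chain_weights) == 2L, any(chain_weights > 0))
  }
  if (kind == "combined") {
    if (!is.numeric(W) || length(W) != 1L || is.na(W) || W < 0 || W > 1)
      stop("combination weight W must lie in [0, 1]", call. = FALSE)
    if (rmsd_scale <= 0)
      stop("rmsd_scale must be positive", call. = FALSE)
  }
  structure(list(kind = kind,
                 scheme = if (kind %in% c("cdr_kernel", "rmsd")) scheme,
                 chain_weights = if (kind == "seqid")
                   setNames(as.numeric(chain_weights), c("alpha", "beta")),
                 W = if (kind == "combined") W,
                 cdr_scheme = if (kind == "combined")
                   as_weight_scheme(cdr_scheme),
                 rmsd_scheme = if (kind == "combined")
                   as_weight_scheme(rmsd_scheme),
                 rmsd_scale = rmsd_scale),
            class = "similarity_model")
}

#' @export
format.similarity_model <- function(x, ...) {
  switch(x$kind,
         cdr_kernel = paste0("CDR", format(x$scheme)),
         rmsd = paste0("RMSD", format(x$scheme)),
         seqid = sprintf("SeqID(%g:%g)", x$chain_weights[1],
                         x$chain_weights[2]),
         combined = sprintf("CDR+RMSD:W=%g", x$W))
}

#' @export
print.similarity_model <- function(x, ...) {
  cat("TCR similarity model", format(x), "\n")
  if (x$kind == "combined")
    cat(sprintf("  sequence term %s, structure term %s / %g\n",
                paste0("CDR", format(x$cdr_scheme)),
                paste0("RMSD", format(x$rmsd_scheme)), x$rmsd_scale))
  invisible(x)
}

as_similarity_model <- function(x) {
  if (inherits(x, "similarity_model")) return(x)
  similarity_model(spec = x)
}

LOOP_COLUMNS <- c(a1 = "cdr1a", a2 = "cdr2a", a3 = "cdr3a",
                  b1 = "cdr1b", b2 = "cdr2b", b3 = "cdr3b")

# Weighted kernel similarity matrix over the loops with positive weight.
weighted_cdr_similarity <- function(query, db, scheme, kernel) {
  w <- unclass(scheme) / sum(scheme)
  sim <- matrix(0, nrow(query), nrow(db))
  for (i in seq_along(LOOP_COLUMNS)) {
    if (w[i] == 0) next
    col <- LOOP_COLUMNS[i]
    qs <- query[[col]]; ds <- db[[col]]
    if (is.null(qs) || anyNA(qs) || is.null(ds) || anyNA(ds))
      stop("model requires loop ", sQuote(col),
           " but it is missing for some records", call. = FALSE)
    sim <- sim + w[i] * cdr_similarity_matrix(qs, ds, kernel)
  }
  sim
}

# Cross (query x db) weighted chain identity matrix.
cross_identity_matrix <- function(query, db, config) {
  w <- config$chain_weights / sum(config$chain_weights)
  out <- matrix(0, nrow(query), nrow(db))
  for (chain in names(w)[w > 0]) {
    col <- if (chain == "alpha") "alpha_seq" else "beta_seq"
    qs <- query[[col]]; ds <- db[[col]]
    if (is.null(qs) || anyNA(qs) || any(!nzchar(qs)) ||
        is.null(ds) || anyNA(ds) || any(!nzchar(ds)))
      stop("chain identity requires full-length ", chain,
           " chains on both sides", call. = FALSE)
    uq <- unique(qs); ud <- unique(ds)
    um <- matrix(NA_real_, length(uq), length(ud))
    for (j in seq_along(ud))
      um[, j] <- chain_identity(uq, ud[j], config)
    out <- out + w[[chain]] * um[match(qs, uq), match(ds, ud), drop = FALSE]
  }
  out
}

# Structures for records, keyed by structure_id (falling back to id).
structures_for <- function(records, structures) {
  if (is.null(structures))
    stop("this model requires structural models, but none were supplied",
         call. = FALSE)
  key <- records$structure_id
  if (is.null(key) || all(is.na(key))) key <- records$id
  key <- ifelse(is.na(key), records$id, key)
  missing <- setdiff(key, names(structures))
  if (length(missing))
    stop("no structural model for record(s): ",
         paste(sQuote(utils::head(missing, 3)), collapse = ", "),
         if (length(missing) > 3) ", ...", call. = FALSE)
  structures[key]
}

#' Dissimilarity matrix between query and database TCRs
#'
#' Scores every query against every database entry under a similarity
#' model. All model kinds return dissimilarities (lower = more similar):
#' `1 - weighted CDR kernel similarity`, `1 - SeqID / 100`, the weighted
#' mean loop RMSD, or the combined sequence + structure score.
#'
#' @param query,db `tcr_repertoire` data frames.
#' @param model a [similarity_model()] or specification string.
#' @param kernel residue matrix from [blosum62_kernel_matrix()].
#' @param seqid a [seqid_config()] (for `SeqID` models).
#' @param structures_query,structures_db named `tcr_structure` lists for
#'   structure-based models (`structures_db` defaults to
#'   `structures_query`).
#' @param rmsd_cap cap for undefined loop RMSDs, in Angstrom.
#' @return a `nrow(query)` x `nrow(db)` matrix of non-negative scores with
#'   record ids as dimnames.
#' @export
score_matrix <- function(query, db, model, kernel = blosum62_kernel_matrix(),
                         seqid = seqid_config(),
                         structures_query = NULL,
                         structures_db = structures_query,
                         rmsd_cap = 10) {
  model <- as_similarity_model(model)
  out <- switch(
    model$kind,
    cdr_kernel = 1 - weighted_cdr_similarity(query, db, model$scheme, kernel),
    seqid = {
      cfg <- seqid
      cfg$chain_weights <- model$chain_weights
      1 - cross_identity_matrix(query, db, cfg) / 100
    },
    rmsd = structural_dissimilarity_matrix(
      structures_for(query, structures_query),
      structures_for(db, structures_db),
      scheme = model$scheme, cap = rmsd_cap),
    combined = {
      seq_term <- 1 - weighted_cdr_similarity(query, db, model$cdr_scheme,
                                              kernel)
      str_term <- structural_dissimilarity_matrix(
        structures_for(query, structures_query),
        structures_for(db, structures_db),
        scheme = model$rmsd_scheme, cap = rmsd_cap)
      model$W * seq_term + (1 - model$W) * str_term / model$rmsd_scale
    })
  # clamp tiny negative values from floating-point normalization
  out[out < 0 & out > -1e-12] <- 0
  dimnames(out) <- list(query$id, db$id)
  out
}

#' Dissimilarity between one query and one database TCR
#'
#' @param query,entry single-row `tcr_repertoire` data frames.
#' @inheritParams score_matrix
#' @param structures named `tcr_structure` list covering both records (for
#'   structure-based models).
#' @return a single non-negative score.
#' @export
score_pair <- function(query, entry, model,
                       kernel = blosum62_kernel_matrix(),
                       seqid = seqid_config(), structures = NULL,
                       rmsd_cap = 10) {
  stopifnot(nrow(query) == 1L, nrow(entry) == 1L)
  as.numeric(score_matrix(query, entry, model, kernel = kernel,
                          seqid = seqid,
                          structures_query = structures,
                          structures_db = structures,
                          rmsd_cap = rmsd_cap))
}
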