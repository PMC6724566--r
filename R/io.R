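#' Column mapping presets for repertoire tables
#'
#' A repertoire table is tab-separated with a header row; the column map
#' names the file columns holding the required fields (CDR3 of each chain
#' and the four V/J gene names, plus the pMHC label) and any optional
#' fields (record id, CDR1/CDR2 loops, full-length chains). VDJdb releases
#' vary in their column names, so the mapping is configuration, with the
#' fixture dialect as default.
#'
#' @param ... named overrides, e.g. `cdr3a = "cdr3.alpha"`.
#' @return named character vector mapping internal field names to file
#'   column names.
#' @export
repertoire_columns <- function(...) {
  map <- c(id = "id",
           cdr3a = "cdr3a", va = "va", ja = "ja",
           cdr3b = "cdr3b", vb = "vb", jb = "jb",
           epitope = "epitope", mhc = "mhc",
           cdr1a = "cdr1a", cdr2a = "cdr2a",
           cdr1b = "cdr1b", cdr2b = "cdr2b",
           alpha_seq = "alpha_seq", beta_seq = "beta_seq",
           structure_id = "structure_id")
  over <- c(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(map))
    if (length(unknown))
      stop("unknown repertoire fields: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    map[names(over)] <- over
  }
  map
}

#' @rdname repertoire_columns
#' @export
vdjdb_columns <- function(...) {
  repertoire_columns(id = "complex.id",
                     cdr3a = "cdr3.alpha", va = "v.alpha", ja = "j.alpha",
                     cdr3b = "cdr3.beta", vb = "v.beta", jb = "j.beta",
                     epitope = "antigen.epitope", mhc = "mhc.a", ...)
}

REQUIRED_FIELDS <- c("cdr3a", "va", "ja", "cdr3b", "vb", "jb")
OPTIONAL_SEQ_FIELDS <- c("cdr1a", "cdr2a", "cdr1b", "cdr2b",
                         "alpha_seq", "beta_seq")

#' Read a paired-chain TCR repertoire table
#'
#' Reads a tab-separated repertoire table into a `tcr_repertoire` data
#' frame: one row per TCR with the six CDR loops (CDR1/CDR2 may be absent
#' until derived from germline V genes), V/J gene names, optional
#' full-length chains and the pMHC label (peptide + MHC allele). Only rows
#' with both CDR3 loops and all four gene annotations are kept; rows
#' failing this, or containing characters outside the 20-letter amino-acid
#' alphabet in a sequence field (e.g. `*` or `.`), are skipped and counted.
#' Sequences are uppercased on read.
#'
#' @param path path to the TSV file.
#' @param column_map a mapping from [repertoire_columns()] or
#'   [vdjdb_columns()].
#' @param quiet suppress the per-stage message.
#' @return a `tcr_repertoire` data frame in file row order with columns
#'   `id, cdr1a, cdr2a, cdr3a, cdr1b, cdr2b, cdr3b, va, ja, vb, jb,
#'   alpha_seq, beta_seq, epitope, mhc, structure_id` and attribute
#'   `n_skipped`.
#' @export
read_repertoire <- function(path, column_map = repertoire_columns(),
                            quiet = FALSE) {
  if (!file.exists(path))
    stop("repertoire file not found: ", sQuote(path), call. = FALSE)
  raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", na.strings = c("NA", ""))
  mapped_present <- intersect(names(column_map),
                              c("id", REQUIRED_FIELDS, "epitope", "mhc",
                                OPTIONAL_SEQ_FIELDS, "structure_id"))
  # required + label columns must exist; optional ones only if present
  must_have <- column_map[c(REQUIRED_FIELDS, "epitope", "mhc")]
  missing_cols <- setdiff(must_have, names(raw))
  if (length(missing_cols))
    stop("repertoire header lacks mapped column(s): ",
         paste(sQuote(missing_cols), collapse = ", "), call. = FALSE)
  get_col <- function(field) {
    col <- column_map[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else
      rep(NA_character_, nrow(raw))
  }
  rep_df <- data.frame(
    id = get_col("id"),
    cdr1a = toupper(get_col("cdr1a")), cdr2a = toupper(get_col("cdr2a")),
    cdr3a = toupper(get_col("cdr3a")),
    cdr1b = toupper(get_col("cdr1b")), cdr2b = toupper(get_col("cdr2b")),
    cdr3b = toupper(get_col("cdr3b")),
    va = get_col("va"), ja = get_col("ja"),
    vb = get_col("vb"), jb = get_col("jb"),
    alpha_seq = toupper(get_col("alpha_seq")),
    beta_seq = toupper(get_col("beta_seq")),
    epitope = toupper(get_col("epitope")), mhc = get_col("mhc"),
    structure_id = get_col("structure_id"),
    stringsAsFactors = FALSE)
  if (all(is.na(rep_df$id)))
    rep_df$id <- sprintf("tcr%04d", seq_len(nrow(rep_df)))

  ok <- is_standard_aa(rep_df$cdr3a) & is_standard_aa(rep_df$cdr3b) &
    !is.na(rep_df$va) & nzchar(rep_df$va) & !is.na(rep_df$ja) & nzchar(rep_df$ja) &
    !is.na(rep_df$vb) & nzchar(rep_df$vb) & !is.na(rep_df$jb) & nzchar(rep_df$jb)
  # optional sequence fields, when present, must also be clean
  for (field in OPTIONAL_SEQ_FIELDS) {
    v <- rep_df[[field]]
    ok <- ok & (is.na(v) | is_standard_aa(v))
  }
  n_skipped <- sum(!ok)
  rep_df <- rep_df[ok, , drop = FALSE]
  rownames(rep_df) <- NULL
  if (anyDuplicated(rep_df$id))
    stop("duplicate record ids in repertoire", call. = FALSE)
  if (!quiet)
    message(sprintf("read_repertoire: %d record(s) kept, %d skipped",
                    nrow(rep_df), n_skipped))
  as_tcr_repertoire(rep_df, n_skipped = n_skipped)
}

as_tcr_repertoire <- function(df, n_skipped = 0L) {
  structure(df, n_skipped = n_skipped,
            class = c("tcr_repertoire", "data.frame"))
}

#' Write a repertoire table
#'
#' Writes a `tcr_repertoire` back to the tab-separated fixture dialect so
#' that reading and writing round-trip.
#'
#' @param repertoire a `tcr_repertoire`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_repertoire <- function(repertoire, path) {
  stopifnot(is.data.frame(repertoire))
  write.table(as.data.frame(repertoire), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf("TCR repertoire: %d paired-chain record(s)", nrow(x)))
  if (!is.null(attr(x, "n_skipped")) && attr(x, "n_skipped") > 0)
    cat(sprintf(" (%d skipped on read)", attr(x, "n_skipped")))
  cat("\n")
  lab <- tcr_labels(x)
  if (!all(is.na(lab)))
    cat(sprintf("pMHC labels: %d distinct\n", length(unique(lab[!is.na(lab)]))))
  NextMethod()
}

# pMHC label strings "peptide|allele"; NA when either field is missing.
tcr_labels <- function(repertoire, granularity = c("pmhc", "peptide")) {
  granularity <- match.arg(granularity)
  pep <- repertoire$epitope
  mhc <- repertoire$mhc
  if (granularity == "peptide") return(ifelse(is.na(pep), NA, pep))
  ifelse(is.na(pep) | is.na(mhc), NA, paste(pep, mhc, sep = "|"))
}

#' Read germline V/J amino-acid sequences from FASTA
#'
#' @param path FASTA file of germline segment amino-acid sequences; record
#'   names are gene names.
#' @return named character vector of uppercased sequences.
#' @export
read_germline <- function(path) {
  if (!file.exists(path))
    stop("germline FASTA not found: ", sQuote(path), call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(seqs)))
    stop("duplicate gene names in germline FASTA", call. = FALSE)
  if (any(!nzchar(seqs)))
    stop("empty germline sequence in FASTA", call. = FALSE)
  seqs
}

#' Write a germline set to FASTA
#'
#' @param germline named character vector of sequences.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_germline <- function(germline, path) {
  set <- Biostrings::AAStringSet(germline)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
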