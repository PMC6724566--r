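#' Residue similarity matrix for the CDR string kernel
#'
#' Builds the 20 x 20 positive residue similarity matrix `B` underlying the
#' k-mer CDR kernel: `B(a, b) = r(a, b)^beta`, where `r(a, b)` is the
#' BLOSUM62 odds ratio `q(a, b) / (p(a) p(b))` between the target (aligned
#' pair) frequency and the background product. The ratio is recovered from
#' the canonical half-bit integer BLOSUM62 log-odds scores `s` shipped with
#' \pkg{Biostrings} as `r = 2^(s / 2)`, i.e. the published ratio at the
#' half-bit precision of the score matrix.
#'
#' The exponent `beta` flattens the matrix towards 1 and is chosen small
#' enough that `B` is positive semi-definite, which guarantees (by
#' Cauchy-Schwarz) that the normalized CDR similarity never exceeds 1.
#' Positive semi-definiteness is verified at build time.
#'
#' @param beta positive exponent applied elementwise to the odds ratio.
#'   Default `0.11387`.
#' @return an object of class `"aa_kernel_matrix"`: a symmetric 20 x 20
#'   numeric matrix with dimnames over the standard amino-acid alphabet and
#'   attributes `beta` and `provenance`.
#' @examples
#' B <- blosum62_kernel_matrix()
#' B["A", "A"]
#' @export
blosum62_kernel_matrix <- function(beta = 0.11387) {
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta <= 0)
    stop("`beta` must be a single positive number", call. = FALSE)
  scores <- get_blosum62_scores()
  B <- 2^(beta * scores / 2)
  ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-9)
    stop("kernel matrix is not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  structure(B,
            beta = beta,
            provenance = "BLOSUM62 odds ratio 2^(s/2) from Biostrings::BLOSUM62",
            class = c("aa_kernel_matrix", "matrix", "array"))
}

# BLOSUM62 integer scores over the 20 standard residues, AA_ALPHABET order.
get_blosum62_scores <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
}

#' @export
print.aa_kernel_matrix <- function(x, ...) {
  cat(sprintf("Residue kernel matrix (beta = %g)\n", attr(x, "beta")))
  cat(attr(x, "provenance"), "\n")
  print(round(unclass(x)[1:5, 1:5], 3))
  cat("... 20 x 20\n")
  invisible(x)
}

check_kernel_matrix <- function(B) {
  if (!inherits(B, "aa_kernel_matrix"))
    stop("`B` must be built with blosum62_kernel_matrix()", call. = FALSE)
  B
}

#' k-mer similarity score
#'
#' Similarity between two equal-length amino-acid words as the product of
#' per-position residue similarities: `K(u, v) = prod_i B(u_i, v_i)`.
#'
#' @param u,v amino-acid strings of equal length (k-mers).
#' @param B residue kernel matrix from [blosum62_kernel_matrix()].
#' @return a single positive number.
#' @examples
#' B <- blosum62_kernel_matrix()
#' kmer_score("ACD", "DCA", B)
#' @export
kmer_score <- function(u, v, B) {
  check_kernel_matrix(B)
  ui <- aa_encode(u)
  vi <- aa_encode(v)
  if (length(ui) != length(vi))
    stop("k-mer lengths differ (", length(ui), " vs ", length(vi), ")",
         call. = FALSE)
  prod(B[cbind(ui, vi)])
}

#' Raw CDR loop similarity (all-substrings kernel)
#'
#' Sum of [kmer_score()] over every pair of equal-length contiguous
#' substrings of the two loop sequences, for all lengths
#' `k = 1, ..., min(|f|, |g|)`. The default implementation uses the
#' `O(|f| |g|)` recurrence `M(i, j) = B(f_i, g_j) (1 + M(i+1, j+1))` with
#' `cdr(f, g) = sum_{i,j} M(i, j)`; `method = "brute_force"` enumerates all
#' substring pairs explicitly and is provided for auditing.
#'
#' @param f,g CDR loop amino-acid sequences (non-empty strings).
#' @param B residue kernel matrix from [blosum62_kernel_matrix()].
#' @param method `"dynamic_programming"` (default) or `"brute_force"`.
#' @return a single positive number.
#' @examples
#' B <- blosum62_kernel_matrix()
#' cdr_raw("CASSL", "CASSF", B)
#' @export
cdr_raw <- function(f, g, B, method = c("dynamic_programming", "brute_force")) {
  method <- match.arg(method)
  check_kernel_matrix(B)
  fi <- aa_encode(f)
  gi <- aa_encode(g)
  if (length(fi) == 0L || length(gi) == 0L)
    stop("loop sequences must be non-empty", call. = FALSE)
  if (method == "dynamic_programming") {
    cdr_raw_dp(fi, gi, unclass(B))
  } else {
    cdr_raw_brute(fi, gi, unclass(B))
  }
}

# Explicit enumeration of all equal-length contiguous substring pairs.
cdr_raw_brute <- function(fi, gi, B) {
  n <- length(fi); m <- length(gi)
  total <- 0
  for (k in seq_len(min(n, m))) {
    for (i in seq_len(n - k + 1L)) {
      for (j in seq_len(m - k + 1L)) {
        total <- total + prod(B[cbind(fi[i:(i + k - 1L)], gi[j:(j + k - 1L)])])
      }
    }
  }
  total
}

#' Normalized CDR loop similarity
#'
#' The CDR sequence similarity
#' `CDR(f, g) = cdr(f, g) / sqrt(cdr(f, f) cdr(g, g))`, a number in
#' `(0, 1]`: symmetric, equal to 1 exactly when `f == g`, and bounded by 1
#' because the residue matrix is positive semi-definite.
#'
#' @inheritParams cdr_raw
#' @return a single number in `(0, 1]`.
#' @examples
#' B <- blosum62_kernel_matrix()
#' cdr_similarity("CASSLGETQYF", "CASSLGDTQYF", B)
#' @export
cdr_similarity <- function(f, g, B, method = c("dynamic_programming", "brute_force")) {
  method <- match.arg(method)
  cdr_raw(f, g, B, method) /
    sqrt(cdr_raw(f, f, B, method) * cdr_raw(g, g, B, method))
}

#' Pairwise normalized CDR similarity matrix
#'
#' Computes [cdr_similarity()] for every pair between two sets of loop
#' sequences. Duplicate sequences are collapsed before computation, so
#' repertoires with shared germline loops are handled efficiently.
#'
#' @param x,y character vectors of loop sequences (`y` defaults to `x`).
#' @param B residue kernel matrix from [blosum62_kernel_matrix()].
#' @return a `length(x)` x `length(y)` numeric matrix of similarities in
#'   `(0, 1]`.
#' @export
cdr_similarity_matrix <- function(x, y = x, B = blosum62_kernel_matrix()) {
  check_kernel_matrix(B)
  stopifnot(is.character(x), is.character(y), length(x) > 0, length(y) > 0)
  ux <- unique(x); uy <- unique(y)
  ex <- lapply(ux, aa_encode)
  ey <- lapply(uy, aa_encode)
  self_x <- vapply(ex, function(e) cdr_raw_dp(e, e, unclass(B)), numeric(1))
  self_y <- vapply(ey, function(e) cdr_raw_dp(e, e, unclass(B)), numeric(1))
  cross <- cdr_raw_cross_dp(ex, ey, unclass(B))
  sim <- cross / sqrt(outer(self_x, self_y))
  sim[match(x, ux), match(y, uy), drop = FALSE]
}
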