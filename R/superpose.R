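#' Simultaneous rigid-body superposition of two TCR models
#'
#' Superposes structure `b` onto structure `a` with a single least-squares
#' rigid-body transform (Kabsch) computed over the alpha carbons of all six
#' CDR loops simultaneously. Atom pairs are matched by identical
#' `(chain, loop, residue number, insertion code)` keys; incomplete loops
#' are excluded from the matching set with a warning. One global transform
#' is used per structure pair; no per-loop re-fitting.
#'
#' @param a,b `tcr_structure` objects (see [read_tcr_structures()]).
#' @param match `"resno"` (default) matches by residue-number keys;
#'   `"index"` matches by position from the loop start, truncated to the
#'   shorter loop.
#' @return a list of class `"tcr_superposition"` with elements `rotation`
#'   (3 x 3 proper rotation), `translation` (length-3), `n_matched`,
#'   `fit_rmsd` (RMSD over the matched fitting atoms) and `structure` (a
#'   copy of `b` with transformed coordinates).
#' @export
superpose_tcr <- function(a, b, match = c("resno", "index")) {
  match <- match.arg(match)
  stopifnot(inherits(a, "tcr_structure"), inherits(b, "tcr_structure"))
  xa <- NULL; xb <- NULL
  for (id in LOOP_IDS) {
    la <- a$loops[[id]]; lb <- b$loops[[id]]
    if (is.null(la) || is.null(lb)) next
    if (isTRUE(la$incomplete) || isTRUE(lb$incomplete)) {
      warning("loop ", id, " incomplete; excluded from superposition",
              call. = FALSE)
      next
    }
    if (match == "resno") {
      ka <- paste(la$resno, la$ins)
      kb <- paste(lb$resno, lb$ins)
      common <- intersect(ka, kb)
      ia <- match(common, ka); ib <- match(common, kb)
    } else {
      n <- min(nrow(la$xyz), nrow(lb$xyz))
      ia <- seq_len(n); ib <- seq_len(n)
    }
    if (length(ia)) {
      xa <- rbind(xa, la$xyz[ia, , drop = FALSE])
      xb <- rbind(xb, lb$xyz[ib, , drop = FALSE])
    }
  }
  if (is.null(xa) || nrow(xa) < 3L)
    stop("fewer than 3 matchable Ca pairs between ", sQuote(a$structure_id),
         " and ", sQuote(b$structure_id), call. = FALSE)
  fit <- kabsch(xa, xb)
  out <- b
  out$loops <- lapply(b$loops, function(l) {
    if (nrow(l$xyz))
      l$xyz <- sweep(l$xyz %*% t(fit$rotation), 2, fit$translation, `+`)
    l
  })
  structure(list(rotation = fit$rotation, translation = fit$translation,
                 n_matched = nrow(xa), fit_rmsd = fit$rmsd,
                 structure = out),
            class = "tcr_superposition")
}

# Least-squares rigid transform mapping y onto x: x ~ y %*% t(R) + t.
# SVD solution with determinant correction so R is a proper rotation.
kabsch <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  x0 <- sweep(x, 2, cx); y0 <- sweep(y, 2, cy)
  s <- svd(crossprod(y0, x0))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cx - as.numeric(R %*% cy)
  fitted <- sweep(y %*% t(R), 2, t, `+`)
  list(rotation = R, translation = t,
       rmsd = sqrt(mean(rowSums((fitted - x)^2))))
}

#' Mutual-nearest alpha-carbon RMSD between two CDR loops
#'
#' For each Ca of `loop_a` the nearest Ca of `loop_b` is located, and then
#' the nearest Ca of `loop_a` to that atom; only if this returns the
#' starting atom (a mutual nearest pair) does the pair contribute its
#' squared distance. The result is `sqrt(sum d^2 / N)` over the `N` mutual
#' pairs, or `NA` when no mutual pair exists. Coordinates must already be
#' in a common frame (see [superpose_tcr()]); no transform is applied here.
#' Distance ties resolve to the lowest residue-number atom.
#'
#' @param loop_a,loop_b `loop_structure` objects with at least one atom.
#' @return a single non-negative RMSD in Angstrom, with attribute `n` (the
#'   mutual pair count), or `NA` with `n = 0`.
#' @export
loop_rmsd <- function(loop_a, loop_b) {
  if (!nrow(loop_a$xyz) || !nrow(loop_b$xyz))
    stop("loop_rmsd requires non-empty loops", call. = FALSE)
  res <- mutual_nn_rmsd(loop_a$xyz, loop_b$xyz)
  structure(if (res[2] > 0) res[1] else NA_real_, n = as.integer(res[2]))
}

#' Weighted structural dissimilarity between two TCR models
#'
#' Superposes `b` onto `a` over all six CDR loops simultaneously, computes
#' the per-loop mutual-nearest Ca RMSD, and returns their weighted
#' arithmetic mean (weights normalized to sum 1). Lower values mean more
#' similar structures; two copies of the same model score 0. A loop with
#' no mutual pairs, or missing/incomplete on either side, is assigned the
#' cap value (with a warning) so the combined score stays finite.
#'
#' @param a,b `tcr_structure` objects.
#' @param scheme loop weights: a `"(a1:a2:a3-b1:b2:b3)"` string, a
#'   [parse_weight_scheme()] result, or a numeric length 6. Default flat.
#' @param cap RMSD ceiling (Angstrom) substituted for undefined loops.
#' @param match passed to [superpose_tcr()].
#' @return a single non-negative number with attribute `loop_rmsd` (the six
#'   per-loop values).
#' @export
structural_dissimilarity <- function(a, b, scheme = "(1:1:1-1:1:1)",
                                     cap = 10, match = "resno") {
  w <- as_weight_scheme(scheme)
  w <- unclass(w) / sum(w)
  sup <- superpose_tcr(a, b, match = match)
  bt <- sup$structure
  rmsds <- setNames(numeric(6), LOOP_IDS)
  for (i in seq_along(LOOP_IDS)) {
    id <- LOOP_IDS[i]
    la <- a$loops[[id]]; lb <- bt$loops[[id]]
    if (is.null(la) || is.null(lb) || !nrow(la$xyz) || !nrow(lb$xyz)) {
      if (w[i] > 0)
        warning("loop ", id, " missing; capped at ", cap, " A",
                call. = FALSE)
      rmsds[i] <- cap
      next
    }
    r <- loop_rmsd(la, lb)
    if (is.na(r)) {
      warning("loop ", id, " has no mutual nearest pairs; capped at ",
              cap, " A", call. = FALSE)
      r <- cap
    }
    rmsds[i] <- min(as.numeric(r), cap)
  }
  structure(sum(w * rmsds), loop_rmsd = rmsds)
}

#' Pairwise structural dissimilarity matrix
#'
#' [structural_dissimilarity()] for every pair between two sets of TCR
#' structures.
#'
#' @param x,y named lists of `tcr_structure` objects (`y` defaults to `x`).
#' @inheritParams structural_dissimilarity
#' @return a `length(x)` x `length(y)` matrix with the structures' names as
#'   dimnames.
#' @export
structural_dissimilarity_matrix <- function(x, y = x,
                                            scheme = "(1:1:1-1:1:1)",
                                            cap = 10, match = "resno") {
  out <- matrix(NA_real_, length(x), length(y),
                dimnames = list(names(x), names(y)))
  symmetric <- identical(names(x), names(y)) && identical(x, y)
  for (i in seq_along(x)) {
    jseq <- if (symmetric) seq_len(i) else seq_along(y)
    for (j in jseq) {
      d <- as.numeric(structural_dissimilarity(x[[i]], y[[j]], scheme,
                                               cap = cap, match = match))
      out[i, j] <- d
      if (symmetric) out[j, i] <- d
    }
  }
  out
}
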