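#' CDR loop residue annotation preset
#'
#' Residue-number ranges locating the six CDR loops in a TCR structural
#' model. The default preset mimics an IMGT-like numbering (CDR1 27-38,
#' CDR2 56-65, CDR3 105-130 on each chain, alpha chain `A`, beta chain
#' `B`); structural model providers use their own numbering scheme, which
#' is not standardized, so the ranges are configuration rather than
#' constants.
#'
#' @param alpha_chain,beta_chain PDB chain identifiers.
#' @param cdr1,cdr2,cdr3 integer length-2 `(first, last)` residue-number
#'   ranges, applied to both chains.
#' @return an object of class `"loop_annotation"`.
#' @export
loop_annotation <- function(alpha_chain = "A", beta_chain = "B",
                            cdr1 = c(27L, 38L), cdr2 = c(56L, 65L),
                            cdr3 = c(105L, 130L)) {
  ranges <- list(cdr1 = as.integer(cdr1), cdr2 = as.integer(cdr2),
                 cdr3 = as.integer(cdr3))
  for (r in ranges)
    if (length(r) != 2L || anyNA(r) || r[1] > r[2])
      stop("loop ranges must be increasing (first, last) pairs", call. = FALSE)
  structure(list(chains = c(alpha = alpha_chain, beta = beta_chain),
                 ranges = ranges),
            class = "loop_annotation")
}

LOOP_IDS <- c("a1", "a2", "a3", "b1", "b2", "b3")

new_loop_structure <- function(chain, index, resno, ins, xyz,
                               incomplete = FALSE) {
  stopifnot(nrow(xyz) == length(resno), length(ins) == length(resno))
  structure(list(chain = chain, index = as.integer(index),
                 resno = as.integer(resno), ins = ins,
                 xyz = xyz, incomplete = incomplete),
            class = "loop_structure")
}

new_tcr_structure <- function(structure_id, loops) {
  incomplete <- vapply(loops, function(l) isTRUE(l$incomplete), logical(1))
  structure(list(structure_id = structure_id, loops = loops,
                 incomplete = any(incomplete)),
            class = "tcr_structure")
}

#' @export
print.tcr_structure <- function(x, ...) {
  cat(sprintf("TCR structure %s%s\n", sQuote(x$structure_id),
              if (x$incomplete) " [incomplete]" else ""))
  for (id in names(x$loops)) {
    l <- x$loops[[id]]
    cat(sprintf("  %s chain %s: %d Ca%s\n", id, l$chain, nrow(l$xyz),
                if (isTRUE(l$incomplete)) " (incomplete)" else ""))
  }
  invisible(x)
}

#' Read TCR structural models from PDB files
#'
#' Extracts the alpha-carbon coordinates of the six annotated CDR loops
#' from each PDB file. Within each annotated residue range, only residues
#' with a Ca atom contribute (others are skipped); alternate locations are
#' resolved by highest occupancy, then lowest altloc identifier. A loop
#' whose range covers no Ca at all is flagged incomplete rather than
#' failing the file.
#'
#' @param paths character vector of PDB file paths.
#' @param annotation a [loop_annotation()].
#' @param ids structure identifiers; default the file base names without
#'   extension.
#' @return a named list of `tcr_structure` objects, each holding six
#'   `loop_structure` entries (`a1, a2, a3, b1, b2, b3`) with ordered
#'   residue numbers and Ca coordinates in Angstrom.
#' @export
read_tcr_structures <- function(paths, annotation = loop_annotation(),
                                ids = NULL) {
  stopifnot(inherits(annotation, "loop_annotation"))
  if (is.null(ids))
    ids <- sub("\\.pdb$", "", basename(paths), ignore.case = TRUE)
  stopifnot(length(ids) == length(paths), !anyDuplicated(ids))
  out <- vector("list", length(paths))
  names(out) <- ids
  for (i in seq_along(paths)) {
    if (!file.exists(paths[i]))
      stop("PDB file not found: ", sQuote(paths[i]), call. = FALSE)
    pdb <- bio3d::read.pdb(paths[i], rm.alt = FALSE, verbose = FALSE)
    atoms <- pdb$atom
    ca <- atoms[atoms$elety == "CA" & atoms$type == "ATOM", , drop = FALSE]
    ca <- resolve_altloc(ca)
    loops <- list()
    for (chain_name in c("alpha", "beta")) {
      chain_id <- annotation$chains[[chain_name]]
      for (k in 1:3) {
        rng <- annotation$ranges[[k]]
        sel <- ca[ca$chain == chain_id & ca$resno >= rng[1] &
                    ca$resno <= rng[2], , drop = FALSE]
        sel <- sel[order(sel$resno, sel$insert, na.last = FALSE), ,
                   drop = FALSE]
        loop_id <- paste0(substr(chain_name, 1, 1), k)
        if (nrow(sel) == 0L) {
          loops[[loop_id]] <- new_loop_structure(
            chain_id, k, integer(0), character(0),
            matrix(numeric(0), 0, 3), incomplete = TRUE)
        } else {
          xyz <- unname(as.matrix(sel[, c("x", "y", "z")]))
          if (!all(is.finite(xyz)))
            stop("non-finite coordinates in ", sQuote(paths[i]),
                 call. = FALSE)
          ins <- ifelse(is.na(sel$insert) | sel$insert == "?", "", sel$insert)
          loops[[loop_id]] <- new_loop_structure(chain_id, k, sel$resno,
                                                 ins, xyz)
        }
      }
    }
    out[[i]] <- new_tcr_structure(ids[i], loops[LOOP_IDS])
  }
  out
}

# Keep one atom per (chain, resno, insert): highest occupancy, ties by
# lowest altloc identifier.
resolve_altloc <- function(ca) {
  if (nrow(ca) <= 1L) return(ca)
  alt <- ifelse(is.na(ca$alt) | ca$alt == "?", "", ca$alt)
  occ <- ifelse(is.na(ca$o), 1, ca$o)
  key <- paste(ca$chain, ca$resno, ca$insert, sep = "\r")
  ord <- order(key, -occ, alt)
  ca <- ca[ord, , drop = FALSE]
  ca[!duplicated(key[ord]), , drop = FALSE]
}

#' Write TCR structural models to PDB files
#'
#' Writes the Ca trace of each structure's six CDR loops as a standard PDB
#' file (one file per structure, named `<structure_id>.pdb`).
#'
#' @param structures named list of `tcr_structure` objects.
#' @param dir output directory (created if needed).
#' @return character vector of file paths, invisibly.
#' @export
write_tcr_structures <- function(structures, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(structures))
  for (i in seq_along(structures)) {
    s <- structures[[i]]
    xyz <- do.call(rbind, lapply(s$loops, `[[`, "xyz"))
    resno <- unlist(lapply(s$loops, `[[`, "resno"), use.names = FALSE)
    chain <- unlist(lapply(s$loops, function(l) rep(l$chain, nrow(l$xyz))),
                    use.names = FALSE)
    paths[i] <- file.path(dir, paste0(s$structure_id, ".pdb"))
    bio3d::write.pdb(file = paths[i],
                     xyz = as.numeric(t(xyz)),
                     resno = resno, chain = chain,
                     resid = rep("GLY", length(resno)),
                     elety = rep("CA", length(resno)))
  }
  invisible(paths)
}
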