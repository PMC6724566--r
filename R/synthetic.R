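#' Configuration for the synthetic repertoire generator
#'
#' Defines the conditions of a synthetic, epitope-clustered benchmark: per
#' epitope, seed CDR loops embedded in germline-like V/J flanks are
#' diverged by independent per-residue substitutions, so that receptors
#' sharing a target share sequence (and, via [generate_structures()],
#' structural) features.
#'
#' @param n_epitopes number of distinct pMHC labels.
#' @param tcrs_per_epitope receptors per label (at least 2, so every label
#'   retains a same-target neighbor under leave-one-out).
#' @param n_v_genes size of the shared germline pool per segment type
#'   (V/J of each chain). Epitopes draw their genes from this common pool,
#'   as real repertoires share V genes across specificities, so germline
#'   context is shared between epitopes and only the CDR3 interior is
#'   epitope-private.
#' @param mutation_rate per-residue substitution probability `p` in
#'   `[0, 1)` applied to every residue outside the splice overlaps.
#' @param cdr3_length_range inclusive range of CDR3 lengths, drawn once
#'   per epitope and chain; minimum must exceed twice the overlap.
#' @param cdr1_length,cdr2_length germline CDR1/CDR2 loop lengths.
#' @param v_length,j_length germline V / J segment lengths (amino acids).
#' @param jitter_sd per-atom Gaussian structural noise sigma, Angstrom.
#' @param transform_magnitude maximum translation of the random rigid-body
#'   transform applied to each whole model, Angstrom.
#' @param ca_spacing consecutive alpha-carbon spacing along a loop arc,
#'   Angstrom (3.8 is the physical value).
#' @param blosum_substitutions draw substitutions proportional to
#'   BLOSUM62-conditional frequencies (default); `FALSE` for uniform.
#' @param overlap_length V/CDR3 and CDR3/J splice overlap (residues).
#' @param template_max_seqid documented modeling-protocol field: the
#'   template blacklist threshold (percent) that a homology-modeling step
#'   would apply so templates share no more than this identity with the
#'   target. The generator records it in its output attributes; it does
#'   not alter the geometry, which is synthetic.
#' @param seed mandatory integer seed.
#' @return an object of class `"synth_config"`.
#' @export
synth_config <- function(n_epitopes = 8, tcrs_per_epitope = 50,
                         mutation_rate = 0.02, n_v_genes = 4,
                         cdr3_length_range = c(10, 16),
                         cdr1_length = 6, cdr2_length = 6,
                         v_length = 60, j_length = 15,
                         jitter_sd = 0.3, transform_magnitude = 20,
                         ca_spacing = 3.8,
                         blosum_substitutions = TRUE,
                         overlap_length = 4,
                         template_max_seqid = 70,
                         seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` is mandatory", call. = FALSE)
  if (mutation_rate < 0 || mutation_rate >= 1)
    stop("mutation_rate must lie in [0, 1)", call. = FALSE)
  if (n_epitopes < 1 || tcrs_per_epitope < 2)
    stop("need at least 1 epitope and 2 TCRs per epitope", call. = FALSE)
  if (n_v_genes < 1)
    stop("n_v_genes must be at least 1", call. = FALSE)
  if (cdr3_length_range[1] < 2 * overlap_length + 1)
    stop("minimum CDR3 length must exceed twice the overlap length",
         call. = FALSE)
  if (cdr1_length < 3 || cdr2_length < 3 || cdr3_length_range[1] < 3)
    stop("loop lengths must be at least 3", call. = FALSE)
  if (v_length < 50 || j_length < overlap_length + 1)
    stop("v_length must be >= 50 and j_length longer than the overlap",
         call. = FALSE)
  if (jitter_sd < 0 || transform_magnitude < 0 || ca_spacing <= 0)
    stop("structural parameters must be non-negative (spacing positive)",
         call. = FALSE)
  structure(list(n_epitopes = as.integer(n_epitopes),
                 tcrs_per_epitope = as.integer(tcrs_per_epitope),
                 mutation_rate = mutation_rate,
                 n_v_genes = as.integer(n_v_genes),
                 cdr3_length_range = as.integer(cdr3_length_range),
                 cdr1_length = as.integer(cdr1_length),
                 cdr2_length = as.integer(cdr2_length),
                 v_length = as.integer(v_length),
                 j_length = as.integer(j_length),
                 jitter_sd = jitter_sd,
                 transform_magnitude = transform_magnitude,
                 ca_spacing = ca_spacing,
                 blosum_substitutions = blosum_substitutions,
                 overlap_length = as.integer(overlap_length),
                 template_max_seqid = template_max_seqid,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# CDR1/CDR2 positions within the V segment (1-based, inclusive start).
CDR1_V_START <- 25L
CDR2_V_START <- 40L

# P(b | a) substitution kernel: proportional to background frequency times
# the BLOSUM62 odds ratio (i.e. the aligned-pair target frequency), with
# the diagonal removed.
substitution_kernel <- function() {
  ratio <- 2^(get_blosum62_scores() / 2)
  cond <- ratio * rep(AA_BACKGROUND, each = 20)
  diag(cond) <- 0
  sweep(cond, 1, rowSums(cond), `/`)
}

random_aa <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE, prob = AA_BACKGROUND),
        collapse = "")
}

# Independent per-residue substitution at rate p.
mutate_seq <- function(seq, p, cond = NULL) {
  if (p == 0 || !nzchar(seq)) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < p)
  for (i in hit) {
    a <- match(chars[i], AA_ALPHABET)
    chars[i] <- if (is.null(cond))
      sample(AA_ALPHABET[-a], 1L)
    else
      sample(AA_ALPHABET, 1L, prob = cond[a, ])
  }
  paste(chars, collapse = "")
}

#' Generate a labeled synthetic repertoire
#'
#' Draws a shared pool of germline-like V/J segments per chain, assigns
#' each epitope a gene combination from that pool plus a seed CDR3
#' junction whose ends splice exactly onto its genes; each receptor is
#' then an independently mutated copy of the epitope's seed chains (every
#' residue substituted with probability `mutation_rate`, except the splice
#' overlaps, which stay intact so germline reconstruction remains
#' well-defined). CDR1/CDR2 loops are read out of each receptor's own
#' mutated V region, so all six loops and both full chains diverge at the
#' configured rate, while epitopes sharing a V gene share germline context
#' and are distinguished mainly by the CDR3 interior.
#'
#' @param config a [synth_config()]; the seed makes the output fully
#'   deterministic.
#' @return a list with `repertoire` (a labeled `tcr_repertoire` with six
#'   loops, gene names, full-length chains and `structure_id = id`) and
#'   `germline` (named character vector of V/J sequences).
#' @export
generate_repertoire <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  with_local_seed(cfg$seed, {
    cond <- if (cfg$blosum_substitutions) substitution_kernel() else NULL
    # shared germline pools; epitopes draw gene combinations from these
    pool <- list(
      a_v = setNames(replicate(cfg$n_v_genes, random_aa(cfg$v_length)),
                     sprintf("TRAV%d", seq_len(cfg$n_v_genes))),
      a_j = setNames(replicate(cfg$n_v_genes, random_aa(cfg$j_length)),
                     sprintf("TRAJ%d", seq_len(cfg$n_v_genes))),
      b_v = setNames(replicate(cfg$n_v_genes, random_aa(cfg$v_length)),
                     sprintf("TRBV%d", seq_len(cfg$n_v_genes))),
      b_j = setNames(replicate(cfg$n_v_genes, random_aa(cfg$j_length)),
                     sprintf("TRBJ%d", seq_len(cfg$n_v_genes))))
    germline <- unlist(unname(pool))
    rows <- vector("list", cfg$n_epitopes * cfg$tcrs_per_epitope)
    alleles <- c("H2-Db", "H2-Kb")
    row_i <- 0L
    for (e in seq_len(cfg$n_epitopes)) {
      pick <- lapply(pool, function(g) sample(names(g), 1L))
      v <- list(a = pool$a_v[[pick$a_v]], b = pool$b_v[[pick$b_v]])
      j <- list(a = pool$a_j[[pick$a_j]], b = pool$b_j[[pick$b_j]])
      genes <- c(a_v = pick$a_v, a_j = pick$a_j,
                 b_v = pick$b_v, b_j = pick$b_j)
      ov <- cfg$overlap_length
      len3 <- sample(seq(cfg$cdr3_length_range[1], cfg$cdr3_length_range[2]),
                     2, replace = TRUE)
      seed3 <- lapply(seq_along(len3), function(k) {
        ch <- c("a", "b")[k]
        paste0(substr(v[[ch]], cfg$v_length - ov + 1L, cfg$v_length),
               random_aa(len3[k] - 2L * ov),
               substr(j[[ch]], 1L, ov))
      })
      names(seed3) <- c("a", "b")
      epitope <- random_aa(9L)
      mhc <- alleles[(e - 1L) %% length(alleles) + 1L]
      for (t in seq_len(cfg$tcrs_per_epitope)) {
        row_i <- row_i + 1L
        chains <- list()
        loops <- list()
        for (ch in c("a", "b")) {
          v_body <- mutate_seq(substr(v[[ch]], 1L, cfg$v_length - ov),
                               cfg$mutation_rate, cond)
          interior <- substr(seed3[[ch]], ov + 1L, nchar(seed3[[ch]]) - ov)
          cdr3 <- paste0(substr(seed3[[ch]], 1L, ov),
                         mutate_seq(interior, cfg$mutation_rate, cond),
                         substr(seed3[[ch]], nchar(seed3[[ch]]) - ov + 1L,
                                nchar(seed3[[ch]])))
          j_tail <- mutate_seq(substr(j[[ch]], ov + 1L, cfg$j_length),
                               cfg$mutation_rate, cond)
          chains[[ch]] <- paste0(v_body, cdr3, j_tail)
          loops[[paste0(ch, "1")]] <-
            substr(v_body, CDR1_V_START, CDR1_V_START + cfg$cdr1_length - 1L)
          loops[[paste0(ch, "2")]] <-
            substr(v_body, CDR2_V_START, CDR2_V_START + cfg$cdr2_length - 1L)
          loops[[paste0(ch, "3")]] <- cdr3
        }
        id <- sprintf("E%02dT%03d", e, t)
        rows[[row_i]] <- data.frame(
          id = id,
          cdr1a = loops$a1, cdr2a = loops$a2, cdr3a = loops$a3,
          cdr1b = loops$b1, cdr2b = loops$b2, cdr3b = loops$b3,
          va = genes[["a_v"]], ja = genes[["a_j"]],
          vb = genes[["b_v"]], jb = genes[["b_j"]],
          alpha_seq = chains$a, beta_seq = chains$b,
          epitope = epitope, mhc = mhc, structure_id = id,
          stringsAsFactors = FALSE)
      }
    }
    repertoire <- as_tcr_repertoire(do.call(rbind, rows))
    attr(repertoire, "template_max_seqid") <- cfg$template_max_seqid
    list(repertoire = repertoire, germline = germline)
  })
}

# Uniform random proper rotation matrix (QR of a Gaussian matrix, sign
# corrected).
random_rotation <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_dec)
  R <- R %*% diag(sign(diag(qr.R(qr_dec))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# n alpha carbons along a circular arc of span `phi` with fixed chord
# spacing, centered at the origin in the xy plane.
arc_loop <- function(n, phi, spacing) {
  if (n == 1L) return(matrix(0, 1, 3))
  delta <- phi / (n - 1L)
  r <- spacing / (2 * sin(delta / 2))
  theta <- (seq_len(n) - 1L) * delta
  pts <- cbind(r * cos(theta), r * sin(theta), 0)
  sweep(pts, 2, colMeans(pts))
}

# Spatial layout of the six loop sites within a model (Angstrom).
LOOP_CENTERS <- matrix(c(0, 0, 0,   20, 0, 0,   40, 0, 0,
                         0, 20, 8,  20, 20, 8,  40, 20, 8),
                       ncol = 3, byrow = TRUE,
                       dimnames = list(c("a1", "a2", "a3",
                                         "b1", "b2", "b3"), NULL))

# First residue number of each loop under the default annotation preset.
LOOP_START_RESNO <- c(a1 = 27L, a2 = 56L, a3 = 105L,
                      b1 = 27L, b2 = 56L, b3 = 105L)

#' Generate toy structural models for a synthetic repertoire
#'
#' Renders each CDR loop as a smooth circular alpha-carbon arc with
#' epitope-specific shape (arc span and orientation drawn once per epitope
#' and loop), per-receptor Gaussian coordinate jitter, and a random
#' rigid-body transform of each whole model — so superposition is always
#' exercised. Residue numbers follow the default [loop_annotation()]
#' preset, and loop lengths match the records' loop sequences.
#'
#' @param repertoire the `repertoire` element of [generate_repertoire()]
#'   (or any repertoire whose labels group receptors by epitope).
#' @param config the same [synth_config()]; geometry derives from
#'   `seed + 1`.
#' @return a named list of `tcr_structure` objects keyed by record id.
#' @export
generate_structures <- function(repertoire, config) {
  stopifnot(inherits(config, "synth_config"), is.data.frame(repertoire))
  cfg <- config
  with_local_seed(cfg$seed + 1L, {
    labels <- tcr_labels(repertoire)
    epitopes <- unique(labels)
    shapes <- list()
    for (ep in epitopes) {
      first <- repertoire[match(ep, labels), ]
      shapes[[ep]] <- lapply(setNames(LOOP_IDS, LOOP_IDS), function(lid) {
        n <- nchar(first[[LOOP_COLUMNS[[lid]]]])
        base <- arc_loop(n, runif(1, 0.6 * pi, 1.5 * pi), cfg$ca_spacing)
        base <- base %*% t(random_rotation())
        sweep(base, 2, LOOP_CENTERS[lid, ], `+`)
      })
    }
    out <- vector("list", nrow(repertoire))
    names(out) <- repertoire$id
    for (i in seq_len(nrow(repertoire))) {
      shape <- shapes[[labels[i]]]
      R <- random_rotation()
      shift <- runif(3, -1, 1) * cfg$transform_magnitude
      loops <- lapply(setNames(LOOP_IDS, LOOP_IDS), function(lid) {
        xyz <- shape[[lid]]
        if (cfg$jitter_sd > 0)
          xyz <- xyz + matrix(rnorm(length(xyz), sd = cfg$jitter_sd),
                              nrow(xyz), 3)
        xyz <- sweep(xyz %*% t(R), 2, shift, `+`)
        chain <- if (substr(lid, 1, 1) == "a") "A" else "B"
        resno <- LOOP_START_RESNO[[lid]] + seq_len(nrow(xyz)) - 1L
        new_loop_structure(chain, as.integer(substr(lid, 2, 2)), resno,
                           rep("", nrow(xyz)), xyz)
      })
      out[[i]] <- new_tcr_structure(repertoire$id[i], loops)
    }
    out
  })
}
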