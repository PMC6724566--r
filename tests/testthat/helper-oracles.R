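# Independent oracles, kept deliberately naive and separate from the
# package's own implementations.

# All-substrings kernel by direct enumeration with substring().
oracle_cdr_raw <- function(f, g, B) {
  total <- 0
  for (k in seq_len(min(nchar(f), nchar(g)))) {
    us <- substring(f, seq_len(nchar(f) - k + 1), k:nchar(f))
    vs <- substring(g, seq_len(nchar(g) - k + 1), k:nchar(g))
    for (u in us) {
      uc <- strsplit(u, "")[[1]]
      for (v in vs) {
        vc <- strsplit(v, "")[[1]]
        total <- total + prod(B[cbind(uc, vc)])
      }
    }
  }
  total
}

# Mutual-nearest RMSD from the full all-pairs distance matrix.
oracle_mutual_rmsd <- function(A, B) {
  D <- as.matrix(stats::dist(rbind(A, B)))[seq_len(nrow(A)),
                                           nrow(A) + seq_len(nrow(B)),
                                           drop = FALSE]
  sum_sq <- 0
  n <- 0L
  for (i in seq_len(nrow(A))) {
    j <- which.min(D[i, ])
    if (which.min(D[, j]) == i) {
      sum_sq <- sum_sq + D[i, j]^2
      n <- n + 1L
    }
  }
  if (n == 0L) NA_real_ else sqrt(sum_sq / n)
}

# Adjusted Rand Index by explicit pair counting over all C(n,2) pairs.
oracle_ari <- function(true, pred) {
  n <- length(true)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      st <- true[i] == true[j]
      sp <- pred[i] == pred[j]
      if (st && sp) n11 <- n11 + 1
      else if (!st && !sp) n00 <- n00 + 1
      else if (st && !sp) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  num <- 2 * (n11 * n00 - n10 * n01)
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) 1 else num / den
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_seq <- function(n) paste(sample(AA20, n, replace = TRUE),
                                collapse = "")

# Minimal labeled repertoire row; chains default to V+CDR3-like filler.
make_record <- function(id, cdr3a = "CASSLGA", cdr3b = "CASSRGE",
                        alpha_seq = NA, beta_seq = NA,
                        epitope = "SIINFEKL", mhc = "H2-Kb",
                        cdr1a = "TSGFYG", cdr2a = "NALDGL",
                        cdr1b = "SGHRSV", cdr2b = "YFSETQ",
                        va = "TRAV1", ja = "TRAJ1",
                        vb = "TRBV1", jb = "TRBJ1") {
  data.frame(id = id, cdr1a = cdr1a, cdr2a = cdr2a, cdr3a = cdr3a,
             cdr1b = cdr1b, cdr2b = cdr2b, cdr3b = cdr3b,
             va = va, ja = ja, vb = vb, jb = jb,
             alpha_seq = alpha_seq, beta_seq = beta_seq,
             epitope = epitope, mhc = mhc,
             structure_id = id, stringsAsFactors = FALSE)
}

make_repertoire <- function(...) {
  df <- do.call(rbind, list(...))
  structure(df, class = c("tcr_repertoire", "data.frame"))
}

# Loop / structure builders over raw coordinates (package-internal
# constructors accessed directly; tests run against the installed package).
make_loop <- function(xyz, chain = "A", index = 3L,
                      resno = 105L + seq_len(nrow(xyz)) - 1L) {
  tcrtarget:::new_loop_structure(chain, index, resno,
                                 rep("", nrow(xyz)), xyz)
}

make_structure <- function(id, loop_xyz) {
  chains <- c(a = "A", b = "B")
  loops <- lapply(seq_along(loop_xyz), function(i) {
    lid <- names(loop_xyz)[i]
    ch <- substr(lid, 1, 1)
    k <- as.integer(substr(lid, 2, 2))
    start <- c("1" = 27L, "2" = 56L, "3" = 105L)[[as.character(k)]]
    tcrtarget:::new_loop_structure(chains[[ch]], k,
                                   start + seq_len(nrow(loop_xyz[[i]])) - 1L,
                                   rep("", nrow(loop_xyz[[i]])),
                                   loop_xyz[[i]])
  })
  names(loops) <- names(loop_xyz)
  tcrtarget:::new_tcr_structure(id, loops)
}

# Six-loop toy structure from a base point cloud generator.
make_toy_structure <- function(id, n_per_loop = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  centers <- list(a1 = c(0, 0, 0), a2 = c(20, 0, 0), a3 = c(40, 0, 0),
                  b1 = c(0, 20, 0), b2 = c(20, 20, 0), b3 = c(40, 20, 0))
  loop_xyz <- lapply(centers, function(ctr) {
    sweep(matrix(rnorm(n_per_loop * 3, sd = 3), n_per_loop, 3), 2, ctr, `+`)
  })
  make_structure(id, loop_xyz)
}

random_rotation_matrix <- function() {
  qd <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qd) %*% diag(sign(diag(qr.R(qd))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

transform_structure <- function(s, R, shift) {
  s$loops <- lapply(s$loops, function(l) {
    if (nrow(l$xyz)) l$xyz <- sweep(l$xyz %*% t(R), 2, shift, `+`)
    l
  })
  s
}

# 10 records: one triple-duplicate group, one pair at 99.5+% identity and
# five mutually dissimilar singletons; by hand, single-linkage at 99% gives
# 7 clusters, hence 7 survivors.
redundancy_fixture <- function() {
  set.seed(77)
  base_a <- random_seq(200)
  base_b <- random_seq(200)
  dup <- lapply(c("r1", "r2", "r3"), function(id)
    make_record(id, alpha_seq = base_a, beta_seq = base_b))
  near_a <- random_seq(200)
  near_b <- random_seq(200)
  near_b_mut <- near_b
  substr(near_b_mut, 100, 100) <- setdiff(AA20,
                                          substr(near_b, 100, 100))[1]
  near <- list(make_record("r4", alpha_seq = near_a, beta_seq = near_b),
               make_record("r5", alpha_seq = near_a, beta_seq = near_b_mut))
  singles <- lapply(6:10, function(i)
    make_record(paste0("r", i), alpha_seq = random_seq(200),
                beta_seq = random_seq(200)))
  do.call(make_repertoire, c(dup, near, singles))
}

pmhc_label <- function(repertoire) {
  paste(repertoire$epitope, repertoire$mhc, sep = "|")
}

pred_label <- function(pred) {
  ifelse(is.na(pred$peptide), NA, paste(pred$peptide, pred$mhc, sep = "|"))
}
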