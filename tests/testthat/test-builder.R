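test_that("reconstruct_chain splices V, CDR3 and J at exact overlaps", {
  expect_equal(reconstruct_chain("MKTWCASS", "CASSLGETQYF", "ETQYFGPG"),
               "MKTWCASSLGETQYFGPG")
  # overlap found inside (not at the very end of) V
  expect_equal(reconstruct_chain("MKTWCASSGG", "CASSLGETQYF", "ETQYFGPG"),
               "MKTWCASSLGETQYFGPG")
  # single-residue overlap
  expect_equal(reconstruct_chain("MKC", "CWF", "FGP", overlap = 1),
               "MKCWFGP")
})

test_that("reconstruction failures are errors naming the pieces", {
  expect_error(reconstruct_chain("MKTWCASS", "CGSSLGETQYF", "ETQYFGPG"),
               "CGSS")
  expect_error(reconstruct_chain("MKTWCASS", "CASSLGETQAA", "ETQYFGPG"),
               "TQAA")
  expect_error(reconstruct_chain("MKTWCASS", "CAS", "ETQYFGPG"),
               "shorter")
  # one mismatch tolerated when allowed
  expect_equal(reconstruct_chain("MKTWCASS", "CGSSLGETQYF", "ETQYFGPG",
                                 max_mismatch = 1),
               "MKTWCGSSLGETQYFGPG")
})

test_that("repertoire reconstruction fills chains and counts failures", {
  germline <- c(TRAV1 = "MKTWCASS", TRAJ1 = "ETQYFGPG",
                TRBV1 = "MGHQCAIS", TRBJ1 = "NQFFGSGT")
  good <- make_record("ok", cdr3a = "CASSLGETQYF", cdr3b = "CAISEPNQFF")
  bad <- make_record("bad", cdr3a = "CGGGLGETQYF", cdr3b = "CAISEPNQFF")
  rep_df <- make_repertoire(good, bad)
  out <- reconstruct_repertoire(rep_df, germline, quiet = TRUE)
  expect_equal(nrow(out), 1L)
  expect_equal(attr(out, "n_failed"), 1L)
  expect_equal(out$alpha_seq, "MKTWCASSLGETQYFGPG")
  expect_equal(out$beta_seq, "MGHQCAISEPNQFFGSGT")
})

test_that("cross-reactive chain pairs are removed entirely", {
  a1 <- make_record("a1", alpha_seq = "MKTWCASSLG", beta_seq = "MGHQCAISEP",
                    epitope = "SIINFEKL")
  a2 <- make_record("a2", alpha_seq = "MKTWCASSLG", beta_seq = "MGHQCAISEP",
                    epitope = "GILGFVFTL")
  b1 <- make_record("b1", alpha_seq = "WWTWCASSLG", beta_seq = "WGHQCAISEP",
                    epitope = "SIINFEKL")
  out <- remove_cross_reactive(make_repertoire(a1, a2, b1), quiet = TRUE)
  expect_equal(out$id, "b1")
  expect_equal(attr(out, "n_removed"), 2L)
  # same chains, same label: both retained
  c1 <- make_record("c1", alpha_seq = "MKTWCASSLG", beta_seq = "MGHQCAISEP")
  c2 <- make_record("c2", alpha_seq = "MKTWCASSLG", beta_seq = "MGHQCAISEP")
  out2 <- remove_cross_reactive(make_repertoire(c1, c2), quiet = TRUE)
  expect_equal(nrow(out2), 2L)
  # unique chain pairs are never removed; empty input passes through
  expect_equal(nrow(remove_cross_reactive(make_repertoire(b1),
                                          quiet = TRUE)), 1L)
  empty <- make_repertoire(b1)[0, ]
  expect_equal(nrow(remove_cross_reactive(empty, quiet = TRUE)), 0L)
})

test_that("redundancy reduction keeps one centroid per 99% cluster", {
  rep_df <- redundancy_fixture()
  # the constructed near-pair really sits at >= 99% average identity
  expect_gte(paired_identity(rep_df[4, ], rep_df[5, ]), 99)
  out <- reduce_redundancy(rep_df, threshold = 99, quiet = TRUE)
  expect_equal(nrow(out), 7L)
  expect_equal(attr(out, "n_removed"), 3L)
  # centroid ties resolve to the lexicographically smallest id,
  # survivors stay in input order
  expect_equal(out$id, c("r1", "r4", "r6", "r7", "r8", "r9", "r10"))
})

test_that("redundancy reduction is idempotent and threshold-sensitive", {
  rep_df <- redundancy_fixture()
  once <- reduce_redundancy(rep_df, threshold = 99, quiet = TRUE)
  twice <- reduce_redundancy(once, threshold = 99, quiet = TRUE)
  expect_equal(as.data.frame(twice), as.data.frame(once),
               ignore_attr = TRUE)
  # at a 99.9% threshold the 99.75% pair is below threshold: both survive
  loose <- reduce_redundancy(rep_df, threshold = 99.9, quiet = TRUE)
  expect_true(all(c("r4", "r5") %in% loose$id))
  expect_equal(nrow(loose), 8L)
})

test_that("three identical records collapse to one", {
  set.seed(78)
  a <- random_seq(80); b <- random_seq(80)
  recs <- lapply(c("x", "y", "z"), function(id)
    make_record(id, alpha_seq = a, beta_seq = b))
  out <- reduce_redundancy(do.call(make_repertoire, recs), quiet = TRUE)
  expect_equal(out$id, "x")
})
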