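B <- blosum62_kernel_matrix()

test_that("the hold-out filter removes strictly-above-cutoff entries", {
  set.seed(303)
  q <- make_record("q", alpha_seq = random_seq(60), beta_seq = random_seq(60))
  dup <- q; dup$id <- "dup"
  far <- make_record("far", alpha_seq = random_seq(60),
                     beta_seq = random_seq(60))
  db <- make_repertoire(dup, far)
  kept <- filter_database(q, db, max_seqid = 99)
  expect_equal(kept$id, "far")
  expect_equal(attr(kept, "n_removed"), 1L)
  # max_seqid = 100 retains everything (boundary is inclusive-retain)
  expect_equal(nrow(filter_database(q, db, max_seqid = 100)), 2L)
  # entries exactly at the cutoff are retained
  id_far <- paired_identity(q, far)
  expect_equal(nrow(filter_database(q, db, max_seqid = id_far)), 1L)
  expect_error(filter_database(q, db, max_seqid = 0), "\\(0, 100\\]")
})

test_that("an all-similar database yields no candidates", {
  set.seed(304)
  a <- random_seq(60); b <- random_seq(60)
  q <- make_record("q", alpha_seq = a, beta_seq = b)
  db <- make_repertoire(make_record("d1", alpha_seq = a, beta_seq = b),
                        make_record("d2", alpha_seq = a, beta_seq = b))
  kept <- filter_database(q, db, max_seqid = 70)
  expect_equal(nrow(kept), 0L)
  # predict() turns that into an abstention, not an error
  ann <- tcr_annotator(db, model = "CDR(1:1:1-1:1:1)", max_seqid = 70,
                       kernel = B)
  pred <- predict(ann, q)
  expect_true(pred$abstained)
  expect_true(is.na(pred$peptide))
  expect_equal(pred$n_candidates, 0L)
})

test_that("a single-entry database always assigns its label", {
  db <- make_repertoire(make_record("only", epitope = "GILGFVFTL",
                                    mhc = "HLA-A*02:01"))
  q <- make_record("q", cdr3a = "CAVRDGGSYIPTF", cdr3b = "CASSIRSSYEQYF")
  ann <- tcr_annotator(db, model = "CDR(1:1:1-1:1:1)", max_seqid = 100,
                       kernel = B)
  pred <- predict(ann, q)
  expect_equal(pred$peptide, "GILGFVFTL")
  expect_equal(pred$best_hit, "only")
  expect_false(pred$abstained)
})

test_that("exact score ties go to the first database entry with a warning", {
  # two database entries identical in every loop but differently labeled
  d1 <- make_record("d1", epitope = "PEPA")
  d2 <- make_record("d2", epitope = "PEPB")
  q <- make_record("q", cdr3a = "CASSLGG", cdr3b = "CASSLGG")
  ann <- tcr_annotator(make_repertoire(d1, d2),
                       model = "CDR(1:1:1-1:1:1)", max_seqid = 100,
                       kernel = B)
  expect_warning(pred <- predict(ann, q), "tie")
  expect_equal(pred$best_hit, "d1")
  expect_equal(pred$peptide, "PEPA")
})

test_that("a same-epitope near-duplicate below the cutoff is recovered", {
  cfg <- synth_config(n_epitopes = 4, tcrs_per_epitope = 6,
                      mutation_rate = 0.05, seed = 404)
  synth <- generate_repertoire(cfg)
  rep_df <- synth$repertoire
  q <- rep_df[1, ]
  db <- rep_df[-1, ]
  ann <- tcr_annotator(db, model = "CDR(1:1:1-1:1:1)", max_seqid = 99,
                       kernel = B)
  pred <- suppressWarnings(predict(ann, q))
  expect_equal(pred$peptide, q$epitope)
  expect_equal(pred$mhc, q$mhc)
})

test_that("annotator validates inputs and prints a summary", {
  db <- make_repertoire(make_record("d1"), make_record("d2", cdr3a = "CAVR"))
  expect_error(tcr_annotator(db, max_seqid = 101), "\\(0, 100\\]")
  unlabeled <- db
  unlabeled$epitope <- NA_character_
  expect_error(tcr_annotator(unlabeled), "label")
  ann <- tcr_annotator(db, model = "CDR(0:0:0-0:0:1)", kernel = B)
  expect_output(print(ann), "Max SeqID")
  expect_output(print(summary(ann)), "label counts")
})

test_that("leave-one-out predictions exclude the query itself", {
  cfg <- synth_config(n_epitopes = 3, tcrs_per_epitope = 3,
                      mutation_rate = 0.05, seed = 405)
  synth <- generate_repertoire(cfg)
  pred <- suppressWarnings(
    loo_predict(synth$repertoire, "CDR(1:1:1-1:1:1)", max_seqid = 100,
                kernel = B))
  expect_false(any(pred$best_hit == pred$query_id, na.rm = TRUE))
  expect_equal(pred$query_id, synth$repertoire$id)
})
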