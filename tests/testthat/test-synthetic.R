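test_that("generator configuration is validated", {
  expect_error(synth_config(n_epitopes = 2, tcrs_per_epitope = 4), "seed")
  expect_error(synth_config(mutation_rate = 1, seed = 1), "mutation_rate")
  expect_error(synth_config(tcrs_per_epitope = 1, seed = 1), "at least")
  expect_error(synth_config(cdr3_length_range = c(6, 10), seed = 1),
               "twice the overlap")
})

test_that("a fixed seed reproduces the repertoire and structures exactly", {
  cfg <- synth_config(n_epitopes = 3, tcrs_per_epitope = 3, seed = 2024)
  s1 <- generate_repertoire(cfg)
  s2 <- generate_repertoire(cfg)
  expect_identical(as.data.frame(s1$repertoire), as.data.frame(s2$repertoire))
  expect_identical(s1$germline, s2$germline)
  st1 <- generate_structures(s1$repertoire, cfg)
  st2 <- generate_structures(s2$repertoire, cfg)
  expect_identical(st1, st2)
})

test_that("generated records carry consistent loops, chains and labels", {
  cfg <- synth_config(n_epitopes = 4, tcrs_per_epitope = 5,
                      mutation_rate = 0.1, seed = 7)
  synth <- generate_repertoire(cfg)
  rep_df <- synth$repertoire
  expect_equal(nrow(rep_df), 20L)
  expect_false(anyDuplicated(rep_df$id) > 0)
  # every sequence field is standard 20-letter uppercase
  for (col in c("cdr1a", "cdr2a", "cdr3a", "cdr1b", "cdr2b", "cdr3b",
                "alpha_seq", "beta_seq"))
    expect_true(all(tcrtarget:::is_standard_aa(rep_df[[col]])), label = col)
  # each label has at least two receptors
  expect_true(all(table(pmhc_label(rep_df)) >= 2))
  # the CDR3 is a substring of the full chain, flanked by germline overlap
  expect_true(all(mapply(grepl, rep_df$cdr3a, rep_df$alpha_seq,
                         MoreArgs = list(fixed = TRUE))))
  # germline reconstruction reproduces a chain with germline flanks
  g <- synth$germline
  r <- rep_df[1, ]
  rc <- reconstruct_chain(g[[r$va]], r$cdr3a, g[[r$ja]])
  expect_equal(nchar(rc), nchar(r$alpha_seq))
})

test_that("zero mutation collapses each epitope to one redundant group", {
  cfg <- synth_config(n_epitopes = 3, tcrs_per_epitope = 4,
                      mutation_rate = 0, seed = 9)
  synth <- generate_repertoire(cfg)
  per_epitope <- split(synth$repertoire$alpha_seq,
                       pmhc_label(synth$repertoire))
  for (seqs in per_epitope)
    expect_equal(length(unique(seqs)), 1L)
  reduced <- reduce_redundancy(synth$repertoire, threshold = 99,
                               quiet = TRUE)
  expect_equal(nrow(reduced), 3L)
})

test_that("structures share epitope geometry up to jitter and rigid motion", {
  cfg <- synth_config(n_epitopes = 3, tcrs_per_epitope = 3,
                      mutation_rate = 0, jitter_sd = 0, seed = 15)
  synth <- generate_repertoire(cfg)
  structs <- generate_structures(synth$repertoire, cfg)
  labels <- pmhc_label(synth$repertoire)
  same <- which(labels == labels[1])
  other <- which(labels != labels[1])
  # sigma = 0, same epitope: identical after superposition
  d_same <- as.numeric(structural_dissimilarity(structs[[same[1]]],
                                                structs[[same[2]]]))
  expect_lt(d_same, 1e-6)
  # different epitopes differ structurally
  d_diff <- as.numeric(structural_dissimilarity(structs[[same[1]]],
                                                structs[[other[1]]]))
  expect_gt(d_diff, d_same + 0.5)
  # a pure rigid transform of the same model is recovered exactly
  moved <- transform_structure(structs[[1]], random_rotation_matrix(),
                               c(30, -12, 4))
  expect_lt(as.numeric(structural_dissimilarity(structs[[1]], moved)),
            1e-6)
})

test_that("loop lengths follow the records and numbering follows the preset", {
  cfg <- synth_config(n_epitopes = 2, tcrs_per_epitope = 2, jitter_sd = 0,
                      seed = 33)
  synth <- generate_repertoire(cfg)
  structs <- generate_structures(synth$repertoire, cfg)
  r <- synth$repertoire[1, ]
  s <- structs[[r$id]]
  expect_equal(nrow(s$loops$a3$xyz), nchar(r$cdr3a))
  expect_equal(nrow(s$loops$b1$xyz), nchar(r$cdr1b))
  expect_equal(s$loops$a1$resno[1], 27L)
  expect_equal(s$loops$a2$resno[1], 56L)
  expect_equal(s$loops$a3$resno[1], 105L)
  # consecutive alpha carbons sit at the configured spacing
  gaps <- sqrt(rowSums(diff(s$loops$a3$xyz)^2))
  expect_equal(gaps, rep(cfg$ca_spacing, length(gaps)), tolerance = 1e-6)
})
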