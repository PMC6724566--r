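test_that("superposition exactly recovers a rigid transform", {
  set.seed(101)
  sA <- make_toy_structure("A", seed = 101)
  R <- random_rotation_matrix()
  sB <- transform_structure(sA, R, c(12, -5, 30))
  sB$structure_id <- "B"
  sup <- superpose_tcr(sA, sB)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
  expect_lt(sup$fit_rmsd, 1e-6)
  for (lid in names(sA$loops))
    expect_equal(sup$structure$loops[[lid]]$xyz, sA$loops[[lid]]$xyz,
                 tolerance = 1e-6)
})

test_that("self-superposition is the identity transform", {
  sA <- make_toy_structure("A", seed = 7)
  sup <- superpose_tcr(sA, sA)
  expect_equal(sup$rotation, diag(3), tolerance = 1e-9)
  expect_equal(sup$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(sup$n_matched, sum(vapply(sA$loops,
                                         function(l) nrow(l$xyz),
                                         numeric(1))))
})

test_that("kabsch agrees with bio3d's least-squares fit", {
  skip_if_not_installed("bio3d")
  set.seed(55)
  x <- matrix(rnorm(30, sd = 5), 10, 3)
  y <- sweep(x %*% t(random_rotation_matrix()), 2, c(3, 1, -2), `+`) +
    matrix(rnorm(30, sd = 0.2), 10, 3)
  fit <- tcrtarget:::kabsch(x, y)
  moved <- suppressWarnings(bio3d::fit.xyz(fixed = as.numeric(t(x)),
                                           mobile = as.numeric(t(y))))
  rmsd_bio3d <- sqrt(mean(rowSums(
    (matrix(moved, ncol = 3, byrow = TRUE) - x)^2)))
  expect_equal(fit$rmsd, rmsd_bio3d, tolerance = 1e-6)
})

test_that("disjoint residue numbering is an alignment error", {
  sA <- make_toy_structure("A", seed = 1)
  sB <- make_toy_structure("B", seed = 2)
  for (lid in names(sB$loops))
    sB$loops[[lid]]$resno <- sB$loops[[lid]]$resno + 500L
  expect_error(superpose_tcr(sA, sB), "3 matchable")
})

test_that("mutual-nearest rmsd matches its definition in simple cases", {
  la <- make_loop(matrix(c(0, 0, 0), 1, 3))
  lb <- make_loop(matrix(c(3, 4, 0), 1, 3))
  r <- loop_rmsd(la, lb)
  expect_equal(as.numeric(r), 5)  # single mutual pair at distance 5
  expect_equal(attr(r, "n"), 1L)
  expect_equal(as.numeric(loop_rmsd(la, la)), 0)
  expect_error(loop_rmsd(make_loop(matrix(numeric(0), 0, 3)), la),
               "non-empty")
})

test_that("mutual-nearest rmsd equals the brute-force oracle", {
  set.seed(202)
  for (rep in 1:100) {
    A <- matrix(rnorm(8 * 3, sd = 4), 8, 3)
    B <- matrix(rnorm(8 * 3, sd = 4), 8, 3)
    r <- loop_rmsd(make_loop(A), make_loop(B))
    expect_equal(as.numeric(r), oracle_mutual_rmsd(A, B))
  }
})

test_that("structural dissimilarity is a weighted mean of loop RMSDs", {
  sA <- make_toy_structure("A", seed = 9)
  expect_equal(as.numeric(structural_dissimilarity(sA, sA)), 0,
               tolerance = 1e-9)
  # rigid-motion invariance
  sB <- transform_structure(sA, random_rotation_matrix(), c(5, 5, 5))
  expect_lt(as.numeric(structural_dissimilarity(sA, sB)), 1e-6)
  # symmetry within tolerance on distinct toy structures
  sC <- make_toy_structure("C", seed = 10)
  d_ac <- as.numeric(structural_dissimilarity(sA, sC))
  d_ca <- as.numeric(structural_dissimilarity(sC, sA))
  expect_lt(abs(d_ac - d_ca), 1e-6)
})

test_that("loop weights average per-loop RMSD after normalization", {
  sA <- make_toy_structure("A", seed = 12)
  sC <- make_toy_structure("C", seed = 13)
  d <- structural_dissimilarity(sA, sC)
  per_loop <- attr(d, "loop_rmsd")
  expect_equal(as.numeric(d), mean(per_loop))
  w <- c(1, 0, 0, 0, 0, 2)
  d_w <- structural_dissimilarity(sA, sC, scheme = w)
  expect_equal(as.numeric(d_w),
               (per_loop[["a1"]] + 2 * per_loop[["b3"]]) / 3)
})

test_that("a missing loop is capped with a warning", {
  sA <- make_toy_structure("A", seed = 20)
  sB <- make_toy_structure("B", seed = 20)  # identical geometry
  sB$loops$b3$xyz <- matrix(numeric(0), 0, 3)
  sB$loops$b3$resno <- integer(0)
  sB$loops$b3$ins <- character(0)
  expect_warning(d <- structural_dissimilarity(sA, sB, cap = 10),
                 "capped")
  expect_equal(as.numeric(d), 10 / 6, tolerance = 1e-6)
})
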