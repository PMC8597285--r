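test_that("fuzzy intersection sizes and sets follow their definitions", {
  ones <- matrix(1L, 3, 3, dimnames = list(paste0("g", 1:3), paste0("m", 1:3)))
  expect_equal(fuzzy_intersection_sizes(ones), c(3L, 3L, 3L))

  m <- matrix(0L, 4, 3, dimnames = list(paste0("g", 1:4), paste0("m", 1:3)))
  m[1, ] <- 1; m[2, 1:2] <- 1; m[3, 1] <- 1
  expect_equal(fuzzy_intersection_sizes(m), c(3L, 2L, 1L))

  zeros <- matrix(0L, 3, 4, dimnames = list(paste0("g", 1:3), paste0("m", 1:4)))
  expect_equal(fuzzy_intersection_sizes(zeros), rep(0L, 4))

  expect_setequal(fuzzy_intersection(m, 1), c("g1", "g2", "g3"))
  expect_equal(fuzzy_intersection(m, 3), "g1")
  expect_error(fuzzy_intersection(m, 4), "must be an integer")

  set.seed(17)
  mm <- random_binary_matrix(6, 4)
  expect_equal(fuzzy_intersection(mm, 3), oracle_intersection(mm, 3))
})

test_that("fuzzy intersections are nested and curves non-increasing in n", {
  set.seed(31)
  for (rep in 1:20) {
    m <- random_binary_matrix(sample(3:10, 1), sample(2:6, 1),
                              p = runif(1, 0.2, 0.8))
    sizes <- fuzzy_intersection_sizes(m)
    expect_true(all(diff(sizes) <= 0))
    for (n in seq_len(ncol(m) - 1)) {
      expect_true(all(fuzzy_intersection(m, n + 1) %in% fuzzy_intersection(m, n)))
    }
    ref <- sample(rownames(m), 3)
    rc <- recall_curve(m, ref)
    expect_true(all(diff(rc) <= 0))
  }
})

test_that("recall curve equals hand-computed reference fractions", {
  m <- matrix(0L, 4, 3, dimnames = list(c("A", "B", "C", "D"), paste0("m", 1:3)))
  m["A", ] <- 1; m["B", 1:2] <- 1; m["C", 1] <- 1
  # reference {A, B, D}: row sums 3, 2, 0
  expect_equal(recall_curve(m, c("A", "B", "D")), c(2/3, 2/3, 1/3))

  ones <- matrix(1L, 3, 3, dimnames = list(paste0("g", 1:3), paste0("m", 1:3)))
  expect_equal(recall_curve(ones, rownames(ones)), rep(1, 3))

  # reference genes absent from the matrix leave the denominator
  expect_message(rc <- recall_curve(m, c("A", "ZZZ")), "1 reference gene")
  expect_equal(rc, rep(1, 3))
  expect_error(recall_curve(m, c("X", "Y")), "no reference gene")
})

test_that("permutation null preserves column sums and is seed-reproducible", {
  ones <- matrix(1L, 4, 3, dimnames = list(paste0("g", 1:4), paste0("m", 1:3)))
  # permutation-invariant matrices: expected sizes equal observed exactly
  expect_equal(null_expected_sizes(ones, n_perm = 5, seed = 1),
               as.numeric(fuzzy_intersection_sizes(ones)))

  one_gene <- matrix(c(1L, 0L), 1, 2, dimnames = list("g1", c("m1", "m2")))
  expect_equal(null_expected_sizes(one_gene, n_perm = 5, seed = 1),
               as.numeric(fuzzy_intersection_sizes(one_gene)))

  set.seed(7)
  m <- random_binary_matrix(12, 5)
  e1 <- null_expected_sizes(m, n_perm = 50, seed = 99)
  e2 <- null_expected_sizes(m, n_perm = 50, seed = 99)
  expect_identical(e1, e2)

  # column-sum conservation: E[|I_1|] summed contributions cannot exceed
  # totals, and a direct check that shuffling preserves per-column totals
  set.seed(8)
  for (j in seq_len(ncol(m))) {
    expect_equal(sum(m[sample.int(nrow(m)), j]), sum(m[, j]))
  }
})

test_that("Monte-Carlo null expectation agrees with subset-enumeration expectation", {
  set.seed(13)
  m <- random_binary_matrix(10, 5, p = 0.4)
  exact <- oracle_expected_exact(m)
  n_perm <- 10000
  mc <- null_expected_sizes(m, n_perm = n_perm, seed = 4)
  # |I_n| per permutation is bounded by G = 10; its sd is at most G/2,
  # so 3 standard errors are at most 3 * 5 / sqrt(n_perm)
  se_bound <- 3 * 5 / sqrt(n_perm)
  expect_true(all(abs(mc - exact) <= se_bound))
  # the package's analytic null equals the enumeration oracle
  expect_equal(null_expected_sizes(m, null_model = "exact"), exact,
               tolerance = 1e-12)
})

test_that("deviance curve applies the add-one log10 guard", {
  expect_equal(deviance_curve(c(5, 3), c(5, 3)), c(0, 0))
  expect_equal(deviance_curve(99, 9), 1)
  expect_equal(deviance_curve(0, 0), 0)
  expect_error(deviance_curve(1:3, 1:2), "equal length")
})

test_that("threshold selection finds the scaled-curve crossing, ties to larger n", {
  recall <- c(1, .75, .5, .25, 0)
  deviance <- c(0, .25, .5, .75, 1)
  expect_equal(select_threshold(recall, deviance), 3)

  # exact crossing at two n: the larger wins
  r2 <- c(1, .5, .5, 0)
  d2 <- c(0, .5, .5, 1)
  expect_equal(select_threshold(r2, d2), 3)

  expect_error(select_threshold(rep(1, 4), d2), "degenerate trade-off")
  expect_error(select_threshold(r2, rep(0.2, 4)), "degenerate trade-off")
})

test_that("adam recovers a hand-constructed always-essential reference set", {
  # 6 genes x 4 models: the reference genes are exactly the genes essential
  # in every line, so recall is flat at 1 and the most stringent threshold
  # n* = N returns precisely that set
  m <- matrix(0L, 6, 4, dimnames = list(paste0("g", 1:6), paste0("m", 1:4)))
  m[1:2, ] <- 1L          # always essential
  m[3, 1:3] <- 1L
  m[4, 1:2] <- 1L
  m[5, 1] <- 1L
  expect_message(
    res <- adam(m, reference = c("g1", "g2"), null_model = "exact"),
    "most stringent")
  expect_equal(res$n_star, 4)
  expect_setequal(res$cfgs, c("g1", "g2"))
  expect_equal(res$cfgs, fuzzy_intersection(m, res$n_star))
})

test_that("adam equals the brute-force oracle on random small matrices", {
  set.seed(2024)
  n_checked <- 0
  for (i in 1:300) {
    G <- sample(3:8, 1)
    N <- sample(2:6, 1)
    m <- random_binary_matrix(G, N, p = runif(1, 0.2, 0.8))
    ref <- sample(rownames(m), sample(1:3, 1))
    expected <- oracle_expected_exact(m)
    got <- tryCatch(suppressMessages(adam(m, ref, null_model = "exact")),
                    error = function(e) e)
    want <- tryCatch(oracle_adam(m, ref, expected), error = function(e) e)
    if (inherits(want, "error")) {
      expect_s3_class(got, "error")
    } else {
      expect_false(inherits(got, "error"))
      expect_equal(got$curves$observed, want$observed)
      expect_equal(got$curves$recall, want$recall)
      expect_equal(got$curves$deviance, want$deviance, tolerance = 1e-8)
      expect_identical(got$n_star, as.integer(want$n_star))
      expect_setequal(got$cfgs, want$cfgs)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 100)
})

test_that("pan-cancer ADaM is symmetric for identical tissues", {
  set.seed(55)
  half <- random_binary_matrix(30, 6, p = 0.5)
  half[1:5, ] <- 1L  # make a clear core
  m <- cbind(half, half)
  colnames(m) <- sprintf("m%02d", 1:12)
  ann <- data.frame(model_id = colnames(m),
                    tissue = rep(c("t1", "t2"), each = 6))
  ref <- c("g01", "g02", "g06", "g07")
  res <- suppressMessages(
    pan_cancer_adam(m, ann, ref, min_models_per_tissue = 5, null_model = "exact"))
  expect_setequal(res$tissue_results$t1$cfgs, res$tissue_results$t2$cfgs)
  expect_true(all(res$pan_cfgs %in% res$tissue_results$t1$cfgs))
})

test_that("all-ones membership rows for the reference push t* to the tissue count", {
  # k identical copies of one tissue: reference genes are tissue CFGs
  # everywhere, so the membership rows of the reference are all ones and the
  # most stringent t* (= number of tissues) is selected; pan CFGs then equal
  # the single tissue's CFGs
  set.seed(66)
  base <- random_binary_matrix(25, 5, p = 0.35)
  base[1:4, ] <- 1L
  k <- 3
  m <- do.call(cbind, replicate(k, base, simplify = FALSE))
  colnames(m) <- sprintf("m%02d", seq_len(5 * k))
  ann <- data.frame(model_id = colnames(m),
                    tissue = rep(paste0("t", 1:k), each = 5))
  ref <- c("g01", "g02", "g03")
  res <- suppressMessages(
    pan_cancer_adam(m, ann, ref, min_models_per_tissue = 5, null_model = "exact"))
  expect_equal(res$t_star, k)
  expect_setequal(res$pan_cfgs, res$tissue_results$t1$cfgs)
  # membership rows of reference genes are all ones
  expect_true(all(res$membership[ref, ] == 1))
})

test_that("pan-cancer ADaM validates tissue counts and input type", {
  screens <- default_screens()
  small <- screens$matrix[1:50, 1:8]
  ann <- screens$annotation[screens$annotation$model_id %in% colnames(small), ]
  expect_error(
    suppressWarnings(suppressMessages(
      pan_cancer_adam(small, ann, rownames(small)[1:5],
                      min_models_per_tissue = 10, seed = 1))),
    "at least 2 tissues")
})
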