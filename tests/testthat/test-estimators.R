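test_that("strided partitioning covers the index with quasi-independent sets", {
  p <- partition_snps(3000, 1000)
  expect_identical(p$sets[[1]], c(1L, 1001L, 2001L))
  expect_identical(p$n_sets, 1000L)

  p1 <- partition_snps(17, 1)
  expect_identical(p1$sets[[1]], 1:17)

  # disjoint cover for assorted shapes, including n_sets > n_snps
  for (case in list(c(10, 3), c(100, 7), c(5, 9), c(1, 1), c(2048, 1000))) {
    p <- partition_snps(case[1], case[2])
    all_idx <- sort(unlist(p$sets))
    expect_identical(all_idx, seq_len(case[1]))
    sizes <- lengths(p$sets)
    expect_lte(max(sizes) - min(sizes), 1L)
  }
})

test_that("estimators shrink the set count when SNPs are scarce", {
  panel <- small_panel(n_snps = 300, n_per_pop = 20, seed = 55)
  sv <- study_vector(panel$afs[, 1], "af")
  expect_warning(fit <- afmix(sv, panel, n_sets = 1000), "reducing")
  expect_lte(fit$n_sets_used + fit$n_sets_skipped, 30L)
})

test_that("genotype standardization centers and scales correctly", {
  # at p = 0.5 the HWE sd is sqrt(2 * 0.5 * 0.5) = sqrt(1/2)
  expect_equal(normalize_genotypes(matrix(2), 0.5), matrix(sqrt(2)))
  expect_equal(normalize_genotypes(matrix(0), 0.5), matrix(-sqrt(2)))
  expect_equal(normalize_genotypes(matrix(1), 0.5), matrix(0))
  set.seed(61)
  g <- matrix(sample(0:2, 400, replace = TRUE), 1)
  p_emp <- mean(g) / 2
  gn <- normalize_genotypes(g, p_emp)
  expect_lt(abs(mean(gn)), 1e-10)
  expect_error(normalize_genotypes(matrix(0:2, 3, 1), c(0.5, 1, 0.2)),
               "monomorphic")
})

test_that("pair correlations match brute-force Pearson on raw dosages", {
  panel <- small_panel(n_snps = 40, n_per_pop = 30, seed = 62)
  set.seed(63)
  pairs <- cbind(sample(40, 15, replace = TRUE),
                 sample(40, 15, replace = TRUE))
  R <- pair_correlations(panel, pairs)
  expect_true(all(R >= -1 & R <= 1))
  for (m in 1:15) {
    for (k in 1:3) {
      x <- panel$dosages[[k]][pairs[m, 1], ]
      y <- panel$dosages[[k]][pairs[m, 2], ]
      expected <- if (sd(x) == 0 || sd(y) == 0) {
        if (pairs[m, 1] == pairs[m, 2]) 0 else 0
      } else {
        cor(x, y)
      }
      if (sd(x) > 0 && sd(y) > 0) {
        expect_equal(unname(R[m, k]), expected, tolerance = 1e-10)
      }
    }
  }
  # self-pairs give correlation one for polymorphic SNPs
  self <- pair_correlations(panel, cbind(1:5, 1:5))
  poly <- vapply(1:3, function(k)
    apply(panel$dosages[[k]][1:5, ], 1, sd) > 0, logical(5))
  expect_true(all(abs(self[poly] - 1) < 1e-12))
})

test_that("pair correlations of independent SNPs are centred at zero", {
  panel <- small_panel(n_snps = 200, n_per_pop = 500, seed = 64)
  set.seed(65)
  i <- sample(200, 300, replace = TRUE)
  l <- sample(200, 300, replace = TRUE)
  keep <- i != l
  R <- pair_correlations(panel, cbind(i[keep], l[keep]))
  expect_lt(abs(mean(R)), 0.01)
})

test_that("simplex least squares solves vertex, interior and random problems", {
  # vertex solution
  w <- solve_simplex_ls(diag(3), c(1, 0, 0))
  expect_equal(unname(w), c(1, 0, 0), tolerance = 1e-8)

  # consistent interior system is recovered exactly
  set.seed(71)
  A <- matrix(rnorm(30), 10, 3)
  w_true <- c(0.5, 0.3, 0.2)
  w2 <- solve_simplex_ls(A, as.numeric(A %*% w_true))
  expect_equal(unname(w2), w_true, tolerance = 1e-6)

  # objective never beats an exhaustive grid search by construction
  grid <- as.matrix(expand.grid(w1 = seq(0, 1, 0.005),
                                w2 = seq(0, 1, 0.005)))
  grid <- grid[rowSums(grid) <= 1 + 1e-12, ]
  grid <- cbind(grid, 1 - rowSums(grid))
  for (rep in 1:5) {
    A <- matrix(rnorm(36), 12, 3)
    b <- as.numeric(A %*% runif(3)) + rnorm(12, sd = 0.3)
    w <- solve_simplex_ls(A, b)
    obj <- sum((b - A %*% w)^2)
    grid_obj <- min(colSums((b - A %*% t(grid))^2))
    expect_lte(obj, grid_obj + 1e-4)
  }

  expect_error(solve_simplex_ls(matrix(c(1, NA), 1, 2), 1), "non-finite")

  # K = 1 is forced to weight one
  expect_equal(unname(solve_simplex_ls(matrix(rnorm(5)), rnorm(5))), 1)
})

test_that("afmix recovers pure and mixed AF sources on a noiseless panel", {
  set.seed(72)
  n <- 2000
  afs <- matrix(runif(n * 4, 0.05, 0.95), n, 4,
                dimnames = list(NULL, c("W", "X", "Y", "Z")))
  snps <- data.frame(rsid = sprintf("rs%d", 1:n), chrom = "1",
                     bp = seq_len(n), a1 = "A", a2 = "G",
                     stringsAsFactors = FALSE)
  meta <- data.frame(pop = c("W", "X", "Y", "Z"),
                     super = c("AFR", "AMR", "ASN", "EUR"), n = 10L)
  panel <- reference_panel(snps, meta, afs)

  # pure population
  fit <- afmix(study_vector(afs[, 2], "af"), panel, n_sets = 100)
  expect_gte(fit$weights[["X"]], 0.99)

  # noiseless linear mixture
  w_true <- c(W = 0.4, X = 0.3, Y = 0.2, Z = 0.1)
  S <- as.numeric(afs %*% w_true)
  fit2 <- afmix(study_vector(S, "af"), panel, n_sets = 100)
  expect_lt(max(abs(fit2$weights - w_true)), 0.01)
  # per-set solutions satisfy the simplex invariants
  expect_true(all(abs(rowSums(fit2$per_set_weights) - 1) < 1e-8))
  expect_true(all(fit2$per_set_weights >= -1e-10 &
                    fit2$per_set_weights <= 1 + 1e-10))
  expect_equal(sum(fit2$weights), 1, tolerance = 1e-8)

  # the strict QP constraint mode agrees on this easy problem
  fit3 <- afmix(study_vector(S, "af"), panel, n_sets = 100,
                constrain = "strict_qp")
  expect_lt(max(abs(fit3$weights - w_true)), 0.01)
})

test_that("summix recovers pure and mixed AF sources", {
  set.seed(73)
  n <- 1500
  afs <- matrix(runif(n * 3, 0.05, 0.95), n, 3,
                dimnames = list(NULL, c("P1", "P2", "P3")))
  snps <- data.frame(rsid = sprintf("rs%d", 1:n), chrom = "1",
                     bp = seq_len(n), a1 = "A", a2 = "G",
                     stringsAsFactors = FALSE)
  meta <- data.frame(pop = c("P1", "P2", "P3"),
                     super = c("AFR", "AMR", "ASN"), n = 10L)
  panel <- reference_panel(snps, meta, afs)

  fit <- summix(study_vector(afs[, 3], "af"), panel)
  expect_gte(fit$weights[["P3"]], 0.99)

  w_true <- c(P1 = 0.2, P2 = 0.5, P3 = 0.3)
  S <- as.numeric(afs %*% w_true) + rnorm(n, sd = 0.005)
  fs <- summix(study_vector(S, "af"), panel)
  fa <- afmix(study_vector(S, "af"), panel, n_sets = 100)
  expect_lt(max(abs(fs$weights - w_true)), 0.02)
  # the two AF estimators agree on a well-conditioned mixture
  expect_lt(max(abs(fs$weights - fa$weights)), 0.02)

  expect_error(summix(study_vector(afs[1:2, 1], "af"), panel), "fewer")
})

test_that("estimator output is equivariant under population reordering", {
  set.seed(74)
  n <- 800
  afs <- matrix(runif(n * 3, 0.05, 0.95), n, 3,
                dimnames = list(NULL, c("P1", "P2", "P3")))
  snps <- data.frame(rsid = sprintf("rs%d", 1:n), chrom = "1",
                     bp = seq_len(n), a1 = "A", a2 = "G",
                     stringsAsFactors = FALSE)
  meta <- data.frame(pop = c("P1", "P2", "P3"),
                     super = c("AFR", "AMR", "ASN"), n = 10L)
  S <- as.numeric(afs %*% c(0.6, 0.1, 0.3)) + rnorm(n, sd = 0.002)
  perm <- c(3, 1, 2)
  p_orig <- reference_panel(snps, meta, afs)
  p_perm <- reference_panel(snps, meta[perm, ], afs[, perm])
  f1 <- summix(study_vector(S, "af"), p_orig)
  f2 <- summix(study_vector(S, "af"), p_perm)
  expect_equal(f2$weights[names(f1$weights)], f1$weights, tolerance = 1e-6)
  a1 <- afmix(study_vector(S, "af"), p_orig, n_sets = 40)
  a2 <- afmix(study_vector(S, "af"), p_perm, n_sets = 40)
  expect_equal(a2$weights[names(a1$weights)], a1$weights, tolerance = 1e-6)
})

test_that("zmix is deterministic and forced to one for a single population", {
  pops1 <- data.frame(pop = "ONLY", super = "EUR", fst = 0.05)
  panel1 <- generate_panel(pops1, group_fst = c(EUR = 0), n_snps = 400,
                           n_per_pop = 40, seed = 81)
  cohort <- simulate_cohort(panel1, c(ONLY = 1), 200, seed = 82)
  zs <- simulate_zscores(cohort, seed = 83)
  fit <- zmix(study_vector(zs$z, "z"), panel1, n_sets = 10, seed = 84)
  expect_equal(unname(fit$weights), 1)

  panel <- small_panel(n_snps = 1200, n_per_pop = 60, seed = 101)
  cohort2 <- simulate_cohort(panel, c(POPA = 0.5, POPB = 0.5), 400,
                             seed = 85)
  zs2 <- simulate_zscores(cohort2, seed = 86)
  sv <- study_vector(zs2$z, "z")
  f1 <- zmix(sv, panel, n_sets = 30, max_pairs_per_set = 200, seed = 87)
  f2 <- zmix(sv, panel, n_sets = 30, max_pairs_per_set = 200, seed = 87)
  expect_identical(f1$weights, f2$weights)
  l1 <- zmix_legacy(sv, panel, n_sets = 30)
  l2 <- zmix_legacy(sv, panel, n_sets = 30)
  expect_identical(l1$weights, l2$weights)
  expect_equal(sum(f1$weights), 1, tolerance = 1e-8)
  expect_equal(sum(l1$weights), 1, tolerance = 1e-8)
})

test_that("all estimators return weights on the probability simplex", {
  panel <- small_panel(n_snps = 1200, n_per_pop = 60, seed = 101)
  cohort <- simulate_cohort(panel, c(POPA = 0.3, POPB = 0.3, POPC = 0.4),
                            500, seed = 91)
  S <- cohort_afs(cohort)
  zs <- simulate_zscores(cohort, seed = 92)
  fits <- list(
    afmix(study_vector(S, "af"), panel, n_sets = 50),
    summix(study_vector(S, "af"), panel),
    zmix(study_vector(zs$z, "z"), panel, n_sets = 40, seed = 93),
    zmix_legacy(study_vector(zs$z, "z"), panel, n_sets = 40))
  for (fit in fits) {
    expect_equal(sum(fit$weights), 1, tolerance = 1e-8)
    expect_true(all(fit$weights >= -1e-10 & fit$weights <= 1 + 1e-10))
    expect_true(all(abs(rowSums(fit$per_set_weights) - 1) < 1e-8))
  }
})
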