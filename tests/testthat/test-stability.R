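test_that("replicate collapse averages wells and propagates missing", {
  e <- data.frame(gene = "G1", sample = "S1", replicate = 1:3,
                  ct = c(20.0, 20.4, 20.3))
  grid <- collapse_replicates(ct_table(e))
  expect_equal(grid["G1", "S1"], mean(c(20.0, 20.4, 20.3)))

  e2 <- rbind(e, data.frame(gene = "G2", sample = "S1", replicate = 1,
                            ct = 25))
  grid2 <- collapse_replicates(ct_table(e2))
  expect_equal(grid2["G2", "S1"], 25)  # single replicate is the identity

  e3 <- make_ct_entries(2, 3, 2)
  e3$ct[e3$gene == "G2" & e3$sample == "S3"] <- NA
  grid3 <- collapse_replicates(ct_table(e3))
  expect_true(is.na(grid3["G2", "S3"]))
  expect_false(anyNA(grid3[, c("S1", "S2")]))
})

test_that("combination Ct is the member mean and is strict about missing", {
  grid <- rbind(A = c(S1 = 20, S2 = 21, S3 = 22),
                B = c(S1 = 22, S2 = 23, S3 = NA))
  expect_equal(combination_ct(grid, "A"), grid["A", ])
  expect_equal(combination_ct(grid, c("A", "B"))[["S1"]], 21)
  expect_true(is.na(combination_ct(grid, c("A", "B"))[["S3"]]))
  expect_error(combination_ct(grid, character(0)), "empty")
  expect_error(combination_ct(grid, "Z"), "not in Ct grid")
})

test_that("pairwise delta-Ct SD is offset-invariant and matches hand values", {
  a <- c(S1 = 20, S2 = 21, S3 = 22)
  expect_equal(pairwise_dct_sd(a, a), 0)
  expect_equal(pairwise_dct_sd(a, a + 1.5), 0)
  b <- a - c(0, 1, 2)                 # delta-Ct values 0, 1, 2
  expect_equal(pairwise_dct_sd(a, b), 1)
  expect_error(pairwise_dct_sd(a[1:2], a[1:2]), "shared sample")
})

test_that("mean delta-Ct SD matches a brute-force oracle", {
  grid <- make_grid(5, 8, seed = 101)
  cand <- rownames(grid)
  for (set in list("G1", c("G2", "G4"), c("G1", "G3", "G5"))) {
    expect_equal(mean_dct_sd(grid, set, cand),
                 brute_mean_sd(grid, set, cand))
  }
  # gene-constant offsets between identical profiles score 0 for every set
  base <- make_grid(1, 8, seed = 5)[1, ]
  flat <- rbind(A = base, B = base + 2, C = base - 1)
  expect_equal(mean_dct_sd(flat, "A", rownames(flat)), 0)
  expect_equal(mean_dct_sd(flat, c("A", "C"), rownames(flat)), 0)
  expect_error(mean_dct_sd(flat, c("A", "B", "C"), rownames(flat)),
               "no partner")
})

test_that("enumeration counts follow the binomial coefficients", {
  grid10 <- make_grid(10, 6, seed = 7)
  rk <- enumerate_and_rank(grid10, rownames(grid10), max_size = 4)
  expect_equal(nrow(rk), 385)                      # 10 + 45 + 120 + 210
  expect_equal(as.vector(table(rk$class)), c(10, 45, 120, 210))

  grid2 <- make_grid(2, 6)
  expect_equal(nrow(enumerate_and_rank(grid2, rownames(grid2), 1)), 2)
  grid4 <- make_grid(4, 6)
  expect_equal(nrow(enumerate_and_rank(grid4, rownames(grid4), 3)), 14)

  expect_error(enumerate_and_rank(grid10, rownames(grid10), 10), "max_size")
  grid20 <- make_grid(20, 6)
  expect_error(enumerate_and_rank(grid20, rownames(grid20), 19), "guard")
})

test_that("ranks are tie-averaged permutations, monotone within class", {
  grid <- make_grid(6, 8, seed = 23)
  rk <- enumerate_and_rank(grid, rownames(grid), max_size = 3)
  expect_equal(sort(rank(rk$mean_sd, ties.method = "average")),
               sort(rk$rank_in_total))
  expect_equal(sum(rk$rank_in_total), nrow(rk) * (nrow(rk) + 1) / 2)
  for (k in 1:3) {
    sub <- rk[rk$class == k, ]
    expect_false(is.unsorted(sub$rank_in_class[order(sub$mean_sd)]))
    expect_equal(sort(sub$rank_in_class),
                 sort(rank(sub$mean_sd, ties.method = "average")))
  }
})

test_that("single-pass geNorm M matches a direct pairwise computation", {
  grid <- make_grid(4, 10, seed = 77)
  cand <- rownames(grid)
  m <- genorm_m(grid, cand)
  oracle <- sapply(cand, function(j)
    mean(sapply(setdiff(cand, j), function(k) sd(grid[k, ] - grid[j, ]))))
  expect_equal(m, oracle)

  base <- make_grid(1, 10, seed = 3)[1, ]
  flat <- rbind(A = base, B = base + 1, C = base - 2)
  expect_equal(unname(genorm_m(flat, rownames(flat))), c(0, 0, 0))

  noisy <- rbind(flat, D = base + rnorm(10, 0, 2))
  m2 <- genorm_m(noisy, rownames(noisy))
  expect_equal(names(which.max(m2)), "D")
  expect_error(genorm_m(flat[1:2, ], c("A", "B")), ">= 3")
})

test_that("stability scores are invariant to per-sample loading shifts", {
  grid <- make_grid(6, 8, seed = 31, lambda_sd = 0)
  shift <- rnorm(8, 0, 3)
  shifted <- grid + matrix(shift, 6, 8, byrow = TRUE)
  cand <- rownames(grid)
  rk <- enumerate_and_rank(grid, cand, 3)
  rk_s <- enumerate_and_rank(shifted, cand, 3)
  expect_equal(rk$mean_sd, rk_s$mean_sd, tolerance = 1e-10)
  expect_equal(genorm_m(grid, cand), genorm_m(shifted, cand),
               tolerance = 1e-10)
})

test_that("ranking summary reports the best set per class", {
  grid <- make_grid(5, 8, seed = 19)
  rk <- enumerate_and_rank(grid, rownames(grid), max_size = 3)
  s <- summary(rk)
  expect_equal(nrow(s$best_per_class), 3)
  for (k in 1:3)
    expect_equal(s$best_per_class$mean_sd[s$best_per_class$class == k],
                 min(rk$mean_sd[rk$class == k]))
  expect_output(print(rk), "Stability ranking")
})
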