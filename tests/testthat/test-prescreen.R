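test_that("CV matches hand-computed values and rejects degenerate input", {
  expect_equal(compute_cv(c(5, 5, 5, 5)), 0)
  expect_equal(compute_cv(c(1, 2, 3)), 0.5)            # sd 1, mean 2
  expect_equal(compute_cv(c(2, 4)), sqrt(2) / 3)       # sd sqrt(2), mean 3
  expect_error(compute_cv(5), "at least 2")
  expect_error(compute_cv(c(-2, 2)), "mean")
})

test_that("CV is scale-invariant", {
  set.seed(7)
  for (i in 1:20) {
    v <- runif(sample(3:12, 1), 1, 100)
    c_ <- runif(1, 1e-3, 1e3)
    expect_equal(compute_cv(c_ * v), compute_cv(v), tolerance = 1e-12)
  }
})

test_that("within-family ranking restarts per family and tie-averages", {
  fam <- c(A = "f1", B = "f1", C = "f2", D = "f2", E = "f2")
  r <- rank_within_family(c(A = 0.1, B = 0.3, C = 0.2, D = 0.2, E = 0.5), fam)
  expect_equal(r, c(A = 1, B = 2, C = 1.5, D = 1.5, E = 3))
})

test_that("WRS follows the rank-percentile formula and normalizes to 100", {
  ranks <- data.frame(gene = c("A", "B", "C"), dataset = "d1",
                      family = "fam", family_rank = 1:3)
  sizes <- data.frame(family = "fam", dataset = "d1", n = 3)
  w <- compute_wrs(ranks, sizes, c(d1 = 1))
  expect_equal(w$scores$s[match(c("A", "B", "C"), w$scores$gene)],
               c(1, 0.5, 0))
  agg <- w$aggregate
  expect_equal(agg$wrs[match(c("A", "B", "C"), agg$gene)], c(1, 0.5, 0))
  expect_equal(agg$wrs_pct[match(c("A", "B", "C"), agg$gene)], c(100, 50, 0))

  # worst rank in every dataset, whatever the weights -> WRS 0
  ranks2 <- rbind(ranks,
                  transform(ranks, dataset = "d2"))
  sizes2 <- rbind(sizes, data.frame(family = "fam", dataset = "d2", n = 3))
  w2 <- compute_wrs(ranks2, sizes2, c(d1 = 3, d2 = 1))
  expect_equal(w2$aggregate$wrs[w2$aggregate$gene == "C"], 0)
  # best rank everywhere -> 100 by construction
  expect_equal(w2$aggregate$wrs_pct[w2$aggregate$gene == "A"], 100)
  # singleton family gets s = 1
  ranks3 <- data.frame(gene = "Z", dataset = "d1", family = "solo",
                       family_rank = 1)
  sizes3 <- data.frame(family = "solo", dataset = "d1", n = 1)
  expect_equal(compute_wrs(ranks3, sizes3, c(d1 = 2))$aggregate$wrs, 2)
})

test_that("improving a rank in any dataset never decreases WRS", {
  set.seed(13)
  for (i in 1:20) {
    n_ds <- sample(2:4, 1)
    n_fam <- sample(3:6, 1)
    weights <- setNames(runif(n_ds, 0.5, 5), paste0("d", seq_len(n_ds)))
    ranks <- expand.grid(gene = paste0("g", seq_len(n_fam)),
                         dataset = names(weights),
                         stringsAsFactors = FALSE)
    ranks$family <- "fam"
    ranks$family_rank <- unlist(lapply(seq_len(n_ds), function(d)
      sample(n_fam)))
    sizes <- data.frame(family = "fam", dataset = names(weights), n = n_fam)
    pick <- which(ranks$family_rank > 1)[1]
    if (is.na(pick)) next
    improved <- ranks
    improved$family_rank[pick] <- improved$family_rank[pick] - 1
    g <- ranks$gene[pick]
    before <- compute_wrs(ranks, sizes, weights)$aggregate
    after <- compute_wrs(improved, sizes, weights)$aggregate
    expect_gte(after$wrs[after$gene == g], before$wrs[before$gene == g])
  }
})

test_that("prescreen weights datasets by sample variety by default", {
  m1 <- make_expression(seed = 1, dataset_id = "d1")
  m2 <- make_expression(seed = 2, dataset_id = "d2")
  w <- prescreen(list(m1, m2))
  expect_s3_class(w, "wrs_table")
  expect_equal(unname(w$weights),
               c(dataset_weight(m1), dataset_weight(m2)))
  expect_true(all(c("cv", "family_rank", "s") %in% names(w$scores)))
  # every family tops out at 100 %
  top <- tapply(w$aggregate$wrs_pct, w$aggregate$family, max)
  expect_equal(as.numeric(top), rep(100, length(top)))
})

test_that("candidate selection honours quotas and breaks ties by gene id", {
  agg <- data.frame(
    gene = c(paste0("ubq", 1:6), paste0("gap", 1:2)),
    family = rep(c("ubiquitin", "GAPDH"), c(6, 2)),
    wrs = c(6, 5, 4, 4, 2, 1, 3, 3))
  agg$wrs_pct <- 100 * agg$wrs / ave(agg$wrs, agg$family, FUN = max)
  wrs <- structure(list(scores = NULL, aggregate = agg, weights = c(d1 = 1)),
                   class = "wrs_table")
  expect_message(
    cand <- select_candidates(wrs, c(GAPDH = 1, ubiquitin = 3)),
    "tie")
  expect_equal(cand, c("gap1", "ubq1", "ubq2", "ubq3"))
  expect_equal(select_candidates(wrs, c(ubiquitin = 0, GAPDH = 1)), "gap1")
  expect_error(select_candidates(wrs, c(GAPDH = 5)), "quota")
})

test_that("family quotas reproduce the 10-candidate screen size", {
  # 74 isogenes in the four families; quotas 1/1/5/3 -> 10 candidates
  set.seed(17)
  fams <- c(GAPDH = 7, actin = 13, ubiquitin = 31, cyclophilin = 23)
  cfg <- simulation_config(families = fams, n_samples = 8, seed = 17)
  mats <- lapply(1:2, function(d) simulate_expression_matrix(cfg, d)$matrix)
  wrs <- prescreen(mats)
  expect_equal(nrow(wrs$aggregate), 74)
  cand <- select_candidates(wrs, c(GAPDH = 1, actin = 1,
                                   ubiquitin = 5, cyclophilin = 3))
  expect_length(cand, 10)
  expect_length(unique(cand), 10)
})
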