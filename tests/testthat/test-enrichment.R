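test_that("top-quantile size follows the ceiling rule", {
  base <- data.frame(gene_a = "A", gene_b = sprintf("B%04d", 1:2000),
                     stringsAsFactors = FALSE)
  for (N in c(10, 99, 100, 101, 568, 1777)) {
    for (q in c(0.01, 0.05, 0.2)) {
      pairs <- base[1:N, ]
      pairs$ftERC <- rnorm(N)
      top <- top_quantile(pairs, q)
      expect_identical(top$count, as.integer(ceiling(q * N)))
      expect_gte(min(top$pairs$ftERC), top$cutoff)
    }
  }
  pairs <- base[1:100, ]
  pairs$ftERC <- seq(100, 1)
  expect_equal(top_quantile(pairs, 0.01)$pairs$ftERC, 100)  # the max
  expect_error(top_quantile(pairs[0, ], 0.01))
})

test_that("every included score is >= every excluded score", {
  set.seed(12)
  pairs <- data.frame(gene_a = "A", gene_b = sprintf("B%03d", 1:300),
                      ftERC = sample(rep(rnorm(60), 5)),
                      stringsAsFactors = FALSE)
  top <- top_quantile(pairs, 0.1)
  excluded <- setdiff(pairs$gene_b, top$pairs$gene_b)
  expect_gte(min(top$pairs$ftERC),
             max(pairs$ftERC[pairs$gene_b %in% excluded]))
})

test_that("ties at the cutoff break deterministically by pair id", {
  # 200 pairs, 5 tied exactly at the cutoff score
  pairs <- data.frame(gene_a = sprintf("A%03d", 1:200),
                      gene_b = sprintf("B%03d", 1:200),
                      ftERC = c(rep(9, 18), rep(5, 5), rep(1, 177)),
                      stringsAsFactors = FALSE)
  top <- top_quantile(pairs, 0.1)   # keeps 20: all 18 nines + 2 fives
  expect_identical(top$count, 20L)
  # independent sort oracle: ties resolved lexicographically
  ord <- order(-pairs$ftERC, pairs$gene_a, pairs$gene_b)
  expect_identical(top$pairs$gene_a, pairs$gene_a[ord[1:20]])
  tied <- top$pairs[top$pairs$ftERC == 5, ]
  expect_identical(tied$gene_a, c("A019", "A020"))
  # same input, same selection
  expect_identical(top_quantile(pairs, 0.1)$pairs, top$pairs)
})

test_that("occurrence enrichment reproduces the worked fold changes", {
  # 30 focal proteins, top set of 5685 values: O = 552 -> +2.91,
  # O = 526 -> +2.78, O = 8 -> -23.69 (own-T arithmetic)
  counts <- c(552, 526, 8, rep(0, 0))
  rest <- rep((5685 - sum(counts)) %/% 27, 27)
  rest[1] <- rest[1] + (5685 - sum(counts) - sum(rest))
  counts <- c(counts, rest)
  names(counts) <- sprintf("P%02d", 1:30)
  top <- synthetic_top_set(counts)
  expect_identical(top$count, 5685L)
  res <- occurrence_enrichment(top, names(counts))
  expect_equal(unique(res$expected), 5685 / 30)  # 189.5
  expect_equal(round(res$fold[res$protein == "P01"], 2), 2.91)
  expect_equal(round(res$fold[res$protein == "P02"], 2), 2.78)
  expect_equal(round(res$fold[res$protein == "P03"], 2), -23.69)
  expect_identical(res$direction[res$protein == "P01"], "over")
  expect_identical(res$direction[res$protein == "P03"], "under")
})

test_that("O = E gives fold 1, chi-squared 0, p 1; O = 0 flags -Inf", {
  counts <- stats::setNames(rep(10, 5), sprintf("P%d", 1:5))
  res <- occurrence_enrichment(synthetic_top_set(counts), names(counts))
  expect_equal(res$fold, rep(1, 5))
  expect_equal(res$chi2, rep(0, 5))
  expect_equal(res$p, rep(1, 5))
  expect_identical(unique(res$direction), "ns")

  counts0 <- stats::setNames(c(20, 20, 0), sprintf("P%d", 1:3))
  res0 <- occurrence_enrichment(synthetic_top_set(counts0), names(counts0))
  p3 <- res0[res0$protein == "P3", ]
  expect_identical(p3$fold, -Inf)
  expect_true(p3$zero_observed)
})

test_that("signed fold change is never inside (-1, 1)", {
  set.seed(19)
  for (rep in 1:20) {
    counts <- stats::setNames(rpois(8, 30), sprintf("P%d", 1:8))
    counts[counts == 0] <- 1
    res <- occurrence_enrichment(synthetic_top_set(counts), names(counts))
    expect_true(all(abs(res$fold) >= 1))
  }
})

test_that("a pair of two focal members counts for both by default", {
  pairs <- data.frame(gene_a = c("P1", "P1", "P2"),
                      gene_b = c("P2", "Q1", "Q2"),
                      ftERC = c(3, 2, 1), stringsAsFactors = FALSE)
  top <- structure(list(q = 0.5, n_total = 6, count = 3, cutoff = 1,
                        pairs = pairs), class = "top_quantile_set")
  res <- occurrence_enrichment(top, c("P1", "P2"))
  expect_identical(sort(res$observed), c(2L, 2L))     # sum O = 4 > T = 3
  res1 <- occurrence_enrichment(top, c("P1", "P2"), double_count = FALSE)
  expect_identical(sum(res1$observed), 3L)            # sum O = T
})

test_that("exchangeable focal proteins are called significant at ~alpha", {
  # under even representation the per-protein chi-squared is calibrated:
  # simulate 200 multinomial repeats and check the 5% call rate
  set.seed(55)
  K <- 20
  n_rep <- 200
  calls <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    O <- as.vector(stats::rmultinom(1, size = 4000, prob = rep(1 / K, K)))
    counts <- stats::setNames(O, sprintf("P%02d", 1:K))
    counts[counts == 0] <- 1
    res <- occurrence_enrichment(synthetic_top_set(counts), names(counts))
    calls[i] <- mean(res$p < 0.05)
  }
  ci <- stats::qbinom(c(0.005, 0.995), n_rep * K, 0.05) / (n_rep * K)
  expect_gte(mean(calls), ci[1])
  expect_lte(mean(calls), ci[2])
})

test_that("focal pair extraction keeps only pairs touching the focal set", {
  s <- sim_erc(n_genes = 30, species = c(14, 12), seed = 4)
  focal <- s$erc$genes[1:5]
  fp <- focal_pairs(s$erc, focal)
  expect_true(all(fp$gene_a %in% focal | fp$gene_b %in% focal))
  expect_true(all(fp$gene_a < fp$gene_b))
  # count oracle: 5 focal genes against 30 = C(5,2) + 5*25 pairs
  expect_equal(nrow(fp), choose(5, 2) + 5 * 25)
})
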