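test_that("group mean averages scored pairs and skips absent ones", {
  m <- pair_scores(c("A|B" = 1, "A|C" = 2, "B|C" = 3), c("A", "B", "C"))
  erc <- toy_erc(m)
  gm <- group_mean_erc(erc, c("A", "B", "C"))
  expect_equal(gm$mean, 2)
  expect_identical(gm$n_pairs, 3L)

  m2 <- pair_scores(c("A|B" = 1, "A|C" = 3), c("A", "B", "C"))  # B|C absent
  gm2 <- group_mean_erc(toy_erc(m2), c("A", "B", "C"))
  expect_equal(gm2$mean, 2)
  expect_identical(gm2$n_pairs, 2L)

  expect_error(group_mean_erc(erc, "A"), ">= 2 group genes")
  m3 <- pair_scores(c("A|B" = 1), c("A", "B", "C", "D"))
  expect_error(group_mean_erc(toy_erc(m3), c("C", "D")), "no scored pairs")
})

test_that("a constant score matrix gives p = 1", {
  g <- sprintf("G%02d", 1:12)
  m <- matrix(0.7, 12, 12, dimnames = list(g, g))
  res <- permute_within(toy_erc(m), g[1:4], n_perm = 500, seed = 1)
  expect_equal(res$p_empirical, 1)
  expect_false(res$p_is_floor)
  expect_equal(res$observed_mean, 0.7)
})

test_that("one-group permutation p matches exhaustive enumeration", {
  set.seed(23)
  g <- LETTERS[1:6]
  m <- matrix(rnorm(36), 6, 6, dimnames = list(g, g))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  erc <- toy_erc(m)
  grp <- c("A", "B", "C")
  obs <- group_mean_erc(erc, grp)$mean
  combos <- combn(g, 3)
  null_exact <- apply(combos, 2, function(s) group_mean_erc(erc, s)$mean)
  p_exact <- mean(null_exact >= obs)   # over all C(6,3) = 20 groups
  res <- permute_within(erc, grp, n_perm = 20000, seed = 99)
  expect_lt(abs(res$p_empirical - p_exact), 0.02)
})

test_that("permutation results are deterministic given the seed", {
  s <- sim_erc(n_genes = 30, species = c(12, 10), seed = 2)
  r1 <- permute_within(s$erc, s$erc$genes[1:5], n_perm = 300, seed = 42)
  r2 <- permute_within(s$erc, s$erc$genes[1:5], n_perm = 300, seed = 42)
  expect_identical(r1, r2)
  r3 <- permute_within(s$erc, s$erc$genes[1:5], n_perm = 300, seed = 43)
  expect_false(identical(r1$null_mean, r3$null_mean))
})

test_that("p cannot increase when within-group scores are raised", {
  set.seed(8)
  g <- sprintf("G%02d", 1:20)
  m <- matrix(rnorm(400), 20, 20, dimnames = list(g, g))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  grp <- g[1:5]
  p0 <- permute_within(toy_erc(m), grp, n_perm = 2000, seed = 7)$p_empirical
  for (c_shift in c(0.5, 2)) {
    m2 <- m
    m2[grp, grp] <- m2[grp, grp] + c_shift
    p1 <- permute_within(toy_erc(m2), grp, n_perm = 2000, seed = 7)$p_empirical
    expect_lte(p1, p0)
  }
})

test_that("floor p-values are flagged and reported as <1/n_perm", {
  g <- sprintf("G%02d", 1:40)
  set.seed(3)
  m <- matrix(rnorm(1600, 0, 0.5), 40, 40, dimnames = list(g, g))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m[g[1:4], g[1:4]] <- 50   # unbeatable group
  res <- permute_within(toy_erc(m), g[1:4], n_perm = 1000, seed = 1)
  expect_true(res$p_is_floor)
  expect_equal(res$p_empirical, 0)
  expect_identical(res$p_report, "<0.001")
  expect_gt(res$sd_distance, 10)
})

test_that("between-group test rejects identical sets and empty overlap", {
  s <- sim_erc(n_genes = 20, species = c(12, 10), seed = 5)
  g <- s$erc$genes
  expect_error(permute_between(s$erc, g[1:3], g[1:3]), "identical sets")
})

test_that("between-group max-p matches exhaustive enumeration", {
  set.seed(14)
  g <- LETTERS[1:7]
  m <- matrix(rnorm(49), 7, 7, dimnames = list(g, g))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  erc <- toy_erc(m)
  A <- c("A", "B"); B <- c("C", "D")
  obs <- ratecov:::.cross_mean(erc$score, match(A, g), match(B, g))$mean
  # exhaustive enumeration of both replacement schemes
  cross_mean <- function(sa, sb) {
    vals <- c()
    for (a in sa) for (b in sb) if (a != b) {
      key <- paste(sort(c(a, b)), collapse = "|")
      vals[key] <- m[a, b]
    }
    mean(vals)
  }
  reps <- combn(g, 2)
  null_a <- apply(reps, 2, function(s) cross_mean(A, s))   # hold A
  null_b <- apply(reps, 2, function(s) cross_mean(s, B))   # hold B
  p_exact <- max(mean(null_a >= obs), mean(null_b >= obs))
  res <- permute_between(erc, A, B, n_perm = 20000, seed = 6)
  expect_lt(abs(res$p_empirical - p_exact), 0.02)
  expect_length(res$directions, 2)
  expect_gte(res$p_empirical,
             min(res$directions$hold_a$p_empirical,
                 res$directions$hold_b$p_empirical))
})

test_that("linked modules score lower between-set p than random sets", {
  hits <- 0L
  for (seed in 1:6) {
    g <- sprintf("g%04d", 1:60)
    s <- sim_erc(n_genes = 60, species = c(20, 16), seed = seed,
                 modules = list(list(genes = g[1:8], rho = 0.7)))
    p_mod <- permute_between(s$erc, g[1:4], g[5:8], n_perm = 400,
                             seed = seed)$p_empirical
    p_rand <- permute_between(s$erc, g[21:24], g[25:28], n_perm = 400,
                              seed = seed)$p_empirical
    if (p_mod < p_rand) hits <- hits + 1L
  }
  expect_gte(hits, 5L)
})
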