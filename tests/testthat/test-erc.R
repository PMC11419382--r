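# rer_matrix fixture with fully controlled values
make_rer <- function(R, clade = "c1") {
  structure(list(clade_id = clade, genes = rownames(R),
                 branches = colnames(R), rer = R,
                 n_usable = rowSums(!is.na(R))),
            class = "rer_matrix")
}

rand_rer <- function(n_genes, n_branches, seed, clade = "c1") {
  set.seed(seed)
  R <- matrix(rnorm(n_genes * n_branches), n_genes, n_branches,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("b%02d", seq_len(n_branches))))
  make_rer(R - rowMeans(R), clade)
}

test_that("pair correlation handles identity, orthogonality and absence", {
  x <- rnorm(20); x <- x - mean(x)
  y <- c(rep(1, 10), rep(-1, 10))  # orthogonal to a symmetric block design
  xo <- c(rep(2, 10), rep(2, 10)) * y   # proportional to y
  R <- rbind(gA = x, gB = x, gC = y, gD = xo)
  colnames(R) <- sprintf("b%02d", 1:20)
  rer <- make_rer(R)
  expect_equal(clade_pair_stat(rer, "gA", "gB")$r, 1, tolerance = 1e-12)
  expect_equal(clade_pair_stat(rer, "gC", "gD")$r, 1, tolerance = 1e-12)
  # constructed zero-covariance pair: sum(x*y) = 0 by symmetrization
  xs <- c(x[1:10], x[1:10])
  R2 <- rbind(gA = xs, gB = y)
  colnames(R2) <- sprintf("b%02d", 1:20)
  expect_lt(abs(clade_pair_stat(make_rer(R2), "gA", "gB")$r), 1e-12)
  expect_error(clade_pair_stat(rer, "gA", "nope"), "not in RER")
})

test_that("pair correlation equals the textbook formula to 1e-12", {
  rer <- rand_rer(2, 30, seed = 77)
  st <- clade_pair_stat(rer, "g01", "g02")
  x <- rer$rer[1, ]; y <- rer$rer[2, ]
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(st$r, r_direct, tolerance = 1e-12)
  expect_identical(st$n, 30L)
})

test_that("pairs with few shared branches or zero variance are absent", {
  R <- rbind(gA = c(1, -1, 0, NA, NA, NA),
             gB = c(NA, NA, 0, 1, -1, NA),
             gC = c(0, 0, 0, 0, 0, 0),
             gD = c(1, -1, 2, -2, 0, 0))
  colnames(R) <- sprintf("b%d", 1:6)
  rer <- make_rer(R)
  expect_null(clade_pair_stat(rer, "gA", "gB", n_min = 4))  # 1 shared
  expect_null(clade_pair_stat(rer, "gC", "gD", n_min = 4))  # sd = 0
})

test_that("Fisher z matches closed forms, including the clamp", {
  expect_equal(fisher_z(list(r = 0, n = 50)), 0)
  expect_equal(fisher_z(list(r = 0.5, n = 12)), atanh(0.5) * 3,
               tolerance = 1e-12)
  expect_equal(fisher_z(list(r = 0.5, n = 12)), 1.64792, tolerance = 1e-5)
  # r = 1 is clamped to 1 - 1e-6: atanh(1-1e-6) * sqrt(25) = 36.27164
  expect_equal(fisher_z(list(r = 1, n = 28)), 36.27164, tolerance = 1e-4)
  expect_true(is.finite(fisher_z(list(r = -1, n = 28))))
  expect_error(fisher_z(list(r = 0.5, n = 3)), "n >= 4")
})

test_that("Fisher z is monotone in r and in n", {
  rs <- seq(-0.95, 0.95, by = 0.05)
  zs <- vapply(rs, function(r) fisher_z(list(r = r, n = 20)), numeric(1))
  expect_true(all(diff(zs) > 0))
  ns <- c(5, 10, 20, 50, 100)
  zn <- vapply(ns, function(n) fisher_z(list(r = 0.4, n = n)), numeric(1))
  expect_true(all(diff(zn) > 0))
})

test_that("pair integration sums clade scores and flags absent pairs", {
  stats <- list(list(r = tanh(1.2 / sqrt(7)), n = 10),
                list(r = tanh(-0.3 / sqrt(22)), n = 25),
                list(r = tanh(2.0 / 2), n = 7))
  expect_equal(integrate_pair(stats), 1.2 - 0.3 + 2.0, tolerance = 1e-10)
  one <- list(list(r = 0.4, n = 15))
  expect_equal(integrate_pair(one), fisher_z(one[[1]]))
  expect_true(is.na(integrate_pair(list())))
  expect_true(is.na(integrate_pair(list(NULL, NULL))))
})

test_that("matrix construction scores all complete pairs", {
  rers <- list(rand_rer(10, 25, seed = 1, clade = "c1"),
               rand_rer(10, 30, seed = 2, clade = "c2"))
  erc <- build_erc_matrix(rers)
  expect_equal(erc$summary$n_pairs, choose(10, 2))
  expect_identical(erc$score, t(erc$score))                 # symmetry
  expect_true(all(is.na(diag(erc$score))))
  expect_true(all(erc$n_clades[upper.tri(erc$n_clades)] == 2L))
})

test_that("matrix equals pair-by-pair recomputation (compositional oracle)", {
  set.seed(4)
  rers <- lapply(1:3, function(ci) {
    R <- matrix(rnorm(50 * 20), 50, 20,
                dimnames = list(sprintf("g%02d", 1:50),
                                sprintf("b%02d", 1:20)))
    R[sample(length(R), 150)] <- NA
    make_rer(R - rowMeans(R, na.rm = TRUE), sprintf("c%d", ci))
  })
  erc <- build_erc_matrix(rers, n_min = 5)
  genes <- erc$genes
  set.seed(9)
  for (k in 1:40) {
    ij <- sample(length(genes), 2)
    a <- genes[ij[1]]; b <- genes[ij[2]]
    stats <- lapply(rers, function(r) clade_pair_stat(r, a, b, n_min = 5))
    expect_equal(erc_score(erc, a, b), integrate_pair(stats),
                 tolerance = 1e-10)
  }
})

test_that("genes absent from all clades appear in no pairs", {
  rers <- list(rand_rer(8, 20, seed = 3))
  erc <- build_erc_matrix(rers, universe = c(rers[[1]]$genes, "ghost"))
  expect_true(all(is.na(erc$score["ghost", ])))
  expect_error(erc_score(erc, "g01", "g01"), "self-pairs")
})

test_that("significance threshold is mean + k SDs of scored values", {
  # vector with mean exactly 0.12 and SD exactly 1.47
  z <- scale(rnorm(100))  # mean 0, sd 1
  v <- 0.12 + 1.47 * as.numeric(z)
  expect_equal(significance_threshold(v), 0.12 + 2 * 1.47, tolerance = 1e-10)
  expect_equal(significance_threshold(rep(5, 10)), 5)
  expect_error(significance_threshold(3), ">= 2 scored pairs")
  erc <- build_erc_matrix(list(rand_rer(10, 25, seed = 1)))
  vals <- erc$score[upper.tri(erc$score)]
  vals <- vals[!is.na(vals)]
  expect_equal(significance_threshold(erc),
               mean(vals) + 2 * sd(vals), tolerance = 1e-12)
})

test_that("an ERC matrix round-trips through pair records", {
  rers <- list(rand_rer(12, 25, seed = 6, clade = "c1"),
               rand_rer(12, 20, seed = 7, clade = "c2"))
  erc <- build_erc_matrix(rers)
  back <- erc_from_pairs(pair_records(erc))
  expect_identical(back$genes, erc$genes)
  expect_equal(back$score, erc$score, tolerance = 1e-12)
  expect_equal(back$summary$mean, erc$summary$mean, tolerance = 1e-12)
  expect_error(erc_from_pairs(data.frame(gene_a = "A", gene_b = "A",
                                         ftERC = 1)), "self-pairs")
})
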