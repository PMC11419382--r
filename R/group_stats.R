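#' Mean pairwise FtERC within a gene set
#'
#' Mean over scored pairs among the set's members; absent pairs are excluded
#' from both numerator and denominator.
#'
#' @param matrix an `erc_matrix`.
#' @param genes character vector of gene identifiers (>= 2 present in the
#'   matrix).
#' @return list with `mean` and `n_pairs` (count of scored pairs).
#' @export
group_mean_erc <- function(matrix, genes) {
  stopifnot(inherits(matrix, "erc_matrix"))
  idx <- match(unique(genes), matrix$genes)
  idx <- idx[!is.na(idx)]
  if (length(idx) < 2) stop("need >= 2 group genes present in the matrix")
  sub <- matrix$score[idx, idx]
  vals <- sub[upper.tri(sub)]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("no scored pairs within the group")
  list(mean = mean(vals), n_pairs = length(vals))
}

# Internal: fast mean over scored within-group pairs, NA when none scored.
.group_mean <- function(score, idx) {
  sub <- score[idx, idx]
  vals <- sub[upper.tri(sub)]
  m <- mean(vals, na.rm = TRUE)
  if (is.nan(m)) NA_real_ else m
}

# Internal: shared assembly of a permutation_result.
.perm_result <- function(observed, n_pairs, null_means, n_perm, seed) {
  used <- null_means[!is.na(null_means)]
  n_used <- length(used)
  if (!n_used) stop("all permutation draws had zero scored pairs")
  k <- sum(used >= observed)
  p <- k / n_used
  structure(list(observed_mean = observed, n_pairs_observed = n_pairs,
                 null_mean = mean(used), null_sd = stats::sd(used),
                 p_empirical = p, p_is_floor = (k == 0L),
                 p_report = if (k == 0L) sprintf("<%g", 1 / n_used)
                            else sprintf("%g", p),
                 n_perm = n_perm, n_perm_used = n_used, seed = seed,
                 sd_distance = (observed - mean(used)) / stats::sd(used)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> observed mean", signif(x$observed_mean, 4),
      "over", x$n_pairs_observed, "pairs\n  null", signif(x$null_mean, 4),
      "+/-", signif(x$null_sd, 4), "(", x$n_perm, "permutations ) p",
      x$p_report, "(", signif(x$sd_distance, 4), "SD above null )\n")
  invisible(x)
}

#' One-group permutation test for elevated mean ERC
#'
#' The observed within-group mean FtERC is compared to the means of `n_perm`
#' random groups of the same size drawn uniformly (without replacement
#' within a draw) from the whole scored universe. The empirical p-value is
#' the proportion of random groups whose mean is at least the observed mean,
#' so with 100,000 permutations the smallest reportable nonzero p is 1e-5
#' and stronger signals are reported as the floor `"<1e-05"`.
#'
#' By default the universe is every gene with at least one scored pair,
#' including the tested genes themselves; set `exclude_group = TRUE` to
#' draw only from the complement.
#'
#' @param matrix an `erc_matrix`.
#' @param genes the tested gene set (>= 2 present).
#' @param n_perm number of permutations (default 1e5).
#' @param seed integer seed; same inputs and seed give identical results.
#' @param exclude_group drop the tested genes from the sampling universe.
#' @return a `permutation_result`: observed mean and pair count, null mean
#'   and SD, `p_empirical`, `p_is_floor`, `p_report`, `n_perm`, `seed`, and
#'   `sd_distance` (observed minus null mean, in null SDs).
#' @export
permute_within <- function(matrix, genes, n_perm = 100000, seed = 1,
                           exclude_group = FALSE) {
  stopifnot(inherits(matrix, "erc_matrix"), n_perm >= 1)
  obs <- group_mean_erc(matrix, genes)
  m <- length(intersect(unique(genes), matrix$genes))
  universe <- which(rowSums(!is.na(matrix$score)) > 0)
  if (exclude_group)
    universe <- setdiff(universe, match(unique(genes), matrix$genes))
  if (length(universe) < m)
    stop("scored universe (", length(universe),
         ") smaller than group size (", m, ")")
  score <- matrix$score
  null_means <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    .group_mean(score, sample(universe, m)), numeric(1)))
  .perm_result(obs$mean, obs$n_pairs, null_means, n_perm, seed)
}

# Internal: mean FtERC over unordered cross pairs between two index sets
# (self-pairs excluded, overlapping members counted once per unordered pair).
.cross_mean <- function(score, ia, ib) {
  pairs <- unique(rbind(
    cbind(pmin(rep(ia, each = length(ib)), rep(ib, times = length(ia))),
          pmax(rep(ia, each = length(ib)), rep(ib, times = length(ia))))))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (!nrow(pairs)) return(list(mean = NA_real_, n = 0L))
  vals <- score[pairs]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(list(mean = NA_real_, n = 0L))
  list(mean = mean(vals), n = length(vals))
}

#' Two-group permutation test for elevated between-set mean ERC
#'
#' The observed mean FtERC over cross pairs (one gene from each set, self
#' pairs excluded) is tested twice: holding set A fixed while set B is
#' replaced by random genes of the same number, and vice versa, each with
#' `n_perm` draws from the scored universe. The more conservative (higher)
#' of the two empirical p-values is returned, with both sub-results kept.
#'
#' @param matrix an `erc_matrix`.
#' @param set_a,set_b gene sets (distinct; each with >= 1 gene present).
#' @param n_perm permutations per direction (default 1e5).
#' @param seed integer seed.
#' @return a `permutation_result` (the higher-p direction) with the two
#'   directional results in `$directions`.
#' @export
permute_between <- function(matrix, set_a, set_b, n_perm = 100000, seed = 1) {
  stopifnot(inherits(matrix, "erc_matrix"), n_perm >= 1)
  ia <- match(unique(set_a), matrix$genes); ia <- ia[!is.na(ia)]
  ib <- match(unique(set_b), matrix$genes); ib <- ib[!is.na(ib)]
  if (!length(ia) || !length(ib))
    stop("both sets need >= 1 gene present in the matrix")
  if (setequal(ia, ib))
    stop("identical sets: between-set ERC is undefined; use permute_within()")
  obs <- .cross_mean(matrix$score, ia, ib)
  if (obs$n == 0L) stop("no scored cross-pairs between the sets")
  universe <- which(rowSums(!is.na(matrix$score)) > 0)
  score <- matrix$score
  one_direction <- function(held, m_replace, dir_seed) {
    if (length(universe) < m_replace)
      stop("scored universe smaller than replacement set size")
    null_means <- with_seed(dir_seed, vapply(seq_len(n_perm), function(i)
      .cross_mean(score, held, sample(universe, m_replace))$mean,
      numeric(1)))
    .perm_result(obs$mean, obs$n, null_means, n_perm, dir_seed)
  }
  res_a <- one_direction(ia, length(ib), seed)          # hold A, replace B
  res_b <- one_direction(ib, length(ia), seed + 1L)     # hold B, replace A
  out <- if (res_a$p_empirical >= res_b$p_empirical) res_a else res_b
  out$directions <- list(hold_a = res_a, hold_b = res_b)
  out
}
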