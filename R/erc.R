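#' Per-clade pair correlation of RER profiles
#'
#' Pearson correlation between two genes' relative evolutionary rates over
#' the branches present for both, with the count of shared branches. The
#' pair is absent (`NULL`) when fewer than `n_min` branches are shared or
#' either RER vector has zero variance on the shared branches.
#'
#' @param rer an `rer_matrix`.
#' @param gene_a,gene_b gene identifiers (must be rows of `rer`).
#' @param n_min minimum shared branches (default 5; must be >= 4 so the
#'   Fisher transform is defined).
#' @return list with `clade_id`, `r`, `n` — or `NULL` if the pair does not
#'   qualify in this clade.
#' @export
clade_pair_stat <- function(rer, gene_a, gene_b, n_min = 5) {
  stopifnot(inherits(rer, "rer_matrix"), n_min >= 4)
  for (g in c(gene_a, gene_b))
    if (!g %in% rer$genes) stop("gene not in RER matrix: ", g)
  x <- rer$rer[gene_a, ]
  y <- rer$rer[gene_b, ]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < n_min) return(NULL)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NULL)
  list(clade_id = rer$clade_id, r = stats::cor(x, y), n = sum(ok))
}

#' Fisher transformation with branch-count adjustment
#'
#' `z = atanh(r) * sqrt(n - 3)`: the variance-stabilized Fisher z, scaled so
#' that under the null of no covariation each clade's score is approximately
#' standard normal regardless of how many branches contributed. This puts
#' clades with different tree sizes on a common scale, making their scores
#' summable into one integrated FtERC value. `r` is clamped to
#' `+/- r_clamp` so perfectly correlated vectors give a large finite score.
#'
#' @param stat a pair statistic from [clade_pair_stat()] (list with `r`,
#'   `n`), or a plain list with those fields.
#' @param r_clamp clamp for `|r|` (default `1 - 1e-6`).
#' @return the branch-count-adjusted Fisher z (finite scalar).
#' @export
fisher_z <- function(stat, r_clamp = 1 - 1e-6) {
  if (is.null(stat$n) || stat$n < 4) stop("fisher_z needs n >= 4")
  r <- max(min(stat$r, r_clamp), -r_clamp)
  atanh(r) * sqrt(stat$n - 3)
}

#' Integrate a pair's per-clade scores into one FtERC value
#'
#' The integrated FtERC score is the plain sum of the branch-count-adjusted
#' Fisher z scores over all qualifying clades. An empty list returns `NA`
#' (an absent pair — deliberately distinct from a score of 0).
#'
#' @param stats list of [clade_pair_stat()] results (`NULL`s are ignored).
#' @param r_clamp passed to [fisher_z()].
#' @return FtERC sum, or `NA_real_` when no clade qualifies.
#' @export
integrate_pair <- function(stats, r_clamp = 1 - 1e-6) {
  stats <- Filter(Negate(is.null), stats)
  if (!length(stats)) return(NA_real_)
  sum(vapply(stats, fisher_z, numeric(1), r_clamp = r_clamp))
}

#' Build the integrated gene-by-gene FtERC matrix
#'
#' For every unordered gene pair and every clade: Pearson correlation of the
#' two RER profiles over shared branches, Fisher z with branch-count
#' adjustment, then the sum over qualifying clades. Pairs with no
#' qualifying clade are `NA` (absent), never 0.
#'
#' @param rers list of `rer_matrix` objects (one per clade).
#' @param universe gene identifiers to score; default the union of genes
#'   across clades.
#' @param n_min minimum shared branches per clade (default 5).
#' @param r_clamp clamp for `|r|` in the Fisher transform.
#' @return an `erc_matrix`: list with `genes`, `score` (symmetric FtERC
#'   matrix, `NA` diagonal and absent pairs), `clade_z` / `clade_r` /
#'   `clade_n` (per-clade component matrices), `n_clades` (qualifying clades
#'   per pair) and `summary` (mean, sd, min, max, n_pairs over scored
#'   values).
#' @export
build_erc_matrix <- function(rers, universe = NULL, n_min = 5,
                             r_clamp = 1 - 1e-6) {
  stopifnot(length(rers) >= 1, n_min >= 4)
  for (r in rers) stopifnot(inherits(r, "rer_matrix"))
  if (is.null(universe))
    universe <- sort(unique(unlist(lapply(rers, `[[`, "genes"))))
  if (!length(universe)) stop("empty gene universe")
  G <- length(universe)
  clade_ids <- vapply(rers, `[[`, character(1), "clade_id")
  if (anyDuplicated(clade_ids)) stop("duplicate clade ids among RER matrices")
  clade_z <- clade_r <- clade_n <- vector("list", length(rers))
  score <- matrix(0, G, G, dimnames = list(universe, universe))
  n_clades <- matrix(0L, G, G, dimnames = list(universe, universe))
  for (ci in seq_along(rers)) {
    rer <- rers[[ci]]
    keep <- intersect(universe, rer$genes)
    # full-universe RER with NA rows for genes absent from this clade
    M <- matrix(NA_real_, G, length(rer$branches),
                dimnames = list(universe, rer$branches))
    M[keep, ] <- rer$rer[keep, , drop = FALSE]
    tM <- t(M)
    pres <- !is.na(tM)
    n <- crossprod(pres)              # shared branch counts
    suppressWarnings(r <- stats::cor(tM, use = "pairwise.complete.obs"))
    ok <- n >= n_min & !is.na(r)      # zero-variance pairs arrive as NA
    r_cl <- pmax(pmin(r, r_clamp), -r_clamp)
    z <- atanh(r_cl) * sqrt(pmax(n - 3, 0))
    z[!ok] <- NA_real_
    r[!ok] <- NA_real_
    storage.mode(n) <- "integer"
    score <- score + ifelse(ok, z, 0)
    n_clades <- n_clades + ok
    clade_z[[ci]] <- z
    clade_r[[ci]] <- r
    clade_n[[ci]] <- n
  }
  score[n_clades == 0L] <- NA_real_
  diag(score) <- NA_real_
  diag(n_clades) <- 0L
  names(clade_z) <- names(clade_r) <- names(clade_n) <- clade_ids
  vals <- score[upper.tri(score)]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("no gene pair qualified in any clade")
  structure(list(genes = universe, score = score, clade_z = clade_z,
                 clade_r = clade_r, clade_n = clade_n, n_clades = n_clades,
                 n_min = n_min,
                 summary = list(mean = mean(vals), sd = stats::sd(vals),
                                min = min(vals), max = max(vals),
                                n_pairs = length(vals))),
            class = "erc_matrix")
}

#' @export
print.erc_matrix <- function(x, ...) {
  s <- x$summary
  cat("<erc_matrix>", length(x$genes), "genes;", s$n_pairs,
      "scored pairs\n  FtERC mean", signif(s$mean, 3), "sd",
      signif(s$sd, 3), "range [", signif(s$min, 3), ",",
      signif(s$max, 3), "]\n")
  invisible(x)
}

#' Integrated FtERC score of one gene pair
#' @param matrix an `erc_matrix`.
#' @param gene_a,gene_b gene identifiers.
#' @return FtERC value (`NA` if the pair is absent).
#' @export
erc_score <- function(matrix, gene_a, gene_b) {
  stopifnot(inherits(matrix, "erc_matrix"))
  for (g in c(gene_a, gene_b))
    if (!g %in% matrix$genes) stop("gene not in ERC matrix: ", g)
  if (gene_a == gene_b) stop("self-pairs have no ERC score")
  matrix$score[gene_a, gene_b]
}

#' Single-clade score matrix from an integrated ERC matrix
#' @param matrix an `erc_matrix`.
#' @param clade_id which clade's Fisher z component to return.
#' @return symmetric gene x gene matrix of that clade's z scores.
#' @export
clade_score <- function(matrix, clade_id) {
  stopifnot(inherits(matrix, "erc_matrix"))
  if (!clade_id %in% names(matrix$clade_z))
    stop("unknown clade: ", clade_id)
  matrix$clade_z[[clade_id]]
}

#' All scored pairs as PairScoreRecord rows
#'
#' Long-format view of the matrix: one row per scored unordered pair, with a
#' list-column of per-clade components, suitable for [write_pair_table()].
#'
#' @param matrix an `erc_matrix`.
#' @return data.frame with `gene_a`, `gene_b` (lexicographic order),
#'   `ftERC`, and list-column `clades` (data.frames with `clade_id`, `r`,
#'   `n`).
#' @export
pair_records <- function(matrix) {
  stopifnot(inherits(matrix, "erc_matrix"))
  ut <- upper.tri(matrix$score)
  idx <- which(ut & !is.na(matrix$score), arr.ind = TRUE)
  ga <- matrix$genes[idx[, 1]]
  gb <- matrix$genes[idx[, 2]]
  swap <- ga > gb
  tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  clades <- lapply(seq_len(nrow(idx)), function(k) {
    i <- idx[k, 1]; j <- idx[k, 2]
    comp <- lapply(names(matrix$clade_z), function(cl) {
      z <- matrix$clade_z[[cl]][i, j]
      if (is.na(z)) return(NULL)
      data.frame(clade_id = cl, r = matrix$clade_r[[cl]][i, j],
                 n = matrix$clade_n[[cl]][i, j])
    })
    do.call(rbind, Filter(Negate(is.null), comp))
  })
  out <- data.frame(gene_a = ga, gene_b = gb,
                    ftERC = matrix$score[idx], stringsAsFactors = FALSE)
  out$clades <- clades
  out[order(out$gene_a, out$gene_b), ]
}

#' Significance threshold from the score distribution
#'
#' Mean plus `k_sd` standard deviations of all scored FtERC values — the
#' convention under which integrated scores two SDs above the genome-wide
#' mean are called notably elevated. With the genome-wide summary mean 0.12
#' and SD 1.47 this evaluates to 3.06, i.e. the familiar "ERC >= 3" cutoff.
#'
#' @param x an `erc_matrix`, or a numeric vector of scored FtERC values.
#' @param k_sd number of SDs above the mean (default 2).
#' @return the threshold value.
#' @export
significance_threshold <- function(x, k_sd = 2) {
  vals <- if (inherits(x, "erc_matrix")) {
    v <- x$score[upper.tri(x$score)]
    v[!is.na(v)]
  } else as.numeric(x)
  if (length(vals) < 2) stop("need >= 2 scored pairs")
  mean(vals) + k_sd * stats::sd(vals)
}

#' Rebuild an ERC matrix from saved pair records
#'
#' Reconstructs a score matrix (without per-clade components) from a
#' long-format pair table, e.g. one written by [write_pair_table()] and
#' read back with [read_pair_table()]. Group tests, enrichment and the
#' complex benchmark all run on the scores alone, so a saved pair table is
#' enough to resume an analysis.
#'
#' @param records data.frame with `gene_a`, `gene_b`, `ftERC`.
#' @return an `erc_matrix` with empty per-clade component lists.
#' @export
erc_from_pairs <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("gene_a", "gene_b", "ftERC") %in% names(records)))
  if (any(records$gene_a == records$gene_b)) stop("self-pairs in records")
  genes <- sort(unique(c(records$gene_a, records$gene_b)))
  score <- matrix(NA_real_, length(genes), length(genes),
                  dimnames = list(genes, genes))
  score[cbind(records$gene_a, records$gene_b)] <- records$ftERC
  score[cbind(records$gene_b, records$gene_a)] <- records$ftERC
  vals <- score[upper.tri(score)]
  vals <- vals[!is.na(vals)]
  if (length(vals) < 1) stop("no scored pairs")
  structure(list(genes = genes, score = score, clade_z = list(),
                 clade_r = list(), clade_n = list(),
                 n_clades = (!is.na(score)) * 1L, n_min = NA_integer_,
                 summary = list(mean = mean(vals), sd = stats::sd(vals),
                                min = min(vals), max = max(vals),
                                n_pairs = length(vals))),
            class = "erc_matrix")
}
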