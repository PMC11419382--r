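#' Focal-versus-genome pair list
#'
#' All scored pairs with at least one member in the focal set — the score
#' list on which top-quantile enrichment operates (e.g. the 30 GPI anchor
#' synthesis proteins against the whole scored universe).
#'
#' @param matrix an `erc_matrix`.
#' @param focal character vector of focal gene identifiers.
#' @return data.frame with `gene_a`, `gene_b`, `ftERC`, one row per scored
#'   unordered pair containing a focal gene.
#' @export
focal_pairs <- function(matrix, focal) {
  stopifnot(inherits(matrix, "erc_matrix"))
  fi <- match(unique(focal), matrix$genes)
  fi <- fi[!is.na(fi)]
  if (!length(fi)) stop("no focal genes present in the matrix")
  keep <- matrix(FALSE, length(matrix$genes), length(matrix$genes))
  keep[fi, ] <- TRUE
  keep[, fi] <- TRUE
  idx <- which(upper.tri(matrix$score) & keep & !is.na(matrix$score),
               arr.ind = TRUE)
  if (!nrow(idx)) stop("no scored pairs involve the focal set")
  ga <- matrix$genes[idx[, 1]]
  gb <- matrix$genes[idx[, 2]]
  swap <- ga > gb
  tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  data.frame(gene_a = ga, gene_b = gb, ftERC = matrix$score[idx],
             stringsAsFactors = FALSE)
}

#' Top quantile of a pair score list
#'
#' Sorts pairs by descending FtERC and keeps the top `ceiling(q * N)`.
#' Ties at the cutoff are broken deterministically by lexicographic pair
#' identifier, so the same input always yields the same set.
#'
#' @param pairs data.frame with `gene_a`, `gene_b`, `ftERC` (e.g. from
#'   [focal_pairs()] or [pair_records()]).
#' @param q quantile in (0, 1); default 0.01 (the top 1 percent).
#' @return a `top_quantile_set`: list with `q`, `n_total`, `count`
#'   (= ceiling(q * N)), `cutoff` (lowest included score) and `pairs` (the
#'   selected rows, descending score).
#' @export
top_quantile <- function(pairs, q = 0.01) {
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 1, q > 0, q < 1)
  N <- nrow(pairs)
  count <- as.integer(ceiling(q * N))
  ord <- order(-pairs$ftERC, pairs$gene_a, pairs$gene_b)
  top <- pairs[ord[seq_len(count)], , drop = FALSE]
  rownames(top) <- NULL
  structure(list(q = q, n_total = N, count = count,
                 cutoff = top$ftERC[count], pairs = top),
            class = "top_quantile_set")
}

#' @export
print.top_quantile_set <- function(x, ...) {
  cat("<top_quantile_set> top", x$q * 100, "% of", x$n_total, "pairs:",
      x$count, "values, cutoff", signif(x$cutoff, 4), "\n")
  invisible(x)
}

#' Per-protein occurrence enrichment in a top score set
#'
#' Counts how many top pairs each focal protein appears in (`O`; a pair
#' with two focal members counts for both) and compares it to the expected
#' count under even distribution across the `K` focal proteins,
#' `E = T / K` with `T` the top-set size. The signed fold change is `O/E`
#' when `O >= E` and `-(E/O)` otherwise, so it is never in (-1, 1). Each
#' protein gets a one-versus-rest 1-df chi-squared goodness-of-fit test
#' (no continuity correction, raw p-values), and a direction call
#' (`over` / `under` / `ns`) at `p < alpha`.
#'
#' @param top a [top_quantile_set()].
#' @param focal the focal gene set (K >= 2).
#' @param alpha significance level for the direction call (default 0.05).
#' @param double_count count a two-focal pair for both proteins (default
#'   TRUE; with FALSE such a pair increments only the lexicographically
#'   first member).
#' @return an `enrichment_result` data.frame: `protein`, `observed`,
#'   `expected`, `fold`, `chi2`, `p`, `direction`, `zero_observed` (fold is
#'   `-Inf` and flagged when `O = 0`).
#' @export
occurrence_enrichment <- function(top, focal, alpha = 0.05,
                                  double_count = TRUE) {
  stopifnot(inherits(top, "top_quantile_set"))
  focal <- unique(focal)
  K <- length(focal)
  if (K < 2) stop("need >= 2 focal proteins")
  tp <- top$pairs
  in_a <- tp$gene_a %in% focal
  in_b <- tp$gene_b %in% focal
  if (!all(in_a | in_b))
    stop("top set contains pairs without any focal member")
  Tn <- top$count
  O <- stats::setNames(integer(K), focal)
  ca <- table(tp$gene_a[in_a])
  cb <- table(tp$gene_b[in_b])
  O[names(ca)] <- O[names(ca)] + as.integer(ca)
  if (double_count) {
    O[names(cb)] <- O[names(cb)] + as.integer(cb)
  } else {
    only_b <- tp$gene_b[in_b & !in_a]
    cob <- table(only_b)
    O[names(cob)] <- O[names(cob)] + as.integer(cob)
  }
  E <- Tn / K
  fold <- ifelse(O >= E, O / E, -(E / O))
  chi2 <- (O - E)^2 / E + ((Tn - O) - (Tn - E))^2 / (Tn - E)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  direction <- ifelse(p >= alpha, "ns", ifelse(O >= E, "over", "under"))
  res <- data.frame(protein = focal, observed = as.integer(O), expected = E,
                    fold = fold, chi2 = chi2, p = p, direction = direction,
                    zero_observed = O == 0L, stringsAsFactors = FALSE,
                    row.names = NULL)
  res <- res[order(-res$fold), ]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}
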