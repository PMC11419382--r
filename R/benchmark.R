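#' Representation-matched random complexes
#'
#' Simulated null complexes used to calibrate complex-level empirical
#' p-values. Each simulated complex draws its size from the real complexes'
#' size distribution and samples that many distinct genes with probability
#' proportional to each gene's frequency of complex membership, so heavily
#' reused subunits are equally heavily reused in the null.
#'
#' @param real_complexes a `gene_sets` object (or named list) of real
#'   complexes.
#' @param n_sim number of simulated complexes (default 1e5).
#' @param seed integer seed.
#' @param uniform sample genes uniformly instead of
#'   membership-frequency-weighted (sensitivity switch; default FALSE).
#' @return list of character vectors (the simulated complexes), with the
#'   sampled sizes as `attr(, "sizes")`.
#' @export
simulate_null_complexes <- function(real_complexes, n_sim = 100000, seed = 1,
                                    uniform = FALSE) {
  sets <- if (inherits(real_complexes, "gene_sets")) real_complexes$sets
          else real_complexes
  if (n_sim < 1) stop("n_sim must be >= 1")
  if (!length(sets)) stop("no real complexes supplied")
  membership <- table(unlist(sets))
  genes <- names(membership)
  w <- if (uniform) rep(1, length(genes)) else as.numeric(membership)
  sizes_real <- lengths(sets)
  with_seed(seed, {
    sizes <- sample(sizes_real, n_sim, replace = TRUE)
    sims <- lapply(sizes, function(s) sample(genes, s, prob = w))
  })
  attr(sims, "sizes") <- sizes
  sims
}

#' Empirical p-values for real complexes against simulated complexes
#'
#' For each real complex of at least `min_size` genes, the mean pairwise
#' integrated FtERC among its members is compared to the null distribution
#' of mean scores over simulated complexes of the same size (size-stratified,
#' since the variance of a mean over pairs depends on the pair count). The
#' empirical p is the proportion of same-size null complexes with a mean at
#' least as large; zero exceedances are reported at the floor
#' `"<1/n_stratum"`. Benjamini-Hochberg q-values and an FDR-level
#' significance call are attached.
#'
#' @param matrix an `erc_matrix` (or a plain symmetric score matrix, which
#'   lets the same benchmark run on a single clade's z scores).
#' @param complexes a `gene_sets` object of real complexes.
#' @param null_sets simulated complexes from [simulate_null_complexes()].
#' @param min_size minimum complex size (default 3).
#' @param fdr FDR level for the significance call (default 0.05).
#' @return a `complex_benchmark` data.frame: `complex`, `size`, `mean_erc`,
#'   `n_pairs`, `p`, `p_is_floor`, `n_stratum`, `q`, `significant`.
#' @export
complex_empirical_p <- function(matrix, complexes, null_sets, min_size = 3,
                                fdr = 0.05) {
  score <- if (inherits(matrix, "erc_matrix")) matrix$score else matrix
  stopifnot(is.matrix(score), !is.null(rownames(score)))
  sets <- if (inherits(complexes, "gene_sets")) complexes$sets else complexes
  sets <- sets[lengths(sets) >= min_size]
  if (!length(sets)) stop("no complexes of size >= ", min_size)
  set_mean <- function(members) {
    idx <- match(members, rownames(score))
    idx <- idx[!is.na(idx)]
    if (length(idx) < 2) return(c(NA_real_, 0))
    sub <- score[idx, idx]
    vals <- sub[upper.tri(sub)]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) return(c(NA_real_, 0))
    c(mean(vals), length(vals))
  }
  null_sizes <- lengths(null_sets)
  null_means <- vapply(null_sets, function(s) set_mean(s)[1], numeric(1))
  rows <- lapply(names(sets), function(nm) {
    sm <- set_mean(sets[[nm]])
    if (is.na(sm[1])) {
      warning("complex '", nm, "' has no scored pairs; excluded",
              call. = FALSE)
      return(NULL)
    }
    stratum <- null_means[null_sizes == length(sets[[nm]])]
    stratum <- stratum[!is.na(stratum)]
    if (!length(stratum)) {
      warning("no null complexes of size ", length(sets[[nm]]),
              " for complex '", nm, "'; excluded", call. = FALSE)
      return(NULL)
    }
    k <- sum(stratum >= sm[1])
    data.frame(complex = nm, size = length(sets[[nm]]), mean_erc = sm[1],
               n_pairs = as.integer(sm[2]), p = k / length(stratum),
               p_is_floor = k == 0L, n_stratum = length(stratum),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(res)) stop("no complex could be scored")
  # floor p at 1/n_stratum for ranking/FDR purposes (a zero would be exact)
  p_for_fdr <- ifelse(res$p_is_floor, 1 / res$n_stratum, res$p)
  fdr_res <- bh_fdr(p_for_fdr, alpha = fdr)
  res$q <- fdr_res$q
  res$significant <- fdr_res$significant
  rownames(res) <- NULL
  class(res) <- c("complex_benchmark", "data.frame")
  res
}

#' Benjamini-Hochberg step-up FDR
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @param alpha FDR level for the significance call (default 0.05).
#' @return list with `q` (BH-adjusted values, input order), `significant`
#'   (logical) and `n_significant`.
#' @export
bh_fdr <- function(pvals, alpha = 0.05) {
  if (!length(pvals)) stop("empty p-value vector")
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must be in [0, 1]")
  q <- stats::p.adjust(pvals, method = "BH")
  list(q = q, significant = q <= alpha, n_significant = sum(q <= alpha))
}

#' Precision-recall fold-change curves for real-vs-null complex separation
#'
#' Ranks real and simulated complexes together by mean score (descending)
#' and traces precision and recall for recovering the real complexes.
#' Fold-change precision is precision divided by precision at 100 percent
#' recall — the class prevalence, i.e. the precision when every complex is
#' included — so a scorer no better than random sits at fold-change 1.
#' Used to compare integrated FtERC with a single clade's ERC.
#'
#' @param scores_real numeric vector of mean scores for real complexes.
#' @param scores_null numeric vector of mean scores for simulated complexes.
#' @return a `pr_curve` data.frame with one row per rank: `recall`,
#'   `precision`, `fold_change`.
#' @export
precision_recall_foldchange <- function(scores_real, scores_null) {
  if (!length(scores_real) || !length(scores_null))
    stop("both real and null score vectors must be non-empty")
  scores <- c(scores_real, scores_null)
  label <- c(rep(TRUE, length(scores_real)), rep(FALSE, length(scores_null)))
  ord <- order(-scores)
  lab <- label[ord]
  tp <- cumsum(lab)
  precision <- tp / seq_along(lab)
  recall <- tp / length(scores_real)
  # baseline: precision with every complex included (class prevalence),
  # the curve's 100%-recall endpoint
  base <- precision[length(precision)]
  out <- data.frame(recall = recall, precision = precision,
                    fold_change = precision / base)
  class(out) <- c("pr_curve", "data.frame")
  out
}

#' Fold-change precision at a given recall
#'
#' Precision fold-change at the first rank where recall reaches `recall`.
#'
#' @param curve a [precision_recall_foldchange()] result.
#' @param recall target recall in (0, 1].
#' @return the fold-change precision value.
#' @export
pr_fold_at <- function(curve, recall = 0.5) {
  stopifnot(inherits(curve, "pr_curve"), recall > 0, recall <= 1)
  curve$fold_change[which(curve$recall >= recall)[1]]
}
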