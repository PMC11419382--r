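#' Genome-wide master branch profile of a clade
#'
#' The per-branch arithmetic mean branch length over all genes present at
#' that branch — the "genome-wide average" baseline that relative
#' evolutionary rates are measured against. Branches supported by too few
#' genes give an unstable average and are flagged unusable.
#'
#' @param table a `branch_table`.
#' @param min_genes_per_branch minimum contributing genes for a branch to be
#'   usable (default 10).
#' @return a `master_profile`: list with `clade_id`, `mean` (named per-branch
#'   average), `n_genes` (contributing gene count per branch) and `usable`
#'   (logical per branch).
#' @export
master_profile <- function(table, min_genes_per_branch = 10) {
  stopifnot(inherits(table, "branch_table"))
  if (!length(table$genes)) stop("empty branch table")
  n_genes <- colSums(!is.na(table$lengths))
  A <- colMeans(table$lengths, na.rm = TRUE)
  A[n_genes == 0] <- NA_real_
  usable <- n_genes >= min_genes_per_branch
  if (!any(usable))
    stop("all branches unusable at min_genes_per_branch = ",
         min_genes_per_branch)
  structure(list(clade_id = table$clade_id, mean = A, n_genes = n_genes,
                 usable = usable),
            class = "master_profile")
}

#' Relative evolutionary rates by centered log-ratio normalization
#'
#' For each gene and usable branch, `raw[g,b] = log((L[g,b] + epsilon) /
#' (A_b + epsilon))`, then each gene's row is centered to mean zero over its
#' present usable branches. The centering removes the gene's overall rate
#' (a gene twice as fast everywhere has RER identically zero), and the
#' log-ratio removes the shared branch profile, leaving the branch-specific
#' rate deviations whose covariation ERC measures. Genes with fewer than
#' `min_branches` usable present branches are dropped with a warning (the
#' downstream Fisher transform needs `n - 3 >= 1`).
#'
#' @param table a `branch_table`.
#' @param master the clade's [master_profile()].
#' @param epsilon pseudo-length in substitutions/site added to numerator and
#'   denominator so zero-length branches stay informative (default 1e-6).
#' @param min_branches minimum usable present branches per gene (default 4).
#' @return an `rer_matrix`: list with `clade_id`, `genes`, `branches`,
#'   `rer` (genes x branches, `NA` where missing/unusable) and
#'   `n_usable` per gene.
#' @export
compute_rer <- function(table, master, epsilon = 1e-6, min_branches = 4) {
  stopifnot(inherits(table, "branch_table"),
            inherits(master, "master_profile"))
  if (!identical(table$clade_id, master$clade_id))
    stop("clade mismatch: table '", table$clade_id, "' vs master '",
         master$clade_id, "'")
  if (!identical(table$branches, names(master$mean)))
    stop("branch sets of table and master profile differ")
  L <- table$lengths[, master$usable, drop = FALSE]
  A <- master$mean[master$usable]
  raw <- log(sweep(L + epsilon, 2, A + epsilon, "/"))
  n_usable <- rowSums(!is.na(raw))
  drop <- n_usable < min_branches
  if (any(drop)) {
    warning(sum(drop), " gene(s) with < ", min_branches,
            " usable branches dropped in clade '", table$clade_id, "'",
            call. = FALSE)
    raw <- raw[!drop, , drop = FALSE]
    n_usable <- n_usable[!drop]
  }
  if (!nrow(raw)) stop("no genes left after usable-branch filter")
  R <- raw - rowMeans(raw, na.rm = TRUE)
  structure(list(clade_id = table$clade_id, genes = rownames(R),
                 branches = colnames(R), rer = R, n_usable = n_usable),
            class = "rer_matrix")
}

#' @export
print.rer_matrix <- function(x, ...) {
  cat("<rer_matrix> clade:", x$clade_id, "|", length(x$genes), "genes x",
      length(x$branches), "usable branches\n")
  invisible(x)
}
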