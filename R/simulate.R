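#' Simulate a clade master tree
#'
#' Random rooted binary topology via [ape::rtree()] with master branch
#' lengths drawn i.i.d. log-normally, `exp(Normal(log 0.05, 0.5^2))`
#' substitutions/site — a scale typical of the per-branch averages seen in
#' multi-species protein alignments.
#'
#' @param n_species number of tips (>= 3).
#' @param seed integer seed; the same seed reproduces the same tree.
#' @param clade_id label for the resulting clade (default `"sim"`).
#' @return a `clade_tree` with `2 * n_species - 2` branches.
#' @export
simulate_clade_tree <- function(n_species, seed, clade_id = "sim") {
  if (n_species < 3) stop("n_species must be >= 3")
  with_seed(seed, {
    phy <- ape::rtree(n_species, rooted = TRUE)
    phy$edge.length <- exp(rnorm(nrow(phy$edge), log(0.05), 0.5))
    new_clade_tree(phy, clade_id)
  })
}

#' Configuration for the multi-clade branch-length simulator
#'
#' Defaults mirror the canonical five-clade study design (62 mammal, 39
#' vertebrate, 22 drosophila, 18 yeast and 17 nematode species). Coevolving
#' modules are lists of gene ids with a target RER correlation `rho`; genes
#' outside any module have `rho = 0`.
#'
#' @param n_genes number of genes.
#' @param species_per_clade integer vector, one entry per clade.
#' @param modules list of `list(genes = <character>, rho = <0 <= rho < 1>)`.
#'   Members must be disjoint across modules unless `allow_overlap = TRUE`.
#' @param sigma per-branch log-deviation scale (> 0). Default 0.3, giving
#'   gene rates that wander a few tens of percent around the master profile.
#' @param gene_scale_sd SD of the per-gene log overall-rate scalar
#'   (default 0.3): some genes evolve uniformly faster/slower than average.
#' @param missing_prob probability a gene is absent from a clade entirely
#'   (no ortholog there). Default 0.1.
#' @param allow_overlap allow a gene in more than one module.
#' @param seed integer root seed for all randomness.
#' @return a validated `sim_config` list.
#' @export
simulation_config <- function(n_genes = 200,
                              species_per_clade = c(62, 39, 22, 18, 17),
                              modules = list(),
                              sigma = 0.3,
                              gene_scale_sd = 0.3,
                              missing_prob = 0.1,
                              allow_overlap = FALSE,
                              seed = 1) {
  stopifnot(n_genes >= 2, length(species_per_clade) >= 1,
            all(species_per_clade >= 3),
            sigma > 0, gene_scale_sd >= 0,
            missing_prob >= 0, missing_prob <= 1)
  genes <- sprintf("g%04d", seq_len(n_genes))
  all_members <- character(0)
  for (i in seq_along(modules)) {
    m <- modules[[i]]
    if (is.null(m$genes) || is.null(m$rho))
      stop("each module needs $genes and $rho")
    if (m$rho < 0 || m$rho >= 1) stop("module rho must be in [0, 1)")
    bad <- setdiff(m$genes, genes)
    if (length(bad)) stop("module genes outside universe: ",
                          paste(bad, collapse = ", "))
    if (!allow_overlap && length(intersect(m$genes, all_members)))
      stop("modules overlap; set allow_overlap = TRUE to permit")
    all_members <- c(all_members, m$genes)
  }
  structure(list(n_genes = n_genes, genes = genes,
                 species_per_clade = species_per_clade,
                 n_clades = length(species_per_clade),
                 modules = modules, sigma = sigma,
                 gene_scale_sd = gene_scale_sd,
                 missing_prob = missing_prob,
                 allow_overlap = allow_overlap, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate multi-clade branch-length tables with known coevolving modules
#'
#' For clade `c` with master branch lengths `A_b`, gene `g` receives
#' `L[g,b] = A_b * s_g * exp(sigma * d_g[b])` with `log s_g ~ N(0,
#' gene_scale_sd^2)` and `d_g[b] = sqrt(rho_m) * f_m[b] + sqrt(1 - rho_m) *
#' e_g[b]`, where `f_m` is the module's shared per-branch factor (drawn
#' independently per clade) and `e_g` is gene-private; both are i.i.d.
#' standard normal per branch. On the log scale two genes of the same module
#' therefore have RER correlation exactly `rho_m` in expectation, while
#' background genes (`rho = 0`) are independent. Each (gene, clade) row is
#' dropped with probability `missing_prob`, emulating ortholog absence.
#'
#' All randomness derives from `config$seed`; identical configs give
#' byte-identical tables.
#'
#' @param config a [simulation_config()].
#' @return list with `tables` (one `branch_table` per clade), `trees`
#'   (matching `clade_tree`s) and `truth` (module assignment per gene, the
#'   realized shared factors, per-clade gene presence, and the config).
#' @export
simulate_branch_tables <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- config$genes
  module_of <- rep(NA_integer_, config$n_genes)
  names(module_of) <- genes
  rho <- rep(0, config$n_genes)
  names(rho) <- genes
  for (i in seq_along(config$modules)) {
    m <- config$modules[[i]]
    module_of[m$genes] <- i
    rho[m$genes] <- m$rho
  }
  tables <- vector("list", config$n_clades)
  trees <- vector("list", config$n_clades)
  factors <- vector("list", config$n_clades)
  present <- vector("list", config$n_clades)
  clade_ids <- sprintf("clade%02d", seq_len(config$n_clades))
  with_seed(config$seed, {
    s_g <- exp(rnorm(config$n_genes, 0, config$gene_scale_sd))
    tree_seeds <- sample.int(2^31 - 1, config$n_clades)
    for (ci in seq_len(config$n_clades)) {
      tr <- simulate_clade_tree(config$species_per_clade[ci], tree_seeds[ci],
                                clade_ids[ci])
      trees[[ci]] <- tr
      nb <- length(tr$branch_ids)
      # master branch lengths in branch_id order
      A <- tr$tree$edge.length[tr$edge_map[tr$branch_ids]]
      f <- matrix(rnorm(length(config$modules) * nb), nrow = nb)
      e <- matrix(rnorm(config$n_genes * nb), nrow = nb)
      d <- sqrt(1 - rho[col(e)]) * e
      for (i in seq_along(config$modules)) {
        idx <- which(module_of == i)
        d[, idx] <- d[, idx] + sqrt(config$modules[[i]]$rho) * f[, i]
      }
      L <- t(A * exp(config$sigma * d)) * s_g  # genes x branches
      dimnames(L) <- list(genes, tr$branch_ids)
      keep <- runif(config$n_genes) >= config$missing_prob
      if (!any(keep)) keep[1] <- TRUE  # degenerate-config guard
      tables[[ci]] <- new_branch_table(clade_ids[ci],
                                       L[keep, , drop = FALSE])
      factors[[ci]] <- f
      present[[ci]] <- genes[keep]
    }
  })
  names(tables) <- clade_ids
  names(trees) <- clade_ids
  names(factors) <- clade_ids
  names(present) <- clade_ids
  truth <- list(genes = genes, module_of = module_of, rho = rho,
                gene_scale = s_g, shared_factors = factors,
                present = present, config = config)
  list(tables = tables, trees = trees, truth = truth)
}
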