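#' Run the full ERC pipeline from a single configuration
#'
#' Orchestrates the stages in dependency order — simulate (or load)
#' branch-length tables, RER normalization, integrated ERC, then any
#' requested gene-set permutation tests, top-quantile enrichment, and the
#' complex benchmark — writing every stage's output plus a run manifest
#' (inputs, seeds, output hashes) under `out_dir`. Reruns with the same
#' config and seed produce identical output hashes.
#'
#' @param config a list, or path to a YAML file, with elements:
#'   \describe{
#'     \item{out_dir}{output directory (created if needed).}
#'     \item{seed}{root seed; stage seeds are derived from it.}
#'     \item{simulate}{optional list of [simulation_config()] arguments;
#'       when absent, `trees` and `tables` must give per-clade file paths
#'       (named lists: clade id -> Newick / TSV path).}
#'     \item{sets}{optional GMT path; each set gets a one-group
#'       permutation test.}
#'     \item{focal}{optional name of a set in `sets` to use for
#'       top-quantile enrichment.}
#'     \item{complexes}{optional GMT path for the complex benchmark.}
#'     \item{n_min, q, n_perm, n_sim, threshold_k}{tuning knobs with
#'       defaults 5, 0.01, 1000, 1000, 2.}
#'   }
#' @return the run manifest (list), invisibly written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1)
  n_min <- config$n_min %||% 5
  q <- config$q %||% 0.01
  n_perm <- config$n_perm %||% 1000
  n_sim <- config$n_sim %||% 1000
  threshold_k <- config$threshold_k %||% 2
  manifest <- list(seed = seed, stages = list())
  log_stage <- function(name, files) {
    manifest$stages[[name]] <<- list(
      outputs = files,
      md5 = as.list(tools::md5sum(files)))
  }

  # stage 1: obtain branch-length tables
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- seed
    sim_cfg <- do.call(simulation_config, sim_args)
    sim <- simulate_branch_tables(sim_cfg)
    tables <- sim$tables
    trees <- sim$trees
    files <- character(0)
    for (cl in names(tables)) {
      tsv <- file.path(out_dir, paste0(cl, ".branches.tsv"))
      nwk <- file.path(out_dir, paste0(cl, ".nwk"))
      write_branch_table(tables[[cl]], tsv)
      ape::write.tree(trees[[cl]]$tree, nwk)
      files <- c(files, tsv, nwk)
    }
    truth_file <- file.path(out_dir, "truth.json")
    jsonlite::write_json(
      list(module_of = as.list(sim$truth$module_of),
           rho = as.list(sim$truth$rho),
           present = lapply(sim$truth$present, identity)),
      truth_file, auto_unbox = TRUE, digits = NA, null = "null")
    log_stage("simulate", c(files, truth_file))
  } else {
    if (is.null(config$trees) || is.null(config$tables))
      stop("config needs either $simulate or both $trees and $tables")
    for (p in c(unlist(config$trees), unlist(config$tables)))
      if (!file.exists(p)) stop("pre-flight failure: missing input file ", p)
    trees <- lapply(names(config$trees), function(cl)
      read_clade_tree(config$trees[[cl]], cl))
    names(trees) <- names(config$trees)
    tables <- lapply(names(config$tables), function(cl)
      read_branch_table(config$tables[[cl]], trees[[cl]]))
    names(tables) <- names(config$tables)
    log_stage("load", c(unlist(config$trees), unlist(config$tables)))
  }

  # stage 2: RER
  rers <- lapply(tables, function(tb)
    compute_rer(tb, master_profile(tb,
      min_genes_per_branch = config$min_genes_per_branch %||% 10)))
  rer_files <- vapply(names(rers), function(cl) {
    f <- file.path(out_dir, paste0(cl, ".rer.tsv"))
    df <- data.frame(gene = rers[[cl]]$genes, rers[[cl]]$rer,
                     check.names = FALSE)
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    f
  }, character(1))
  log_stage("rer", unname(rer_files))

  # stage 3: integrated ERC
  erc <- build_erc_matrix(rers, n_min = n_min)
  erc_file <- file.path(out_dir, "erc_pairs.tsv")
  write_pair_table(pair_records(erc), erc_file)
  summary_file <- file.path(out_dir, "erc_summary.json")
  thr <- significance_threshold(erc, k_sd = threshold_k)
  jsonlite::write_json(c(erc$summary, list(threshold = thr)),
                       summary_file, auto_unbox = TRUE, digits = NA)
  log_stage("erc", c(erc_file, summary_file))

  # stage 4: gene-set permutation tests
  if (!is.null(config$sets)) {
    gs <- read_gene_sets(config$sets)
    tests <- lapply(names(gs$sets), function(nm) {
      r <- permute_within(erc, gs$sets[[nm]], n_perm = n_perm,
                          seed = seed + 101L)
      list(set = nm, observed_mean = r$observed_mean,
           n_pairs = r$n_pairs_observed, null_mean = r$null_mean,
           null_sd = r$null_sd, p = r$p_report,
           sd_distance = r$sd_distance, n_perm = r$n_perm, seed = r$seed)
    })
    gt_file <- file.path(out_dir, "group_tests.json")
    jsonlite::write_json(tests, gt_file, auto_unbox = TRUE, digits = NA)
    log_stage("group_tests", gt_file)

    # stage 5: enrichment around the focal set
    if (!is.null(config$focal)) {
      focal <- gs$sets[[config$focal]]
      if (is.null(focal)) stop("focal set '", config$focal,
                               "' not found in ", config$sets)
      top <- top_quantile(focal_pairs(erc, focal), q = q)
      enr <- occurrence_enrichment(top, focal)
      enr_file <- file.path(out_dir, "enrichment.tsv")
      utils::write.table(enr, enr_file, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      hm_file <- file.path(out_dir, "focal_heatmap.tsv")
      export_heatmap_matrix(erc, focal, thr, hm_file)
      log_stage("enrichment", c(enr_file, hm_file))
    }
  }

  # stage 6: complex benchmark
  if (!is.null(config$complexes)) {
    cx <- read_gene_sets(config$complexes, min_size = 3)
    nulls <- simulate_null_complexes(cx, n_sim = n_sim, seed = seed + 202L)
    bench <- complex_empirical_p(erc, cx, nulls)
    bench_file <- file.path(out_dir, "complex_benchmark.tsv")
    utils::write.table(bench, bench_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    log_stage("benchmark", bench_file)
  }

  manifest_file <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Export a thresholded square FtERC matrix for heatmap display
#'
#' Square TSV over the given genes in the given order (e.g. pathway order
#' from a gene-set file), with cells below `threshold` masked (empty), the
#' convention used for significant-pair heatmaps.
#'
#' @param matrix an `erc_matrix`.
#' @param genes ordered gene identifiers (all must be in the matrix).
#' @param threshold mask scores below this value (use `-Inf` for the full
#'   matrix).
#' @param path output TSV path.
#' @return the masked matrix, invisibly.
#' @export
export_heatmap_matrix <- function(matrix, genes, threshold, path) {
  stopifnot(inherits(matrix, "erc_matrix"))
  missing <- setdiff(genes, matrix$genes)
  if (length(missing)) stop("genes not in matrix: ",
                            paste(missing, collapse = ", "))
  sub <- matrix$score[genes, genes, drop = FALSE]
  sub[!is.na(sub) & sub < threshold] <- NA_real_
  df <- data.frame(gene = genes, sub, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(sub)
}

#' Export an edge list of strong focal-partner scores
#'
#' TSV edges `(focal, partner, ftERC)` for every scored focal-partner pair
#' at or above `threshold` — the tabular form of an ERC network view.
#' Self-pairs arising from overlapping sets are excluded.
#'
#' @param matrix an `erc_matrix`.
#' @param focal,partners gene sets (non-empty).
#' @param threshold minimum FtERC to include.
#' @param path optional output TSV path.
#' @return data.frame of edges (also written to `path` when given).
#' @export
export_edge_list <- function(matrix, focal, partners, threshold,
                             path = NULL) {
  stopifnot(inherits(matrix, "erc_matrix"),
            length(focal) >= 1, length(partners) >= 1)
  fi <- intersect(unique(focal), matrix$genes)
  pa <- intersect(unique(partners), matrix$genes)
  edges <- expand.grid(focal = fi, partner = pa, stringsAsFactors = FALSE)
  edges <- edges[edges$focal != edges$partner, , drop = FALSE]
  edges$ftERC <- matrix$score[cbind(edges$focal, edges$partner)]
  edges <- edges[!is.na(edges$ftERC) & edges$ftERC >= threshold, ,
                 drop = FALSE]
  edges <- edges[order(-edges$ftERC), ]
  rownames(edges) <- NULL
  if (!is.null(path))
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  edges
}
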