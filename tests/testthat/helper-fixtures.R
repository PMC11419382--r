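# Shared fixtures built in code.

# Minimal erc_matrix around a given symmetric score matrix (NA = absent),
# for tests that need exact control over pair scores.
toy_erc <- function(score, genes = NULL) {
  if (is.null(genes)) genes <- rownames(score) %||% sprintf("G%02d", seq_len(nrow(score)))
  dimnames(score) <- list(genes, genes)
  diag(score) <- NA_real_
  vals <- score[upper.tri(score)]
  vals <- vals[!is.na(vals)]
  structure(list(genes = genes, score = score,
                 clade_z = list(), clade_r = list(), clade_n = list(),
                 n_clades = (!is.na(score)) * 1L, n_min = 5,
                 summary = list(mean = mean(vals), sd = stats::sd(vals),
                                min = min(vals), max = max(vals),
                                n_pairs = length(vals))),
            class = "erc_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Symmetric score matrix from a named pair list, e.g.
# pair_scores(c("A|B" = 1, "A|C" = 2), genes = c("A","B","C"))
pair_scores <- function(scores, genes) {
  m <- matrix(NA_real_, length(genes), length(genes),
              dimnames = list(genes, genes))
  for (nm in names(scores)) {
    ab <- strsplit(nm, "|", fixed = TRUE)[[1]]
    m[ab[1], ab[2]] <- m[ab[2], ab[1]] <- scores[[nm]]
  }
  m
}

# Small multi-clade simulation -> list(erc, truth, rers)
sim_erc <- function(n_genes = 60, species = c(20, 16, 12), modules = list(),
                    seed = 1, missing_prob = 0, ...) {
  cfg <- simulation_config(n_genes = n_genes, species_per_clade = species,
                           modules = modules, missing_prob = missing_prob,
                           seed = seed, ...)
  sim <- simulate_branch_tables(cfg)
  rers <- lapply(sim$tables, function(tb)
    compute_rer(tb, master_profile(tb)))
  list(erc = build_erc_matrix(rers), rers = rers, truth = sim$truth,
       tables = sim$tables, trees = sim$trees)
}

# A synthetic top_quantile_set with prescribed per-protein occurrence
# counts: each pair has exactly one focal member.
synthetic_top_set <- function(counts) {
  stopifnot(!is.null(names(counts)))
  Tn <- sum(counts)
  ga <- rep(names(counts), counts)
  gb <- sprintf("zz_partner_%05d", seq_len(Tn))
  pairs <- data.frame(gene_a = ga, gene_b = gb,
                      ftERC = seq(10, 5, length.out = Tn),
                      stringsAsFactors = FALSE)
  structure(list(q = 0.01, n_total = Tn * 100, count = as.integer(Tn),
                 cutoff = min(pairs$ftERC), pairs = pairs),
            class = "top_quantile_set")
}

# Textbook Benjamini-Hochberg step-up, written independently of the
# package (and of p.adjust): q_i = min_{j >= i} ( n * p_(j) / j ).
bh_textbook <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- rep(NA_real_, n)
  running <- Inf
  for (i in n:1) {
    running <- min(running, n * p[o[i]] / i)
    q_sorted[i] <- min(running, 1)
  }
  q <- numeric(n)
  q[o] <- q_sorted
  q
}
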