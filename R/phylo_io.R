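#' Read a clade master tree from a Newick file
#'
#' Each clade dataset (mammals, vertebrates, flies, yeast, nematodes in the
#' canonical five-clade design) is anchored by one rooted master tree. Every
#' edge receives a stable branch identifier derived from the sorted leaf set
#' of its child node, so identifiers survive re-serialization of the tree:
#' terminal edges are named after their tip, internal edges get a hash of the
#' descendant leaf set prefixed with `"n"`.
#'
#' @param path path to a Newick file containing a single rooted tree. Branch
#'   lengths are optional.
#' @param clade_id short label for the clade (e.g. `"mammals"`).
#' @return a `clade_tree` object: list with `clade_id`, `tree` (an
#'   [ape::read.tree()] phylo), `branch_ids` (sorted character vector, one
#'   per edge) and `edge_map` (named integer index into `tree$edge` rows).
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("(A:1,(B:1,C:1):1);", tf)
#' tr <- read_clade_tree(tf, "demo")
#' length(tr$branch_ids)  # 4 edges
#' @export
read_clade_tree <- function(path, clade_id) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  phy <- tryCatch(suppressWarnings(ape::read.tree(path)),
                  error = function(e) stop("malformed Newick in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(phy)) stop("malformed Newick in ", path)
  if (inherits(phy, "multiPhylo")) phy <- phy[[1]]
  new_clade_tree(phy, clade_id)
}

# Shared constructor: assigns branch ids from child leaf sets.
new_clade_tree <- function(phy, clade_id) {
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf labels in tree for clade '", clade_id, "': ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  ntip <- length(phy$tip.label)
  ids <- character(nrow(phy$edge))
  for (i in seq_len(nrow(phy$edge))) {
    child <- phy$edge[i, 2]
    if (child <= ntip) {
      ids[i] <- phy$tip.label[child]
    } else {
      tips <- sort(phy$tip.label[tips_under(phy, child)])
      ids[i] <- paste0("n", str_hash(paste(tips, collapse = "|")))
    }
  }
  if (anyDuplicated(ids)) stop("branch identifier collision in clade '",
                               clade_id, "'")
  edge_map <- stats::setNames(seq_along(ids), ids)
  structure(list(clade_id = clade_id, tree = phy,
                 branch_ids = sort(ids), edge_map = edge_map),
            class = "clade_tree")
}

# Tip indices descending from an internal node (iterative DFS).
tips_under <- function(phy, node) {
  ntip <- length(phy$tip.label)
  stack <- node
  tips <- integer(0)
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    kids <- phy$edge[phy$edge[, 1] == nd, 2]
    tips <- c(tips, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  tips
}

#' @export
print.clade_tree <- function(x, ...) {
  cat("<clade_tree> clade:", x$clade_id,
      "|", length(x$tree$tip.label), "species,",
      length(x$branch_ids), "branches\n")
  invisible(x)
}

#' Read a genes-by-branches branch-length table
#'
#' The table is TSV with gene identifiers in the first column and one column
#' per branch, headed by the branch identifiers of the clade's master tree.
#' Empty cells encode missing data (a gene absent from a branch); `0` is a
#' legal branch length and is kept distinct from missing.
#'
#' @param path path to the TSV file.
#' @param tree the clade's [read_clade_tree()] object; headers are validated
#'   against its `branch_ids`.
#' @return a `branch_table`: list with `clade_id`, `genes`, `branches` and
#'   `lengths` (genes x branches numeric matrix, `NA` = missing).
#' @export
read_branch_table <- function(path, tree) {
  stopifnot(inherits(tree, "clade_tree"))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "")
  if (ncol(df) < 2) stop("branch table needs a gene column plus >=1 branch")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) stop("duplicate gene ids in ", path)
  branches <- colnames(df)[-1]
  unknown <- setdiff(branches, tree$branch_ids)
  if (length(unknown))
    stop("branch ids not in clade '", tree$clade_id, "' tree: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE))
    stop("negative branch lengths in ", path)
  dimnames(m) <- list(genes, branches)
  new_branch_table(tree$clade_id, m)
}

new_branch_table <- function(clade_id, lengths) {
  structure(list(clade_id = clade_id, genes = rownames(lengths),
                 branches = colnames(lengths), lengths = lengths),
            class = "branch_table")
}

#' Write a branch-length table as TSV (missing entries as empty cells)
#' @param table a `branch_table`.
#' @param path output path.
#' @export
write_branch_table <- function(table, path) {
  stopifnot(inherits(table, "branch_table"))
  df <- data.frame(gene = table$genes, table$lengths, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @export
print.branch_table <- function(x, ...) {
  cat("<branch_table> clade:", x$clade_id, "|", length(x$genes), "genes x",
      length(x$branches), "branches;",
      sum(is.na(x$lengths)), "missing entries\n")
  invisible(x)
}

#' Read gene sets (pathways, complexes) from a GMT file
#'
#' GMT: one set per line, tab-separated `name`, `description`, members.
#' Members are deduplicated (with a warning); empty sets and duplicated set
#' names are errors.
#'
#' @param path path to the GMT file.
#' @param min_size drop sets smaller than this after deduplication
#'   (default 1 keeps everything; complex benchmarking uses 3).
#' @return a `gene_sets` object: list with `sets` (named list of character
#'   vectors) and `description` (named character vector).
#' @export
read_gene_sets <- function(path, min_size = 1) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no gene sets in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nm))
    stop("duplicate gene-set names in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  desc <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else "",
                 character(1))
  sets <- lapply(parts, function(p) {
    mem <- p[-(1:2)]
    mem <- mem[nzchar(mem)]
    if (!length(mem)) stop("empty gene set '", p[[1]], "' in ", path)
    if (anyDuplicated(mem)) {
      warning("duplicated members deduplicated in set '", p[[1]], "'",
              call. = FALSE)
      mem <- unique(mem)
    }
    mem
  })
  names(sets) <- nm
  names(desc) <- nm
  keep <- lengths(sets) >= min_size
  structure(list(sets = sets[keep], description = desc[keep]),
            class = "gene_sets")
}

#' Write gene sets to a GMT file
#' @param gs a `gene_sets` object (or plain named list of character vectors).
#' @param path output path.
#' @export
write_gene_sets <- function(gs, path) {
  sets <- if (inherits(gs, "gene_sets")) gs$sets else gs
  desc <- if (inherits(gs, "gene_sets")) gs$description
          else stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]] %||% "", sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_sets <- function(x, ...) {
  cat("<gene_sets>", length(x$sets), "sets; sizes",
      paste(range(lengths(x$sets)), collapse = "-"), "\n")
  invisible(x)
}

#' Write pairwise FtERC records as a long-format TSV
#'
#' Records are canonicalized so `gene_a < gene_b` lexicographically and each
#' unordered pair is stored once. Per-clade components (clade id, Pearson r,
#' shared branch count) are serialized into a JSON column, so
#' `read_pair_table()` round-trips the full record.
#'
#' @param records data.frame with columns `gene_a`, `gene_b`, `ftERC` and
#'   optionally `clades` (list-column of per-clade component data.frames, or
#'   JSON strings).
#' @param path output TSV path.
#' @export
write_pair_table <- function(records, path) {
  stopifnot(is.data.frame(records),
            all(c("gene_a", "gene_b", "ftERC") %in% names(records)))
  if (any(records$gene_a == records$gene_b))
    stop("self-pairs are not allowed in a pair table")
  swap <- records$gene_a > records$gene_b
  if (any(swap)) {
    tmp <- records$gene_a[swap]
    records$gene_a[swap] <- records$gene_b[swap]
    records$gene_b[swap] <- tmp
  }
  clades_json <- if ("clades" %in% names(records)) {
    if (is.character(records$clades)) records$clades
    else vapply(records$clades, function(cl)
      as.character(jsonlite::toJSON(cl, digits = NA)), character(1))
  } else rep("[]", nrow(records))
  out <- data.frame(gene_a = records$gene_a, gene_b = records$gene_b,
                    ftERC = records$ftERC, clades = clades_json,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pair table written by [write_pair_table()]
#' @param path TSV path.
#' @return data.frame with `gene_a`, `gene_b`, `ftERC` and list-column
#'   `clades` of per-clade component data.frames.
#' @export
read_pair_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "")
  df$clades <- lapply(df$clades, function(s)
    as.data.frame(jsonlite::fromJSON(s)))
  df
}
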