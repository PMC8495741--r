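# Single tabular dialect everywhere: tab-separated, UTF-8, header row.

#' Read a tab-separated table
#'
#' @param path Path to a TSV file with a header row.
#' @return A `data.frame` with columns as stored (no name mangling).
#' @export
read_tsv_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "")
}

#' Write a tab-separated table
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

## ---------------------------------------------------------------------------
## Subfamily alignments
## ---------------------------------------------------------------------------

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")
GAP <- "-"

#' Construct a two-subfamily alignment
#'
#' An alignment of two labeled paralog subfamilies (group "A", e.g. Mlh3-like,
#' and group "B", e.g. Pms1-like), stored as a character matrix of aligned
#' residues. Ambiguous residues (B, Z, X) and unknown symbols are coerced to
#' the gap character `-`; scoring functions ignore gaps.
#'
#' @param seqs Named character vector of aligned sequences (equal lengths).
#' @param groups Named character vector mapping every sequence id to "A" or
#'   "B"; both groups must be non-empty.
#' @return An object of class `subfam_aln`: a character matrix (rows =
#'   sequences, columns = alignment positions) with a `groups` attribute.
#' @export
subfamily_alignment <- function(seqs, groups) {
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("sequences must be named")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequences have unequal lengths")
  ids <- names(seqs)
  missing <- setdiff(ids, names(groups))
  if (length(missing))
    stop("unlabeled sequence id(s): ", paste(missing, collapse = ", "))
  unknown <- setdiff(names(groups), ids)
  if (length(unknown))
    stop("group label for unknown id(s): ", paste(unknown, collapse = ", "))
  groups <- groups[ids]
  if (!all(groups %in% c("A", "B")))
    stop("group labels must be 'A' or 'B'")
  if (!all(c("A", "B") %in% groups))
    stop("both groups must be non-empty")
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  rownames(m) <- ids
  m[!(m %in% AA_ALPHABET)] <- GAP   # gaps, B/Z/X, '.' etc.
  structure(m, groups = groups, class = c("subfam_aln", "matrix", "array"))
}

#' @export
print.subfam_aln <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("subfam_aln: %d sequences (%d in A, %d in B) x %d columns\n",
              nrow(x), sum(g == "A"), sum(g == "B"), ncol(x)))
  invisible(x)
}

#' Group labels of an alignment
#' @param aln A `subfam_aln`.
#' @return Named character vector of "A"/"B" labels.
#' @export
alignment_groups <- function(aln) attr(aln, "groups")

#' Read a FASTA alignment with subfamily labels
#'
#' @param path FASTA file of aligned amino-acid sequences (all records the
#'   same length).
#' @param group_map Named character vector: sequence id -> "A" or "B". Every
#'   record must be labeled.
#' @return A [subfamily_alignment()] object.
#' @export
read_fasta_alignment <- function(path, group_map) {
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  widths <- Biostrings::width(ss)
  if (length(unique(widths)) != 1L)
    stop("ragged alignment: FASTA records have unequal lengths")
  seqs <- as.character(ss)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  subfamily_alignment(seqs, group_map)
}

#' Write an alignment to FASTA
#' @param aln A `subfam_aln`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  ss <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Gene trees on a shared master topology
## ---------------------------------------------------------------------------

# Tip set below the child node of every edge.
edge_tip_sets <- function(tree) {
  n_node <- max(tree$edge)
  sets <- vector("list", n_node)
  for (i in seq_along(tree$tip.label)) sets[[i]] <- tree$tip.label[i]
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  lapply(seq_len(nrow(tree$edge)), function(k) sets[[tree$edge[k, 2L]]])
}

# Canonical bipartition key for a tip subset, relative to taxon set `taxa`.
# The side not containing the alphabetically first taxon is the key; trivial
# bipartitions give NA. Branch identity is therefore rooting-invariant.
canonical_key <- function(side, taxa) {
  side <- sort(side)
  taxa <- sort(taxa)
  if (taxa[1L] %in% side) side <- setdiff(taxa, side)
  if (length(side) == 0L || length(side) == length(taxa)) return(NA_character_)
  paste(side, collapse = "|")
}

# Per-edge canonical bipartition keys of a (possibly rooted) tree.
edge_keys <- function(tree, taxa = tree$tip.label) {
  sets <- edge_tip_sets(tree)
  vapply(sets, canonical_key, character(1L), taxa = taxa)
}

#' Map the branches of a pruned master topology back to master branches
#'
#' Restricting the master topology to a taxon subset merges runs of master
#' branches into single branches of the pruned tree; the pruned branch length
#' is the sum of the merged master branch lengths. This function reports, for
#' every branch of the master tree, the bipartition key it induces on the
#' subset and how many master branches share that key (the merged-path size).
#'
#' @param master A `phylo` tree.
#' @param taxa Character vector, a subset of `master$tip.label` (>= 3 taxa).
#' @return A data frame with columns `master_key`, `restricted_key`,
#'   `n_merged` (one row per non-trivial master branch).
#' @export
prune_branch_map <- function(master, taxa) {
  stopifnot(all(taxa %in% master$tip.label), length(taxa) >= 3L)
  master <- ape::unroot(master)
  mk <- edge_keys(master)
  sets <- edge_tip_sets(master)
  rk <- vapply(sets, function(s) canonical_key(intersect(s, taxa), taxa),
               character(1L))
  keep <- !is.na(mk)
  df <- data.frame(master_key = mk[keep], restricted_key = rk[keep],
                   stringsAsFactors = FALSE)
  tab <- table(df$restricted_key[!is.na(df$restricted_key)])
  df$n_merged <- ifelse(is.na(df$restricted_key), NA_integer_,
                        as.integer(tab[df$restricted_key]))
  df
}

# Branch-length vector of one gene tree keyed by master bipartition keys.
# A master branch gets a value only when it is the unique master branch
# matching the gene branch (merged paths after pruning are reported NA: no
# imputation of fused lengths onto individual master branches).
match_branch_lengths <- function(gene_tree, master, master_keys) {
  if (is.null(gene_tree$edge.length) || anyNA(gene_tree$edge.length))
    stop("missing branch length in gene tree")
  if (any(gene_tree$edge.length < 0))
    stop("negative branch length in gene tree")
  extra <- setdiff(gene_tree$tip.label, master$tip.label)
  if (length(extra))
    stop("gene tree has taxa absent from the master topology: ",
         paste(extra, collapse = ", "))
  taxa <- gene_tree$tip.label
  if (length(taxa) < 3L) stop("gene tree must have at least 3 taxa")
  gu <- ape::unroot(gene_tree)
  gk <- edge_keys(gu, taxa)
  glen <- gu$edge.length
  # collapse the duplicate key a rooted input would create
  gene_vals <- tapply(glen, gk, sum)
  pm <- ape::unroot(ape::keep.tip(master, taxa))
  pmk <- unique(edge_keys(pm, taxa))
  pmk <- pmk[!is.na(pmk)]
  gkeys <- names(gene_vals)[!is.na(names(gene_vals))]
  if (!setequal(gkeys, pmk))
    stop("gene tree topology conflicts with the master topology after pruning")
  map <- prune_branch_map(master, taxa)
  out <- rep(NA_real_, length(master_keys))
  names(out) <- master_keys
  uniq <- map[!is.na(map$restricted_key) & map$n_merged == 1L, , drop = FALSE]
  out[uniq$master_key] <- as.numeric(gene_vals[uniq$restricted_key])
  out
}

#' Construct a gene-tree set on a master topology
#'
#' @param master A `phylo` master (species) topology with branch lengths.
#' @param trees Named list of `phylo` gene/domain trees, each with branch
#'   lengths and a taxon set that is a subset of the master's; topologies must
#'   agree with the master after pruning.
#' @return An object of class `gene_tree_set` with elements `master` (unrooted
#'   `phylo`), `branch_keys` (canonical bipartition key per master branch),
#'   `branches` (branch x gene numeric matrix, NA for branches a gene lacks),
#'   and `trees` (the input trees).
#' @export
gene_tree_set <- function(master, trees) {
  if (!inherits(master, "phylo")) stop("master must be a phylo tree")
  master <- ape::unroot(master)
  if (is.null(master$edge.length) || anyNA(master$edge.length))
    stop("master topology must have branch lengths")
  keys <- edge_keys(master)
  branch_keys <- unname(keys[!is.na(keys)])
  if (anyDuplicated(branch_keys)) stop("master topology has duplicate branches")
  if (is.null(names(trees)))
    names(trees) <- paste0("gene", seq_along(trees))
  branches <- vapply(trees, match_branch_lengths, numeric(length(branch_keys)),
                     master = master, master_keys = branch_keys)
  if (is.null(dim(branches)))
    branches <- matrix(branches, ncol = length(trees),
                       dimnames = list(branch_keys, names(trees)))
  structure(list(master = master, branch_keys = branch_keys,
                 branches = branches, trees = trees),
            class = "gene_tree_set")
}

#' @export
print.gene_tree_set <- function(x, ...) {
  cat(sprintf("gene_tree_set: %d genes on a %d-taxon master (%d branches)\n",
              ncol(x$branches), length(x$master$tip.label),
              length(x$branch_keys)))
  invisible(x)
}

#' Read newick gene trees against a master topology
#'
#' @param path File of newick trees (one per line or a multi-tree file).
#' @param master Master topology: a `phylo` object or a path to a newick file.
#' @return A [gene_tree_set()].
#' @export
read_newick_trees <- function(path, master) {
  if (is.character(master)) master <- ape::read.tree(master)
  trees <- ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- list(gene1 = trees)
  trees <- as.list(trees)
  if (is.null(names(trees)) || any(names(trees) == ""))
    names(trees) <- paste0("gene", seq_along(trees))
  gene_tree_set(master, trees)
}

#' Write a gene-tree set to newick
#' @param gtset A `gene_tree_set`.
#' @param path Output newick file (one tree per line, in gene order).
#' @return `path`, invisibly.
#' @export
write_newick_trees <- function(gtset, path) {
  trees <- gtset$trees
  class(trees) <- "multiPhylo"
  ape::write.tree(trees, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Fluctuation-assay culture tables and tetrad tables
## ---------------------------------------------------------------------------

#' Validate a fluctuation-assay culture table
#'
#' @param df Data frame with columns `strain`, `revertants` (non-negative
#'   integer r_i), `viable` (positive count N_i, cells); optional `batch`.
#' @return The validated data frame (class `culture_table` prepended).
#' @export
culture_table <- function(df) {
  need <- c("strain", "revertants", "viable")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("culture table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$revertants < 0)) stop("negative revertant count")
  if (any(df$revertants != round(df$revertants)))
    stop("revertant counts must be integers")
  if (any(df$viable <= 0)) stop("viable counts must be positive")
  if (any(df$revertants > df$viable))
    stop("revertant count exceeds viable count")
  if (!inherits(df, "culture_table"))
    class(df) <- c("culture_table", class(df))
  df
}

#' Read a culture table from TSV
#' @param path TSV with header (`strain`, `revertants`, `viable`, optional
#'   `batch`).
#' @return A [culture_table()].
#' @export
read_culture_table <- function(path) culture_table(read_tsv_table(path))

#' Write a culture table to TSV
#' @param ct A culture table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_culture_table <- function(ct, path) write_tsv_table(ct, path)

#' Validate a tetrad count table
#'
#' @param df Data frame with columns `genotype`, `TT` (tetratype count), `PD`
#'   (parental ditype count).
#' @return The validated data frame with an `n` column (TT + PD), class
#'   `tetrad_table`.
#' @export
tetrad_table <- function(df) {
  need <- c("genotype", "TT", "PD")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("tetrad table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$TT < 0) || any(df$PD < 0)) stop("negative tetrad counts")
  df$n <- df$TT + df$PD
  if (any(df$n <= 0)) stop("each genotype needs at least one scored tetrad")
  if (!inherits(df, "tetrad_table"))
    class(df) <- c("tetrad_table", class(df))
  df
}

#' Read a tetrad table from TSV
#' @param path TSV with header (`genotype`, `TT`, `PD`).
#' @return A [tetrad_table()].
#' @export
read_tetrad_table <- function(path) tetrad_table(read_tsv_table(path))

#' Write a tetrad table to TSV
#' @param tt A tetrad table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tetrad_table <- function(tt, path) write_tsv_table(tt, path)
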