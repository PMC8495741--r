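# In-code fixtures shared across test files.

toy_alignment <- function() {
  # 4 + 4 sequences, 8 columns: col 1 separates the groups perfectly,
  # col 2 is constant, col 3 noisy within groups, the rest background
  seqs <- c(
    a1 = "KAGLMKRS",
    a2 = "KAGLMKRT",
    a3 = "KATLMKRS",
    a4 = "KAGLMKRS",
    b1 = "TAGLMKRS",
    b2 = "TAGLMKRT",
    b3 = "TATLMKRS",
    b4 = "TAGLMKRS")
  groups <- setNames(rep(c("A", "B"), each = 4L), names(seqs))
  subfamily_alignment(seqs, groups)
}

four_taxon_master <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

# a profile pair with identical branch keys, for direct erc tests
fake_profile <- function(gene, values) {
  names(values) <- paste0("b", seq_along(values))
  structure(list(gene = gene, rer = values, beta = 1,
                 branches = names(values)),
            class = "rer_profile")
}

ref_gene_set <- function(gtset) {
  genes <- grep("^ref", colnames(gtset$branches), value = TRUE)
  structure(list(master = gtset$master, branch_keys = gtset$branch_keys,
                 branches = gtset$branches[, genes, drop = FALSE],
                 trees = gtset$trees[genes]),
            class = "gene_tree_set")
}
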