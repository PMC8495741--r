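# Independent oracles, deliberately written as plain loops over sorted copies
# so they share no code path with the package implementations.

# rank-and-clip Winsorization: two most extreme values per tail replaced by
# the third order statistic of that tail
oracle_winsorize <- function(x) {
  fin <- which(is.finite(x))
  if (length(fin) < 5L) return(x)
  v <- x[fin]
  if (length(unique(v)) < 3L) return(x)
  out <- x
  sv <- sort(v, decreasing = TRUE)
  tmp <- v
  for (k in 1:2) {
    i <- which.max(tmp)
    out[fin[i]] <- min(v[i], sv[3L])
    tmp[i] <- -Inf
  }
  tmp <- v
  for (k in 1:2) {
    i <- which.min(tmp)
    out[fin[i]] <- max(v[i], sv[length(sv) - 2L])
    tmp[i] <- Inf
  }
  out
}

# Jensen-Shannon divergence by direct summation over the residue alphabet
oracle_sh <- function(resA, resB) {
  alphabet <- sort(unique(c(resA, resB)))
  pA <- sapply(alphabet, function(r) mean(resA == r))
  pB <- sapply(alphabet, function(r) mean(resB == r))
  m <- (pA + pB) / 2
  kl <- function(p, q) {
    s <- 0
    for (i in seq_along(p)) if (p[i] > 0)
      s <- s + as.numeric(p[i]) * log2(as.numeric(p[i]) / as.numeric(q[i]))
    s
  }
  1 - (kl(pA, m) + kl(pB, m)) / 2
}

# exact multi-RELIEF expectation: enumerate every (sampled sequence, hit,
# miss) outcome with uniform tie-breaking
oracle_mr_expectation <- function(aln) {
  m <- unclass(aln)
  g <- alignment_groups(aln)
  n <- nrow(m)
  L <- ncol(m)
  sim <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    sim[i, j] <- sum(m[i, ] == m[j, ])
  w <- numeric(L)
  for (s in seq_len(n)) {
    hits <- setdiff(which(g == g[s]), s)
    misses <- which(g != g[s])
    hit_ties <- hits[sim[s, hits] == max(sim[s, hits])]
    miss_ties <- misses[sim[s, misses] == max(sim[s, misses])]
    miss_term <- rep(0, L)
    for (mm in miss_ties) miss_term <- miss_term + (m[s, ] != m[mm, ]) / length(miss_ties)
    hit_term <- rep(0, L)
    for (hh in hit_ties) hit_term <- hit_term + (m[s, ] != m[hh, ]) / length(hit_ties)
    w <- w + (miss_term - hit_term) / n
  }
  w
}

# textbook Pearson chi-squared on a 2x2 table
oracle_chi2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Benjamini-Hochberg step-up by explicit search for the largest k
oracle_bh <- function(p, q) {
  m <- length(p)
  s <- sort(p)
  k <- 0
  for (i in seq_len(m)) if (s[i] <= i * q / m) k <- i
  if (k == 0) return(list(significant = rep(FALSE, m), cutoff = NA_real_))
  list(significant = p <= s[k], cutoff = s[k])
}

# restricted-bipartition enumeration: expected unique master-branch values of
# a gene tree equal to the master pruned to `taxa`
oracle_pruned_values <- function(master, taxa) {
  master <- ape::unroot(master)
  e <- master$edge
  len <- master$edge.length
  tipsets <- lapply(seq_len(nrow(e)), function(k) {
    below <- function(node) {
      if (node <= length(master$tip.label)) return(master$tip.label[node])
      unlist(lapply(e[e[, 1] == node, 2], below))
    }
    below(e[k, 2])
  })
  canon <- function(side, tx) {
    side <- sort(intersect(side, tx))
    tx <- sort(tx)
    if (length(side) && tx[1] %in% side) side <- setdiff(tx, side)
    if (length(side) == 0 || length(side) == length(tx)) return(NA_character_)
    paste(side, collapse = "|")
  }
  full_keys <- sapply(tipsets, canon, tx = master$tip.label)
  restr_keys <- sapply(tipsets, canon, tx = taxa)
  out <- rep(NA_real_, sum(!is.na(full_keys)))
  names(out) <- full_keys[!is.na(full_keys)]
  for (key in unique(restr_keys[!is.na(restr_keys)])) {
    members <- which(!is.na(restr_keys) & restr_keys == key & !is.na(full_keys))
    if (length(members) == 1L)
      out[full_keys[members]] <- len[members]
  }
  out
}
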