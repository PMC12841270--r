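# Shared fixtures and independent oracles for the test suite.

# Overlapping occurrence count via a perl lookahead — a different route
# from the package's substring scan.
regex_occurrences <- function(word, motif) {
  hits <- gregexpr(paste0("(?=", motif, ")"), word, perl = TRUE)[[1L]]
  sum(hits > 0L)
}

# Random DNA word, optionally salted with ambiguous bases.
random_word <- function(len, n_prob = 0) {
  alphabet <- c("A", "C", "G", "T")
  chars <- sample(alphabet, len, replace = TRUE)
  if (n_prob > 0) {
    mask <- runif(len) < n_prob
    chars[mask] <- "N"
  }
  paste(chars, collapse = "")
}

# A count table with random counts (not derived from any sequence).
random_count_table <- function(k = 8, lambda = 15) {
  counts <- stats::rpois(4^k, lambda)
  tab <- count_kmers(Biostrings::DNAStringSet(), k)  # empty scaffold
  tab$counts[] <- counts
  tab$total_windows <- sum(counts)
  tab
}

write_temp_fasta <- function(lines, gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".fa.gz" else ".fa")
  con <- if (gz) gzfile(path, "wt") else file(path, "wt")
  writeLines(lines, con)
  close(con)
  path
}

# Random unrooted binary tree with positive branch lengths; its cophenetic
# (path-length) matrix is additive by construction.
random_additive_tree <- function(n) {
  tr <- ape::unroot(ape::rtree(n))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 2)
  tr
}

# All non-trivial bipartition sides of an unrooted tree, as sorted label sets.
tree_splits <- function(tree) {
  pp <- ape::prop.part(tree)
  sides <- lapply(pp[-1L], function(idx) sort(tree$tip.label[idx]))
  unique(sides)
}

has_bipartition <- function(tree, side) {
  side <- sort(side)
  other <- sort(setdiff(tree$tip.label, side))
  any(vapply(tree_splits(tree),
             function(s) identical(s, side) || identical(s, other),
             logical(1)))
}
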