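# Motif-content partitions of the complete k-mer set.
#
# Every k-mer is assigned to class 0, 1 or 2 by its number of occurrences of
# a short motif (dinucleotide or trinucleotide), with overlaps allowed and
# class 2 meaning "two or more". Overlap counting is the convention under
# which the class cardinalities match their combinatorial values (e.g.
# exactly one overlapping "AA" in an 8-mer: 14,931 of the 65,536).

#' Count overlapping occurrences of a motif in a word
#'
#' Number of start positions at which `motif` matches inside `word`,
#' overlaps allowed (so `"AAAAAAAA"` contains seven `"AA"`).
#'
#' @param word DNA word (character scalar).
#' @param motif Motif text, `nchar(motif) <= nchar(word)`.
#' @return Non-negative integer occurrence count.
#' @examples
#' count_overlapping("ACACACACA", "ACA")  # 4, overlap at shift 2
#' @export
count_overlapping <- function(word, motif) {
  stopifnot(is.character(word), length(word) == 1L,
            is.character(motif), length(motif) == 1L,
            nchar(motif) <= nchar(word))
  m <- nchar(motif)
  starts <- seq_len(nchar(word) - m + 1L)
  sum(substring(word, starts, starts + m - 1L) == motif)
}

#' Classify a word by motif content
#'
#' @inheritParams count_overlapping
#' @return 0 (no occurrence), 1 (exactly one) or 2 (two or more).
#' @export
classify_word <- function(word, motif) {
  min(count_overlapping(word, motif), 2L)
}

# Occurrence counts of `motif` in every k-mer 0..4^k-1, computed
# arithmetically: the m-wide window at each of the k-m+1 positions of a
# k-mer index is a base-4 digit slice, compared against the motif's code.
motif_occurrences <- function(motif, k) {
  m <- nchar(motif)
  code <- encode_kmer(motif)
  v <- as.numeric(0:(4^k - 1))
  occ <- integer(4^k)
  for (p in seq_len(k - m + 1L)) {
    occ <- occ + ((v %/% 4^(k - m - p + 1L)) %% 4^m == code)
  }
  occ
}

#' Partition all k-mers by motif content
#'
#' Assigns every one of the `4^k` k-mers the label 0, 1 or 2 for zero /
#' exactly one / two-or-more overlapping occurrences of `motif`. The three
#' classes partition the complete k-mer set; their sizes are combinatorial
#' constants of the motif's self-overlap structure (e.g. for `"CG"` at k=8:
#' 40,545 / 21,468 / 3,523). Partitions are cached per (motif, k) within a
#' session.
#'
#' @param motif Dinucleotide or trinucleotide over `{A,C,G,T}`.
#' @param k Word width, `k >= nchar(motif)`.
#' @return A `motif_partition`: list with `motif`, `k`, `classes` (integer
#'   vector of length `4^k`, position i+1 = label of the k-mer with base-4
#'   index i) and `sizes` (named class-size vector `c("0","1","2")`).
#' @examples
#' partition_by_motif("CG", 8)$sizes
#' @export
partition_by_motif <- function(motif, k) {
  stopifnot(is.character(motif), length(motif) == 1L,
            nchar(motif) %in% c(2L, 3L), k >= nchar(motif), k <= 12)
  key <- paste0(motif, ":", k)
  cached <- .partition_cache[[key]]
  if (!is.null(cached)) return(cached)
  classes <- pmin(motif_occurrences(motif, k), 2L)
  sizes <- tabulate(classes + 1L, nbins = 3L)
  out <- structure(
    list(motif = motif, k = as.integer(k), classes = classes,
         sizes = setNames(sizes, c("0", "1", "2"))),
    class = "motif_partition"
  )
  .partition_cache[[key]] <- out
  out
}

.partition_cache <- new.env(parent = emptyenv())

#' @export
print.motif_partition <- function(x, ...) {
  cat(sprintf("motif_partition: %s over %d-mers; sizes %s/%s/%s\n",
              x$motif, x$k, x$sizes[1L], x$sizes[2L], x$sizes[3L]))
  invisible(x)
}

#' Second-level partition: outer motif presence crossed with inner content
#'
#' Splits the 8-mer set six ways: `i` in {0,1} flags absence/presence of
#' the outer dinucleotide (classes 1 and 2 merged into "1"), `j` in {0,1,2}
#' is the inner-motif content class. The feature pipeline uses inner `"CG"`
#' with each non-CG outer dinucleotide.
#'
#' @param outer,inner Dinucleotides over `{A,C,G,T}`.
#' @param k Word width (default 8).
#' @return A `second_level_partition`: list with `outer`, `inner`, `k`, `i`
#'   (0/1 per k-mer), `j` (0/1/2 per k-mer), and `sizes` (2x3 matrix).
#' @export
partition_second_level <- function(outer, inner, k = 8) {
  po <- partition_by_motif(outer, k)
  pi_ <- partition_by_motif(inner, k)
  i <- pmin(po$classes, 1L)
  j <- pi_$classes
  sizes <- base::table(factor(i, levels = 0:1), factor(j, levels = 0:2))
  structure(
    list(outer = outer, inner = inner, k = as.integer(k),
         i = i, j = j, sizes = unclass(sizes)),
    class = "second_level_partition"
  )
}

#' Independent class-size oracle via a matching automaton
#'
#' Recomputes the (zero / one / two-or-more) class sizes of
#' [partition_by_motif()] by dynamic programming over the motif's
#' KMP failure automaton — a transfer-matrix (linear recurrence) route that
#' never enumerates or decodes individual k-mers. For a
#' non-self-overlapping dinucleotide this reduces to the classical
#' avoid-word recurrence (e.g. `f(n) = 4 f(n-1) - f(n-2)` for `"CG"`).
#'
#' @inheritParams partition_by_motif
#' @return Named numeric vector of the three class sizes.
#' @export
class_size_oracle <- function(motif, k) {
  m <- nchar(motif)
  stopifnot(m >= 2, m <= k)
  mot <- strsplit(motif, "", fixed = TRUE)[[1L]]
  # KMP failure function of the motif
  fail <- integer(m)
  len <- 0L
  for (q in 2:m) {
    while (len > 0L && mot[q] != mot[len + 1L]) len <- fail[len]
    if (mot[q] == mot[len + 1L]) len <- len + 1L
    fail[q] <- len
  }
  # delta[s+1, c]: next matched-prefix length from state s on base c;
  # a transition that completes the motif emits a hit and falls back to
  # the border state (overlapping occurrences counted).
  delta <- matrix(0L, nrow = m + 1L, ncol = 4L)
  hit <- matrix(FALSE, nrow = m + 1L, ncol = 4L)
  for (s in 0:m) {
    s_eff <- if (s == m) fail[m] else s
    for (c in 1:4) {
      len <- s_eff
      while (len > 0L && BASES[c] != mot[len + 1L]) len <- fail[len]
      if (BASES[c] == mot[len + 1L]) len <- len + 1L
      if (len == m) {
        hit[s + 1L, c] <- TRUE
      }
      delta[s + 1L, c] <- len
    }
  }
  # DP over (state, occurrences capped at 2)
  f <- matrix(0, nrow = m + 1L, ncol = 3L)  # f[s+1, t+1]
  f[1L, 1L] <- 1
  for (step in seq_len(k)) {
    g <- matrix(0, nrow = m + 1L, ncol = 3L)
    for (s in 0:m) {
      for (t in 0:2) {
        w <- f[s + 1L, t + 1L]
        if (w == 0) next
        for (c in 1:4) {
          t2 <- if (hit[s + 1L, c]) min(t + 1L, 2L) else t
          s2 <- delta[s + 1L, c]
          g[s2 + 1L, t2 + 1L] <- g[s2 + 1L, t2 + 1L] + w
        }
      }
    }
    f <- g
  }
  setNames(colSums(f), c("0", "1", "2"))
}

#' Write a partition to TSV for audit
#'
#' One `kmer<TAB>class` row per k-mer in lexicographic order.
#' @param partition A `motif_partition`.
#' @param path Output path.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "motif_partition"))
  kmers <- decode_kmer(0:(4^partition$k - 1), partition$k)
  writeLines(c("kmer\tclass",
               paste(kmers, partition$classes, sep = "\t")), path)
  invisible(path)
}
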