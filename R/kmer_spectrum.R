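#' @importFrom stats setNames
NULL

BASES <- c("A", "C", "G", "T")

#' Encode k-mers as base-4 integer indices
#'
#' Bijective encoding of DNA words over `{A,C,G,T}`: `A=0, C=1, G=2, T=3`,
#' leftmost base most significant, so `"AAAAAAAA"` is 0 and `"TTTTTTTT"` is
#' `4^8 - 1 = 65535`. This is also the lexicographic rank of the k-mer,
#' which is the order all count tables in the package use.
#'
#' @param kmer Character vector of equal-length DNA words.
#' @return Integer vector of 0-based indices in `0 .. 4^k - 1`.
#' @examples
#' encode_kmer(c("AAAAAAAA", "AAAAAAAC", "TTTTTTTT"))
#' @export
encode_kmer <- function(kmer) {
  stopifnot(is.character(kmer))
  n <- nchar(kmer)
  if (length(kmer) && any(n != n[1L])) stop("k-mers must share one width")
  if (length(kmer) && n[1L] > 15L) stop("k-mer width > 15 not supported")
  if (any(grepl("[^ACGT]", kmer))) stop("non-ACGT character in k-mer")
  strtoi(chartr("ACGT", "0123", kmer), base = 4L)
}

#' Decode base-4 indices back to k-mers
#'
#' @param index Integer vector of 0-based indices.
#' @param k Word width.
#' @return Character vector of DNA words; inverse of [encode_kmer()].
#' @export
decode_kmer <- function(index, k) {
  stopifnot(all(index >= 0), all(index < 4^k))
  digits <- vector("list", k)
  v <- as.numeric(index)
  for (p in k:1) {
    digits[[p]] <- BASES[v %% 4 + 1]
    v <- v %/% 4
  }
  do.call(paste0, digits)
}

#' Count all 4^k k-mers of a genome
#'
#' Slides a width-`k` window with step 1 over every record independently
#' (windows never span record boundaries) and tallies each window into the
#' complete table of `4^k` k-mers, in base-4 / lexicographic order. Windows
#' containing a non-ACGT character are skipped; both strands are NOT merged
#' (a k-mer and its reverse complement are counted separately). Counting is
#' delegated to [Biostrings::oligonucleotideFrequency()].
#'
#' @param records A [Biostrings::DNAStringSet] (e.g. from [read_fasta()]), a
#'   single `DNAString`, or a character vector of sequences.
#' @param k Word width, 1..15; the feature pipeline uses 8 (and 9 for the
#'   trinucleotide analysis).
#' @return A `kmer_count_table`: list with `k`, `counts` (named numeric
#'   vector of length `4^k`, names in lexicographic order) and
#'   `total_windows` (= `sum(counts)`, the number of valid windows).
#' @examples
#' tab <- count_kmers(strrep("A", 15), k = 8)
#' tab$total_windows  # 15 - 8 + 1 = 8
#' @export
count_kmers <- function(records, k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1, k <= 15)
  k <- as.integer(k)
  if (is.character(records)) records <- Biostrings::DNAStringSet(toupper(records))
  if (methods::is(records, "DNAString")) records <- Biostrings::DNAStringSet(records)
  if (length(records) == 0L) {
    counts <- setNames(numeric(4^k), decode_kmer(0:(4^k - 1), k))
  } else {
    m <- Biostrings::oligonucleotideFrequency(records, width = k, step = 1L)
    counts <- if (is.matrix(m)) colSums(m) else m
    counts <- as.numeric(counts) |> setNames(colnames(m) %||% names(m))
  }
  new_kmer_count_table(k, counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_kmer_count_table <- function(k, counts) {
  stopifnot(length(counts) == 4^k, all(counts >= 0))
  structure(
    list(k = k, counts = counts, total_windows = sum(counts)),
    class = "kmer_count_table"
  )
}

#' @export
print.kmer_count_table <- function(x, ...) {
  cat(sprintf("kmer_count_table: k=%d, %d k-mers, %s windows\n",
              x$k, length(x$counts), format(x$total_windows, big.mark = ",")))
  invisible(x)
}

#' Spectrum histogram (relative motif number, RMN)
#'
#' The k-mer spectrum is the distribution of "number of k-mers with
#' occurrence frequency i" against i. For a chosen subset of k-mers, each
#' distinct frequency value i is paired with
#' `RMN(i) = (# subset k-mers with count i) / 4^8`
#' (for general k the denominator is `4^k`). The denominator is always the
#' size of the complete k-mer set, even when restricted to a subset, so a
#' subset histogram sums to `subset size / 4^k`, not to 1.
#'
#' @param table A `kmer_count_table`.
#' @param subset Integer vector of 0-based k-mer indices (default: all).
#' @return A data.frame with columns `frequency` (sorted distinct counts)
#'   and `rmn`.
#' @export
rmn_histogram <- function(table, subset = NULL) {
  stopifnot(inherits(table, "kmer_count_table"))
  n_total <- length(table$counts)
  if (is.null(subset)) subset <- 0:(n_total - 1)
  if (length(subset) == 0L) stop("subset must be non-empty")
  stopifnot(all(subset >= 0), all(subset < n_total))
  cnt <- table$counts[subset + 1L]
  tb <- base::table(cnt)
  freq <- as.numeric(names(tb))
  o <- order(freq)
  data.frame(frequency = freq[o], rmn = as.numeric(tb)[o] / n_total)
}

#' Random center of a k-mer spectrum
#'
#' The random center is the mean occurrence frequency over the complete
#' k-mer set: `sum(counts) / 4^k = total_windows / 4^k` — the frequency
#' every k-mer would have under uniform usage. It anchors the separability
#' feature ([separability()]).
#'
#' @param table A `kmer_count_table`.
#' @return The mean frequency (0 for an empty genome).
#' @export
random_center <- function(table) {
  stopifnot(inherits(table, "kmer_count_table"))
  table$total_windows / length(table$counts)
}

#' Write / read a k-mer count table as TSV
#'
#' Plain-text interchange: a `# k=<k> total_windows=<n>` header line, then
#' `kmer<TAB>count` rows in lexicographic k-mer order.
#'
#' @param table A `kmer_count_table`.
#' @param path Output path.
#' @return `write_count_table` returns `path` invisibly; `read_count_table`
#'   returns the reconstructed `kmer_count_table`.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "kmer_count_table"))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# k=%d total_windows=%s", table$k,
                     format(table$total_windows, scientific = FALSE)), con)
  writeLines(paste(names(table$counts),
                   format(table$counts, scientific = FALSE, trim = TRUE),
                   sep = "\t"), con)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("^# k=(\\d+) total_windows=(\\d+)", hdr))[[1L]]
  if (length(m) != 3L) stop("not a count-table file (bad header): ", path)
  k <- as.integer(m[2L])
  df <- utils::read.table(path, sep = "\t", skip = 1L,
                          col.names = c("kmer", "count"),
                          colClasses = c("character", "numeric"))
  tab <- new_kmer_count_table(k, setNames(df$count, df$kmer))
  if (tab$total_windows != as.numeric(m[3L])) {
    stop("count-table header total_windows disagrees with counts in ", path)
  }
  tab
}
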