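#' Read genome sequences from a FASTA file
#'
#' Reads a plain or gzip-compressed FASTA file into a
#' [Biostrings::DNAStringSet]. Residues are upper-cased on read (soft-masked
#' lowercase bases are counted like any other); record order is preserved and
#' record names are taken from the FASTA headers.
#'
#' @param path Path to a FASTA or gzipped FASTA file.
#' @return A [Biostrings::DNAStringSet], one element per FASTA record
#'   (possibly of length zero for an empty file).
#' @details A malformed file whose first non-blank line is not a `>` header
#'   (a sequence line before any header) is rejected with the offending line
#'   number. Further format errors are reported by the Biostrings parser.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s", "acgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lineno <- 0L
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) {
      # empty file: no records
      return(Biostrings::DNAStringSet())
    }
    lineno <- lineno + 1L
    if (nzchar(trimws(ln))) break
  }
  if (!startsWith(trimws(ln), ">")) {
    stop("malformed FASTA '", path, "': sequence data before any '>' header ",
         "at line ", lineno)
  }
  recs <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (any(!nzchar(names(recs)))) stop("FASTA record with empty identifier in ", path)
  recs
}

#' Enumerate valid fixed-width windows of a sequence
#'
#' Slides a window of width `k` along a single sequence with step 1 and
#' returns every window composed entirely of `A`, `C`, `G`, `T`; any window
#' overlapping another character (e.g. `N`) is skipped. For an
#' ambiguity-free sequence of length `L` this yields exactly `max(0, L-k+1)`
#' windows. Intended for inspection and verification; bulk counting goes
#' through [count_kmers()], which never materialises the windows.
#'
#' @param record A single sequence: a character scalar or a
#'   [Biostrings::DNAString] (elements of a `DNAStringSet` work via `[[`).
#' @param k Window width in nucleotides (>= 1).
#' @return Character vector of k-mer windows in positional order.
#' @examples
#' iterate_windows("ACGTNACGT", 4)  # the four N-overlapping windows are skipped
#' @export
iterate_windows <- function(record, k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1)
  k <- as.integer(k)
  s <- toupper(as.character(record))
  stopifnot(length(s) == 1L)
  L <- nchar(s)
  if (L < k) return(character(0))
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- cumsum(!(chars %in% c("A", "C", "G", "T")))
  starts <- seq_len(L - k + 1L)
  # window [i, i+k-1] is clean iff no bad character accrued across it
  ok <- (bad[starts + k - 1L] - c(0L, bad)[starts]) == 0L
  starts <- starts[ok]
  if (length(starts) == 0L) return(character(0))
  substring(s, starts, starts + k - 1L)
}
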