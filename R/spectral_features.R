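# Class-level (separability/conservatism) and order-level (rank) features
# of an 8-mer count table.

NON_CG_DINUCLEOTIDES <- c("AA", "AC", "AG", "AT", "CA", "CC", "CT", "GA",
                          "GC", "GG", "GT", "TA", "TC", "TG", "TT")

# Canonical names of the 93 class-level subsets: CG0..CG2 then XYi_CGj for
# the 15 non-CG dinucleotides (lexicographic), i = 0 then 1 (1 = merged
# one-or-more), j = 0,1,2. Feature order must be identical across species.
class_feature_names <- function() {
  xy <- as.vector(t(outer(NON_CG_DINUCLEOTIDES,
                          c("0_CG0", "0_CG1", "0_CG2", "1_CG0", "1_CG1", "1_CG2"),
                          paste0)))
  c(paste0("CG", 0:2), xy)
}

#' Mean and standard deviation of a k-mer subset's counts
#'
#' @param table A `kmer_count_table`.
#' @param subset Integer vector of 0-based k-mer indices (non-empty).
#' @param id Subset name carried in the result.
#' @return A `subset_stats` list: `subset_id`, `mean`, `sd` (population
#'   divisor), `size`.
#' @export
subset_stats <- function(table, subset, id = "subset") {
  stopifnot(inherits(table, "kmer_count_table"))
  if (length(subset) == 0L) stop("empty subset: ", id)
  stopifnot(all(subset >= 0), all(subset < length(table$counts)))
  x <- table$counts[subset + 1L]
  mu <- mean(x)
  structure(
    list(subset_id = id, mean = mu,
         sd = sqrt(mean((x - mu)^2)), size = length(x)),
    class = "subset_stats"
  )
}

#' Separability of a subset spectrum
#'
#' `delta = log2(global_mean / subset_mean)`, the log-ratio of the random
#' center to the subset's mean frequency. Positive values place the subset
#' at the low-frequency end of the spectrum (depleted usage); 0 means the
#' subset sits on the random center.
#'
#' @param global_mean Random center of the full table ([random_center()]).
#' @param subset_mean Mean count of the subset.
#' @param id Subset name, used in error messages.
#' @return The separability value.
#' @export
separability <- function(global_mean, subset_mean, id = "subset") {
  if (!is.finite(global_mean) || global_mean <= 0 ||
      !is.finite(subset_mean) || subset_mean <= 0) {
    stop("degenerate mean for subset '", id,
         "': genome too small or empty for this word width")
  }
  log2(global_mean / subset_mean)
}

#' Conservatism of a subset spectrum
#'
#' `beta = log2(global_sd / subset_sd)`, the log-ratio of the full-spectrum
#' standard deviation to the subset's. Positive values mean a narrower,
#' more conserved subset spectrum.
#'
#' @param global_sd Population SD of all counts.
#' @param subset_sd Population SD of the subset's counts.
#' @param id Subset name, used in error messages.
#' @return The conservatism value.
#' @export
conservatism <- function(global_sd, subset_sd, id = "subset") {
  if (!is.finite(global_sd) || global_sd <= 0 ||
      !is.finite(subset_sd) || subset_sd <= 0) {
    stop("degenerate standard deviation for subset '", id, "'")
  }
  log2(global_sd / subset_sd)
}

#' The 186 class-level features of a genome
#'
#' For each of the 93 canonical subsets — CG0, CG1, CG2 and the 90
#' `XYi_CGj` subsets (15 non-CG dinucleotides x i in {0, 1-merged} x
#' j in {0,1,2}) — computes separability against the random center and
#' conservatism against the full-spectrum SD, giving 93 delta plus 93 beta
#' values in a fixed canonical order shared by all species.
#'
#' @param table A `kmer_count_table` with `k = 8`.
#' @param species_id Label carried into the result.
#' @return A `class_features` list: `species_id`, `delta` and `beta` (named
#'   numeric vectors of length 93, same names and order).
#' @export
class_feature_vector <- function(table, species_id = "genome") {
  stopifnot(inherits(table, "kmer_count_table"))
  if (table$k != 8L) stop("class-level features require k = 8")
  counts <- table$counts
  nbar <- random_center(table)
  if (nbar <= 0) stop("empty genome: no 8-mer windows")
  global_sd <- sqrt(mean((counts - nbar)^2))

  cg <- partition_by_motif("CG", 8L)$classes
  nms <- class_feature_names()
  delta <- beta <- setNames(numeric(length(nms)), nms)

  put <- function(name, sel) {
    x <- counts[sel]
    mu <- mean(x)
    sdv <- sqrt(mean((x - mu)^2))
    delta[[name]] <<- separability(nbar, mu, name)
    beta[[name]] <<- conservatism(global_sd, sdv, name)
  }
  for (j in 0:2) put(paste0("CG", j), cg == j)
  for (xy in NON_CG_DINUCLEOTIDES) {
    xyc <- pmin(partition_by_motif(xy, 8L)$classes, 1L)
    for (i in 0:1) for (j in 0:2) {
      put(paste0(xy, i, "_CG", j), xyc == i & cg == j)
    }
  }
  structure(
    list(species_id = species_id, delta = delta, beta = beta),
    class = "class_features"
  )
}

#' @export
print.class_features <- function(x, ...) {
  cat(sprintf("class_features: %s — %d delta + %d beta\n",
              x$species_id, length(x$delta), length(x$beta)))
  cat(sprintf("  delta_CG1 = %.3f, delta_CG2 = %.3f, beta_CG1 = %.3f\n",
              x$delta[["CG1"]], x$delta[["CG2"]], x$beta[["CG1"]]))
  invisible(x)
}

#' Frequency ranks of all 8-mers
#'
#' Assigns rank 1 to the most frequent 8-mer and `4^8 = 65536` to the least
#' frequent; ties are broken by ascending k-mer index (lexicographic), so
#' the result is always a deterministic permutation of `1..65536`. Ranking
#' discards overall genome size: multiplying all counts by a positive
#' constant leaves the ranks unchanged.
#'
#' @param table A `kmer_count_table` with `k = 8`.
#' @param species_id Label carried into the result.
#' @return A `rank_vector` list: `species_id`, `ranks` (integer
#'   permutation of `1..65536`, position = k-mer index + 1, named by k-mer).
#' @export
rank_vector <- function(table, species_id = "genome") {
  stopifnot(inherits(table, "kmer_count_table"))
  if (table$k != 8L) stop("rank features require k = 8")
  n <- length(table$counts)
  ord <- order(-table$counts, seq_len(n))
  ranks <- integer(n)
  ranks[ord] <- seq_len(n)
  structure(
    list(species_id = species_id, ranks = setNames(ranks, names(table$counts))),
    class = "rank_vector"
  )
}

#' @export
print.rank_vector <- function(x, ...) {
  top <- names(x$ranks)[which(x$ranks == 1L)]
  cat(sprintf("rank_vector: %s — permutation of 1..%d (top 8-mer: %s)\n",
              x$species_id, length(x$ranks), top))
  invisible(x)
}

#' Write a feature table for a set of species
#'
#' TSV with one row per species and 186 named columns
#' (`delta_CG0 ... beta_TT1_CG2`) in the canonical feature order.
#'
#' @param features List of `class_features`.
#' @param path Output path.
#' @export
write_feature_table <- function(features, path) {
  stopifnot(length(features) >= 1L,
            all(vapply(features, inherits, logical(1), "class_features")))
  nms <- class_feature_names()
  header <- c("species", paste0("delta_", nms), paste0("beta_", nms))
  rows <- vapply(features, function(f) {
    stopifnot(identical(names(f$delta), nms), identical(names(f$beta), nms))
    paste(c(f$species_id,
            format(c(f$delta, f$beta), digits = 15, scientific = FALSE,
                   trim = TRUE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), rows), path)
  invisible(path)
}

#' Write a rank vector as TSV
#'
#' `kmer<TAB>rank`, one of the 65,536 8-mers per line in lexicographic
#' order — a plain-text form the distance step can reload.
#'
#' @param rv A `rank_vector`.
#' @param path Output path.
#' @export
write_rank_vector <- function(rv, path) {
  stopifnot(inherits(rv, "rank_vector"))
  writeLines(c("kmer\trank", paste(names(rv$ranks), rv$ranks, sep = "\t")),
             path)
  invisible(path)
}

#' @rdname write_rank_vector
#' @param path Path of a file written by `write_rank_vector`.
#' @param species_id Label for the reloaded vector.
#' @export
read_rank_vector <- function(path, species_id = basename(path)) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer"))
  structure(
    list(species_id = species_id, ranks = setNames(df$rank, df$kmer)),
    class = "rank_vector"
  )
}
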