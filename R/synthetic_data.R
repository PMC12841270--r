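# Markov-chain genome simulator with tunable dinucleotide transition
# biases. A first-order chain is enough to reproduce the dinucleotide-level
# spectrum structure the feature pipeline reads out (CpG depletion pushes
# the CG1/CG2 subsets below the random center); no attempt is made to
# emulate isochores, repeats or higher-order composition.

#' Specify a synthetic Markov genome
#'
#' The transition matrix is built as
#' `P[x, y] proportional to base_frequencies[y] * transition_bias["xy"]`,
#' rows renormalised; a CpG multiplier of 0.2 therefore suppresses C->G
#' transitions five-fold relative to the unbiased chain, emulating
#' vertebrate CpG depletion. The initial base is drawn from the chain's
#' stationary distribution so dinucleotide frequencies match the
#' closed-form stationary prediction from the first window on.
#'
#' @param length Target genome length in nucleotides (>= 8).
#' @param base_frequencies Non-negative weights for A, C, G, T (normalised
#'   internally; default uniform).
#' @param transition_bias Named numeric vector of per-dinucleotide
#'   multipliers, e.g. `c(CG = 0.2)`; unnamed dinucleotides keep
#'   multiplier 1.
#' @param seed Integer seed; the same spec and seed always regenerate a
#'   byte-identical genome.
#' @param n_records Number of FASTA records the sequence is split into.
#' @return A `markov_genome_spec` list.
#' @export
markov_genome_spec <- function(length, base_frequencies = rep(0.25, 4),
                               transition_bias = numeric(0), seed = 1L,
                               n_records = 1L) {
  stopifnot(length >= 8, base_frequencies >= 0, sum(base_frequencies) > 0,
            n_records >= 1L, length >= n_records)
  if (base::length(transition_bias) > 0) {
    stopifnot(!is.null(names(transition_bias)),
              all(grepl("^[ACGT]{2}$", names(transition_bias))),
              all(transition_bias >= 0))
  }
  structure(
    list(length = as.numeric(length),
         base_frequencies = setNames(base_frequencies / sum(base_frequencies),
                                     BASES),
         transition_bias = transition_bias,
         seed = as.integer(seed),
         n_records = as.integer(n_records)),
    class = "markov_genome_spec"
  )
}

#' Transition matrix and stationary distribution of a genome spec
#'
#' @param spec A `markov_genome_spec`.
#' @return List with `P` (4x4 row-stochastic transition matrix) and `pi`
#'   (its stationary distribution).
#' @export
chain_model <- function(spec) {
  stopifnot(inherits(spec, "markov_genome_spec"))
  P <- matrix(rep(spec$base_frequencies, each = 4L), 4L, 4L,
              dimnames = list(BASES, BASES))
  for (nm in names(spec$transition_bias)) {
    x <- substr(nm, 1L, 1L); y <- substr(nm, 2L, 2L)
    P[x, y] <- P[x, y] * spec$transition_bias[[nm]]
  }
  rs <- rowSums(P)
  if (any(rs == 0)) stop("degenerate transition row (all-zero after bias)")
  P <- P / rs
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  list(P = P, pi = setNames(v / sum(v), BASES))
}

#' Generate a synthetic genome
#'
#' Samples a first-order Markov chain from the spec's biased transition
#' matrix and splits it into `n_records` FASTA-style records named
#' `<id>_r1 ...`. Deterministic given the spec (seeded RNG, restored on
#' exit).
#'
#' @param spec A `markov_genome_spec`.
#' @param id Genome identifier used for record names.
#' @return A [Biostrings::DNAStringSet] totalling `spec$length` bases.
#' @export
generate_genome <- function(spec, id = "synthetic") {
  stopifnot(inherits(spec, "markov_genome_spec"))
  mod <- chain_model(spec)
  L <- spec$length
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  cum <- t(apply(mod$P, 1L, cumsum))
  c1 <- cum[, 1L]; c2 <- cum[, 2L]; c3 <- cum[, 3L]
  u <- stats::runif(L)
  s <- integer(L)
  s[1L] <- findInterval(u[1L], cumsum(mod$pi)) + 1L
  for (t in seq_len(L - 1L) + 1L) {
    p <- s[t - 1L]
    s[t] <- 1L + (u[t] > c1[p]) + (u[t] > c2[p]) + (u[t] > c3[p])
  }
  seqc <- intToUtf8(c(65L, 67L, 71L, 84L)[s])
  bounds <- round(seq(0, L, length.out = spec$n_records + 1L))
  parts <- substring(seqc, bounds[-length(bounds)] + 1L, bounds[-1L])
  Biostrings::DNAStringSet(setNames(parts, paste0(id, "_r", seq_along(parts))))
}

#' Write a generated genome to FASTA
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param path Output path (`.gz` suffix writes gzip).
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Two-clade synthetic fixture
#'
#' Generates `2 * n_per_clade` genomes: clade A with CpG multiplier
#' `depletion_a`, clade B with `depletion_b`, all other parameters shared.
#' Per-genome seeds are `seed + ordinal` (ordinal 1..2n in label order), so
#' the fixture is stable across platforms and sessions. A depletion
#' contrast (e.g. 0.2 vs 1.0) yields a class-level and order-level signal
#' that neighbor joining resolves as the A-versus-B bipartition.
#'
#' @param n_per_clade Genomes per clade (>= 2).
#' @param depletion_a,depletion_b CpG multipliers of the two clades.
#' @param length Genome length in nucleotides.
#' @param seed Master seed.
#' @return List with `genomes` (named list of `DNAStringSet`), `clades`
#'   (named "A"/"B" factor-like character vector) and `manifest`
#'   (data.frame of genome id, clade, CpG multiplier, length, seed).
#' @export
two_clade_fixture <- function(n_per_clade = 3L, depletion_a = 0.2,
                              depletion_b = 1.0, length = 1e6, seed = 1L) {
  stopifnot(n_per_clade >= 2L)
  ids <- c(paste0("A", seq_len(n_per_clade)), paste0("B", seq_len(n_per_clade)))
  mult <- rep(c(depletion_a, depletion_b), each = n_per_clade)
  clades <- setNames(rep(c("A", "B"), each = n_per_clade), ids)
  genomes <- vector("list", base::length(ids))
  names(genomes) <- ids
  for (i in seq_along(ids)) {
    spec <- markov_genome_spec(length,
                               transition_bias = c(CG = mult[i]),
                               seed = seed + i)
    genomes[[i]] <- generate_genome(spec, id = ids[i])
  }
  manifest <- data.frame(genome = ids, clade = unname(clades),
                         cpg_multiplier = mult, length = length,
                         seed = seed + seq_along(ids))
  list(genomes = genomes, clades = clades, manifest = manifest)
}

#' Write a fixture manifest TSV
#'
#' @param manifest The `manifest` data.frame of [two_clade_fixture()].
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
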