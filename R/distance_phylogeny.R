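# Evolutionary distances over spectral features and neighbor-joining trees.

#' Class-level distance between two genomes
#'
#' Sum over the 93 canonical subsets of the per-subset Euclidean distance
#' between (delta, beta) pairs:
#' `D = sum_k sqrt((delta_ak - delta_bk)^2 + (beta_ak - beta_bk)^2)`
#' with the square root inside the sum — each subset contributes its own
#' planar displacement. Setting `pooled = TRUE` instead takes a single root
#' over all 186 squared differences (plain Euclidean distance on the
#' concatenated vector); this variant is provided for sensitivity analysis
#' only and is not the default.
#'
#' @param a,b `class_features` objects with identical feature order.
#' @param pooled Use the single-root pooled variant (default `FALSE`).
#' @return Non-negative distance, 0 for feature-wise equal inputs.
#' @export
class_distance <- function(a, b, pooled = FALSE) {
  stopifnot(inherits(a, "class_features"), inherits(b, "class_features"))
  if (!identical(names(a$delta), names(b$delta)) ||
      !identical(names(a$beta), names(b$beta))) {
    stop("feature order mismatch between '", a$species_id, "' and '",
         b$species_id, "'")
  }
  sq <- (a$delta - b$delta)^2 + (a$beta - b$beta)^2
  if (pooled) sqrt(sum(sq)) else sum(sqrt(sq))
}

#' Order-level distance between two genomes
#'
#' Euclidean distance between the two 65,536-entry rank permutations:
#' `W = sqrt(sum_k (R_ak - R_bk)^2)` (single root outside the sum). As a
#' Euclidean metric it satisfies the triangle inequality; because ranks
#' discard scale, so does W.
#'
#' @param a,b `rank_vector` objects.
#' @return Non-negative distance, 0 iff the permutations are identical.
#' @export
rank_distance <- function(a, b) {
  stopifnot(inherits(a, "rank_vector"), inherits(b, "rank_vector"))
  for (rv in list(a, b)) {
    n <- length(rv$ranks)
    if (!all(sort(rv$ranks) == seq_len(n))) {
      stop("ranks of '", rv$species_id, "' are not a permutation of 1..", n)
    }
  }
  if (length(a$ranks) != length(b$ranks)) stop("rank vectors differ in length")
  sqrt(sum((as.numeric(a$ranks) - as.numeric(b$ranks))^2))
}

#' Pairwise distance matrix over feature or rank vectors
#'
#' @param items Named or labelled list of `class_features` (metric
#'   `"class"`) or `rank_vector` (metric `"rank"`) objects; labels default
#'   to each item's `species_id`.
#' @param metric `"class"` (distance D) or `"rank"` (distance W).
#' @param pooled Passed to [class_distance()] when `metric = "class"`.
#' @return Symmetric numeric matrix with zero diagonal and species labels
#'   as dimnames.
#' @export
distance_matrix <- function(items, metric = c("class", "rank"),
                            pooled = FALSE) {
  metric <- match.arg(metric)
  stopifnot(length(items) >= 2L)
  want <- if (metric == "class") "class_features" else "rank_vector"
  if (!all(vapply(items, inherits, logical(1), want))) {
    stop("all items must be ", want, " objects for metric '", metric, "'")
  }
  labels <- names(items) %||% vapply(items, `[[`, character(1), "species_id")
  if (anyDuplicated(labels)) stop("duplicate species labels")
  n <- length(items)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- if (metric == "class") {
      class_distance(items[[i]], items[[j]], pooled = pooled)
    } else {
      rank_distance(items[[i]], items[[j]])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Native Saitou–Nei neighbor joining: repeatedly join the pair minimising
#' the Q-criterion `Q(i,j) = (r-2) d(i,j) - R_i - R_j`, estimate the two
#' pendant branch lengths by the standard two-point formulas, reduce the
#' matrix, and resolve the final three clusters by the three-point
#' equations. Ties in Q are broken by the lowest (row, column) pair in
#' label order, so the output is deterministic. Negative branch-length
#' estimates are clamped to zero with the deficit moved to the sister
#' branch (their sum, the joined pair's distance, is preserved). On an
#' additive (tree-realisable) matrix NJ recovers the generating topology
#' and branch lengths exactly.
#'
#' @param matrix Symmetric numeric distance matrix with labels as dimnames
#'   (or a `dist` object), `n >= 3`, finite entries.
#' @return An unrooted [ape] `phylo` tree.
#' @export
neighbor_joining <- function(matrix) {
  if (inherits(matrix, "dist")) matrix <- as.matrix(matrix)
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  n <- nrow(matrix)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (any(!is.finite(matrix))) stop("non-finite distances")
  if (max(abs(matrix - t(matrix))) > 0) stop("distance matrix is not symmetric")
  labels <- rownames(matrix) %||% paste0("t", seq_len(n))

  d <- matrix
  # active clusters: node id in the growing edge list; leaves are 1..n,
  # internal nodes n+1 (final join) then n+2, n+3, ...
  node_of <- seq_len(n)
  next_internal <- n + 2L
  edges <- integer(0)
  lengths <- numeric(0)
  add_edge <- function(parent, child, len) {
    edges <<- c(edges, parent, child)
    lengths <<- c(lengths, len)
  }

  while (nrow(d) > 3L) {
    r <- nrow(d)
    R <- rowSums(d)
    q <- (r - 2) * d - outer(R, R, `+`)
    diag(q) <- Inf
    # first strict minimum in column-major upper order = lowest (row, col)
    best <- Inf; bi <- bj <- 0L
    for (j in 2:r) for (i in 1:(j - 1L)) {
      if (q[i, j] < best) { best <- q[i, j]; bi <- i; bj <- j }
    }
    vi <- d[bi, bj] / 2 + (R[bi] - R[bj]) / (2 * (r - 2))
    vj <- d[bi, bj] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    new_node <- next_internal
    next_internal <- next_internal + 1L
    add_edge(new_node, node_of[bi], vi)
    add_edge(new_node, node_of[bj], vj)
    dk <- (d[bi, -c(bi, bj)] + d[bj, -c(bi, bj)] - d[bi, bj]) / 2
    keep <- setdiff(seq_len(r), c(bi, bj))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk), c(dk, 0))
    node_of <- c(node_of[keep], new_node)
  }

  # three-point resolution at the central node (id n+1)
  va <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  vb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  vc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  center <- n + 1L
  add_edge(center, node_of[1L], max(va, 0))
  add_edge(center, node_of[2L], max(vb, 0))
  add_edge(center, node_of[3L], max(vc, 0))

  tr <- structure(
    list(edge = matrix(edges, ncol = 2L, byrow = TRUE),
         edge.length = lengths,
         tip.label = labels,
         Nnode = n - 2L),
    class = "phylo", order = NULL
  )
  ape::reorder.phylo(tr, "cladewise")
}

#' Write and read Newick trees
#'
#' Serialises a tree to standard Newick with branch lengths via
#' [ape::write.tree()]. Labels containing Newick metacharacters are
#' underscore-escaped first (spaces and any of `(),:;[]'"` become `_`), the
#' relaxed-PHYLIP convention, so trees round-trip through [read_newick()].
#'
#' @param tree An ape `phylo` tree.
#' @param path Optional output file; omitted, the Newick string is returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  tree$tip.label <- gsub("[\\s(),:;\\[\\]'\"]", "_", tree$tip.label, perl = TRUE)
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname write_newick
#' @param x A Newick string or a path to a Newick file.
#' @export
read_newick <- function(x) {
  if (length(x) == 1L && file.exists(x)) ape::read.tree(x)
  else ape::read.tree(text = x)
}

#' Distance-matrix I/O: PHYLIP square format and TSV
#'
#' The PHYLIP writer emits the taxon count line then one row per taxon —
#' label, whitespace, the full row of distances (relaxed label widths, not
#' padded to 10 characters). The TSV writer emits a header of labels and
#' labelled rows.
#'
#' @param d Symmetric labelled distance matrix.
#' @param path Output path.
#' @export
write_phylip <- function(d, path) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  labels <- gsub("\\s", "_", rownames(d))
  rows <- vapply(seq_len(nrow(d)), function(i) {
    paste(c(labels[i], format(d[i, ], digits = 10, scientific = FALSE,
                              trim = TRUE)), collapse = "  ")
  }, character(1))
  writeLines(c(format(nrow(d)), rows), path)
  invisible(path)
}

#' @rdname write_phylip
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  toks <- strsplit(trimws(lines[1L + seq_len(n)]), "\\s+")
  labels <- vapply(toks, `[[`, character(1), 1L)
  d <- t(vapply(toks, function(tk) as.numeric(tk[-1L]), numeric(n)))
  dimnames(d) <- list(labels, labels)
  d
}

#' @rdname write_phylip
#' @export
write_dist_tsv <- function(d, path) {
  stopifnot(is.matrix(d))
  rows <- vapply(seq_len(nrow(d)), function(i) {
    paste(c(rownames(d)[i], format(d[i, ], digits = 10, scientific = FALSE,
                                   trim = TRUE)), collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("species", colnames(d)), collapse = "\t"), rows), path)
  invisible(path)
}
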