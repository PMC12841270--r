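make_features <- function(delta, beta, id = "x") {
  nms <- sprintf("F%02d", seq_along(delta))
  structure(list(species_id = id,
                 delta = stats::setNames(delta, nms),
                 beta = stats::setNames(beta, nms)),
            class = "class_features")
}

make_ranks <- function(ranks, id = "x") {
  structure(list(species_id = id, ranks = as.integer(ranks)),
            class = "rank_vector")
}

test_that("class distance sums per-feature planar displacements", {
  a <- make_features(rep(1, 93), rep(2, 93), "a")
  expect_equal(class_distance(a, a), 0)
  b <- a
  b$delta[5] <- a$delta[5] + 3
  b$beta[5] <- a$beta[5] + 4
  expect_equal(class_distance(a, b), 5)       # 3-4-5 triangle
  expect_equal(class_distance(a, b, pooled = TRUE), 5)
  # two displaced features: per-feature roots add, pooled root does not
  b$delta[7] <- a$delta[7] + 3
  b$beta[7] <- a$beta[7] + 4
  expect_equal(class_distance(a, b), 10)
  expect_equal(class_distance(a, b, pooled = TRUE), sqrt(50))

  mismatched <- make_features(rep(0, 93), rep(0, 93))
  names(mismatched$delta) <- rev(names(mismatched$delta))
  expect_error(class_distance(a, mismatched), "order mismatch")
})

test_that("class distance is symmetric and non-negative on random vectors", {
  set.seed(12)
  for (rep in 1:20) {
    a <- make_features(rnorm(93), rnorm(93), "a")
    b <- make_features(rnorm(93), rnorm(93), "b")
    d <- class_distance(a, b)
    expect_gte(d, 0)
    expect_equal(d, class_distance(b, a))
  }
})

test_that("rank distance is the Euclidean metric on permutations", {
  r1 <- make_ranks(1:65536, "a")
  expect_equal(rank_distance(r1, r1), 0)
  r2 <- make_ranks(c(2L, 1L, 3:65536), "b")
  expect_equal(rank_distance(r1, r2), sqrt(2))
  expect_error(rank_distance(r1, make_ranks(rep(1L, 65536))), "permutation")
})

test_that("rank distance satisfies triangle inequality and reversal bound", {
  set.seed(33)
  n <- 100
  bound <- sqrt(sum((seq_len(n) - (n + 1 - seq_len(n)))^2))
  for (rep in 1:50) {
    p1 <- make_ranks(sample(n), "1")
    p2 <- make_ranks(sample(n), "2")
    p3 <- make_ranks(sample(n), "3")
    d12 <- rank_distance(p1, p2)
    d23 <- rank_distance(p2, p3)
    d13 <- rank_distance(p1, p3)
    expect_lte(d13, d12 + d23 + 1e-12)
    expect_lte(d12, bound)
  }
  # the reversal attains the bound
  expect_equal(rank_distance(make_ranks(1:n), make_ranks(n:1)), bound)
})

test_that("distance_matrix is symmetric, labelled and permutation-equivariant", {
  set.seed(2)
  items <- list(a = make_features(rnorm(93), rnorm(93), "a"),
                b = make_features(rnorm(93), rnorm(93), "b"),
                c = make_features(rnorm(93), rnorm(93), "c"))
  d <- distance_matrix(items, "class")
  expect_equal(d, t(d))
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  d_perm <- distance_matrix(items[c(3, 1, 2)], "class")
  expect_equal(d_perm, d[c("c", "a", "b"), c("c", "a", "b")])

  dup <- distance_matrix(items[c("a", "a")] |> stats::setNames(c("x", "y")),
                         "class")
  expect_equal(dup, matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y"))))
  expect_error(distance_matrix(list(items$a, make_ranks(1:10)), "class"),
               "class_features")
})

test_that("3-taxon NJ solves the three-point equations", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  expect_s3_class(tr, "phylo")
  lens <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(lens, c(A = 1, B = 2, C = 3))
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
  d_bad <- d; d_bad[1, 2] <- Inf; d_bad[2, 1] <- Inf
  expect_error(neighbor_joining(d_bad), "non-finite")
})

test_that("NJ recovers every 4-taxon quartet exactly from additive input", {
  quartets <- list(c("A", "B"), c("A", "C"), c("A", "D"))
  for (pair in quartets) {
    nwk <- sprintf("((%s:0.7,%s:1.1):0.5,%s:0.9,%s:1.3);",
                   pair[1], pair[2],
                   setdiff(LETTERS[1:4], pair)[1], setdiff(LETTERS[1:4], pair)[2])
    tr_true <- ape::read.tree(text = nwk)
    d <- stats::cophenetic(tr_true)[LETTERS[1:4], LETTERS[1:4]]
    tr <- neighbor_joining(d)
    expect_equal(ape::dist.topo(tr, tr_true), structure(0, names = "PH85"),
                 ignore_attr = TRUE)
    expect_equal(max(abs(stats::cophenetic(tr)[LETTERS[1:4], LETTERS[1:4]] - d)),
                 0, tolerance = 1e-12)
  }
})

test_that("duplicate taxa become zero-length siblings", {
  set.seed(8)
  tr_base <- random_additive_tree(5)
  d <- stats::cophenetic(tr_base)
  labs <- c(rownames(d), "t1_copy")
  d2 <- rbind(cbind(d, d[, "t1"]), c(d["t1", ], 0))
  dimnames(d2) <- list(labs, labs)
  tr <- neighbor_joining(d2)
  expect_true(has_bipartition(tr, c("t1", "t1_copy")))
  pend <- tr$edge.length[match(match(c("t1", "t1_copy"), tr$tip.label),
                               tr$edge[, 2])]
  expect_equal(unname(pend), c(0, 0))
})

test_that("NJ agrees with ape's implementation on perturbed matrices", {
  set.seed(14)
  for (rep in 1:10) {
    n <- sample(5:9, 1)
    d <- stats::cophenetic(random_additive_tree(n))
    noise <- matrix(stats::runif(n * n, 0, 0.01), n, n)
    d <- d + noise + t(noise); diag(d) <- 0
    mine <- neighbor_joining(d)
    apes <- ape::nj(d)
    expect_equal(as.numeric(ape::dist.topo(mine, apes)), 0)
  }
})

test_that("newick output round-trips and escapes metacharacters", {
  tr <- neighbor_joining(matrix(c(0, 2, 2, 2, 0, 2, 2, 2, 0), 3, 3,
                                dimnames = rep(list(c("A", "B", "C")), 2)))
  nwk <- write_newick(tr)
  expect_match(nwk, "^\\(.*\\);$")
  back <- read_newick(nwk)
  expect_setequal(back$tip.label, c("A", "B", "C"))
  expect_equal(sort(back$edge.length), sort(tr$edge.length))

  set.seed(3)
  tr2 <- random_additive_tree(8)
  path <- tempfile(fileext = ".nwk")
  write_newick(tr2, path)
  back2 <- read_newick(path)
  expect_equal(as.numeric(ape::dist.topo(tr2, back2)), 0)
  expect_equal(sort(back2$edge.length), sort(tr2$edge.length), tolerance = 1e-9)

  tr$tip.label[1] <- "sp 1"
  expect_match(write_newick(tr), "sp_1")
})

test_that("PHYLIP and TSV distance writers round-trip", {
  set.seed(21)
  d <- stats::cophenetic(random_additive_tree(6))
  path <- tempfile(fileext = ".phylip")
  write_phylip(d, path)
  expect_equal(readLines(path)[1], format(6))
  back <- read_phylip(path)
  expect_equal(back, d, tolerance = 1e-9)

  tsv <- tempfile(fileext = ".tsv")
  write_dist_tsv(d, tsv)
  df <- read.table(tsv, sep = "\t", header = TRUE, row.names = 1)
  expect_equal(as.matrix(df), d, tolerance = 1e-9, ignore_attr = TRUE)
})
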