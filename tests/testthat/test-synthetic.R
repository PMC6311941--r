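test_that("block association generator honors its degenerate settings", {
  Y <- generate_block_associations(6, 4, 2, p_in = 1, p_out = 0, seed = 1)
  bm <- attr(Y, "block_m")
  bd <- attr(Y, "block_d")
  expect_true(all(Y[outer(bm, bd, `==`)] == 1))
  expect_true(all(Y[outer(bm, bd, `!=`)] == 0))
  Y0 <- generate_block_associations(5, 5, 2, p_in = 0, p_out = 0, seed = 1)
  expect_true(all(Y0 == 0))
  expect_error(generate_block_associations(5, 5, 2, p_in = 0.2, p_out = 0.5),
               "p_out < p_in")
})

test_that("block density concentrates around its expectation", {
  p_in <- 0.8; p_out <- 0.05; b <- 4
  Y <- generate_block_associations(200, 200, b, p_in, p_out, seed = 99)
  p_cell <- p_in / b + p_out * (1 - 1 / b)
  sd3 <- 3 * sqrt(p_cell * (1 - p_cell) / length(Y))
  expect_lt(abs(mean(Y) - p_cell), sd3)
})

test_that("generators are pure functions of their seed", {
  expect_identical(generate_block_associations(20, 10, 2, seed = 7),
                   generate_block_associations(20, 10, 2, seed = 7))
  expect_false(identical(generate_block_associations(20, 10, 2, seed = 7),
                         generate_block_associations(20, 10, 2, seed = 8)))
  expect_identical(generate_sequences(paste0("m", 1:5), seed = 3),
                   generate_sequences(paste0("m", 1:5), seed = 3))
  d1 <- generate_dag(8, depth = 3, seed = 5)
  d2 <- generate_dag(8, depth = 3, seed = 5)
  expect_identical(d1$edges, d2$edges)
  g1 <- generate_gene_network(20, 0.2, paste0("D", 1:3), seed = 11)
  g2 <- generate_gene_network(20, 0.2, paste0("D", 1:3), seed = 11)
  expect_identical(g1$network$edges, g2$network$edges)
  expect_identical(g1$sets, g2$sets)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_block_associations(10, 5, 2, seed = 99))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("depth-1 DAGs are stars and generated DAGs are single-rooted and acyclic", {
  star <- generate_dag(5, depth = 1, seed = 2)
  expect_true(all(star$edges$parent == "root"))
  expect_setequal(star$edges$child, sprintf("dis_%03d", 1:5))
  for (seed in 1:3) {
    dag <- generate_dag(10, depth = 3, seed = seed)
    roots <- setdiff(dag$edges$parent, dag$edges$child)
    expect_identical(roots, "root")
    expect_true(igraph::is_dag(dag$graph))
    # every catalog disease is reachable for the semantic kernel
    K <- semantic_kernel(dag, sprintf("dis_%03d", 1:10))
    expect_true(all(diag(K) == 1))
  }
})

test_that("a two-sibling star reproduces the hand semantic similarity", {
  dag <- generate_dag(c("dA", "dB"), depth = 2, seed = 1)
  # force the known shape: both leaves under one internal node under root
  dag <- disease_dag(data.frame(child = c("dA", "dB", "t1_001"),
                                parent = c("t1_001", "t1_001", "root")),
                     delta = dag$delta)
  expect_equal(semantic_kernel(dag, c("dA", "dB"))["dA", "dB"], 3 / 7,
               tolerance = 1e-12)
})

test_that("generated sequences and networks satisfy their contracts", {
  seqs <- generate_sequences(paste0("m", 1:20), c(18L, 24L), seed = 6)
  expect_true(all(nchar(seqs) >= 18 & nchar(seqs) <= 24))
  expect_true(all(grepl("^[ACGU]+$", seqs)))
  gn <- generate_gene_network(30, 0.2, paste0("D", 1:5), lls_range = c(0.5, 5),
                              seed = 7)
  expect_gt(length(unique(gn$network$edges$lls)), 1)
  expect_true(all(gn$network$edges$lls >= 0.5 & gn$network$edges$lls <= 5))
  expect_true(all(lengths(gn$sets) >= 3))
})

test_that("the synthetic bundle writes every input format consistently", {
  dir <- withr::local_tempdir()
  paths <- write_synthetic_bundle(dir, m = 15, n = 10, b = 2, seed = 3)
  expect_true(all(file.exists(paths)))
  Y <- read_associations(paths[["associations"]])
  expect_lte(nrow(Y), 15)  # all-zero rows drop out of a pair list
  seqs <- read_sequences(paths[["sequences"]])
  expect_setequal(names(seqs), sprintf("mir_%03d", 1:15))
  dag <- read_dag(paths[["dag"]])
  expect_true(all(sprintf("dis_%03d", 1:10) %in% dag$nodes))
  net <- read_gene_network(paths[["gene_network"]])
  sets <- read_disease_gene_sets(paths[["disease_genes"]])
  K <- functional_kernel(normalize_lls(net), sets, colnames(Y))
  expect_true(all(diag(K) == 1))
  # byte-identical regeneration from the same seed
  dir2 <- withr::local_tempdir()
  paths2 <- write_synthetic_bundle(dir2, m = 15, n = 10, b = 2, seed = 3)
  for (nm in names(paths)) {
    expect_identical(readLines(paths[[nm]]), readLines(paths2[[nm]]),
                     info = nm)
  }
})
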