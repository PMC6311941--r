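test_that("fusion targets are the per-side association Gram matrices", {
  Y <- association_matrix(rbind(c(1, 0), c(0, 1)), c("m1", "m2"), c("d1", "d2"))
  expect_equal(unname(fusion_target(Y, "miRNA")), diag(2))
  Y1 <- association_matrix(matrix(c(1, 1), 1), "m1", c("d1", "d2"))
  expect_equal(unname(fusion_target(Y1, "miRNA")), matrix(2))
  Y2 <- association_matrix(matrix(c(1, 1), 2), c("m1", "m2"), "d1")
  expect_equal(unname(fusion_target(Y2, "disease")), matrix(2))
  Y3 <- tiny_assoc()
  expect_equal(fusion_target(Y3, "disease"), t(Y3) %*% Y3)
})

test_that("exact-target fit at lam = 0 puts all weight on the matching kernel", {
  withr::local_seed(1)
  ks <- lapply(1:3, function(i) random_spd_kernel(5))
  w <- fkl_fit(ks, unclass(ks[[2]]), lam = 0)
  expect_equal(unname(w$mu), c(0, 1, 0), tolerance = 1e-9)
  expect_equal(w$objective, 0, tolerance = 1e-9)
})

test_that("a dominating ridge drives the weights to uniform", {
  withr::local_seed(2)
  ks <- lapply(1:3, function(i) random_kernel(6))
  w <- fkl_fit(ks, unclass(random_spd_kernel(6)) * 3, lam = 1e9)
  expect_equal(unname(w$mu), rep(1 / 3, 3), tolerance = 1e-3)
})

test_that("QP solutions dominate a 0.01-step simplex grid search", {
  withr::local_seed(3)
  grid <- simplex_grid3(0.01)
  for (inst in 1:20) {
    ks <- lapply(1:3, function(i) random_kernel(5))
    Tgt <- unclass(random_spd_kernel(5)) * 2
    lam <- sample(c(0, 1, 200), 1)
    w <- fkl_fit(ks, Tgt, lam = lam)
    expect_true(all(w$mu >= -1e-9))
    expect_equal(sum(w$mu), 1, tolerance = 1e-8)
    obj_fit <- fusion_objective(w$mu, ks, Tgt, lam)
    expect_equal(obj_fit, w$objective, tolerance = 1e-6)
    grid_obj <- apply(grid, 1, fusion_objective, kernels = ks, target = Tgt,
                      lam = lam)
    expect_lte(obj_fit, min(grid_obj) + 1e-9)
  }
})

test_that("the support-enumeration QP agrees with an interior-point solver", {
  skip_if_not_installed("kernlab")
  withr::local_seed(4)
  for (inst in 1:5) {
    ks <- lapply(1:3, function(i) random_kernel(6))
    Tgt <- unclass(random_spd_kernel(6))
    lam <- 10
    G <- outer(1:3, 1:3, Vectorize(function(a, b) sum(ks[[a]] * ks[[b]])))
    cv <- sapply(ks, function(K) sum(K * Tgt))
    ip <- kernlab::ipop(c = -2 * cv, H = 2 * (G + diag(lam, 3)),
                        A = matrix(1, 1, 3), b = 1, r = 0,
                        l = rep(0, 3), u = rep(1, 3), sigf = 12)
    w <- fkl_fit(ks, Tgt, lam = lam)
    expect_equal(unname(w$mu), kernlab::primal(ip), tolerance = 1e-5)
  }
})

test_that("fkl_fit is equivariant under kernel permutation", {
  withr::local_seed(5)
  ks <- lapply(1:3, function(i) random_kernel(5, name = paste0("k", i)))
  Tgt <- unclass(random_spd_kernel(5))
  w <- fkl_fit(ks, Tgt, lam = 50)
  perm <- c(3, 1, 2)
  w_perm <- fkl_fit(ks[perm], Tgt, lam = 50)
  expect_equal(unname(w_perm$mu), unname(w$mu)[perm], tolerance = 1e-9)
})

test_that("combining kernels is the weighted elementwise sum", {
  withr::local_seed(6)
  ks <- lapply(1:3, function(i) random_kernel(4))
  expect_equal(unclass(combine_kernels(ks, c(1, 0, 0))), unclass(ks[[1]]),
               ignore_attr = "kernel_name")
  mu <- c(0.2, 0.5, 0.3)
  K <- combine_kernels(ks, mu)
  for (idx in list(c(1, 2), c(3, 4), c(2, 2))) {
    expect_equal(K[idx[1], idx[2]],
                 sum(sapply(1:3, function(j) mu[j] * ks[[j]][idx[1], idx[2]])))
  }
  expect_error(combine_kernels(ks, c(1, 0)), "weights")
})

test_that("average kernel is the uniform combination", {
  withr::local_seed(7)
  ks <- lapply(1:3, function(i) random_kernel(4))
  expect_equal(unclass(average_kernel(ks)),
               unclass(combine_kernels(ks, rep(1 / 3, 3))))
  expect_equal(unclass(average_kernel(ks[1])), unclass(ks[[1]]),
               ignore_attr = "kernel_name")
  z <- similarity_kernel(matrix(0, 3, 3))
  j <- similarity_kernel(matrix(1, 3, 3))
  expect_true(all(average_kernel(list(z, j)) == 0.5))
  expect_error(average_kernel(list()), "no kernels")
})

test_that("fused PSD kernels with simplex weights stay PSD", {
  withr::local_seed(8)
  for (rep in 1:5) {
    ks <- lapply(1:3, function(i) random_spd_kernel(6))
    w <- fkl_fit(ks, unclass(random_spd_kernel(6)), lam = 5)
    K <- combine_kernels(ks, w)
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("fusion weights serialize as readable key-value text", {
  withr::local_seed(9)
  ks <- list(random_kernel(4, "gip"), random_kernel(4, "sequence"))
  w <- fkl_fit(ks, unclass(random_spd_kernel(4)), lam = 200)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fusion_weights(w, f)
  lines <- readLines(f)
  expect_match(lines[1], "^lambda\t200$")
  expect_true(any(grepl("^mu\\.gip\t", lines)))
  got <- as.numeric(sub(".*\t", "", grep("^mu\\.", lines, value = TRUE)))
  expect_equal(got, unname(w$mu), tolerance = 1e-10)
})
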