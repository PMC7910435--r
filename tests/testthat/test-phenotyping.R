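test_that("four separated blobs are recovered as four pure clusters", {
  pt <- blob_table()
  sol <- cluster_parameters(pt, seed = 42)
  expect_equal(sol$k, 4)
  expect_equal(mclust::adjustedRandIndex(sol$assignments,
                                         attr(pt, "truth")), 1)
  expect_equal(sort(unique(sol$assignments)), 1:4)
  expect_equal(dim(sol$pca), c(nrow(pt), 2L))
  expect_equal(nrow(sol$profiles), 4)
})

test_that("unstructured data shows no strong cluster support", {
  set.seed(43)
  noise <- as.data.frame(exp(matrix(rnorm(450, 0, 0.3), ncol = 3)))
  names(noise) <- c("alpha", "P", "C")
  sol <- cluster_parameters(noise, k_range = 2:6, seed = 44)
  # silhouettes stay low everywhere (a blob solution would exceed 0.5)
  expect_lt(max(sol$criteria$silhouette), 0.45)
})

test_that("clustering is invariant to duplication and user order", {
  pt <- blob_table(n_per = 25)
  sol <- cluster_parameters(pt, k_range = 2:6, seed = 45)
  dup <- rbind(pt, pt)
  sol_dup <- cluster_parameters(dup, k_range = 2:6, seed = 45)
  expect_equal(sol_dup$k, sol$k)
  expect_equal(sol_dup$assignments, rep(sol$assignments, 2))
  perm <- sample(nrow(pt))
  sol_perm <- cluster_parameters(pt[perm, ], k_range = 2:6, seed = 45)
  expect_equal(sol_perm$k, sol$k)
  expect_equal(sol_perm$assignments, sol$assignments[perm])
})

test_that("criteria votes are reproducible under a fixed seed", {
  pt <- blob_table(n_per = 20)
  v1 <- cluster_parameters(pt, k_range = 2:6, seed = 46)$votes
  v2 <- cluster_parameters(pt, k_range = 2:6, seed = 46)$votes
  expect_identical(v1, v2)
})

test_that("PCA scores preserve the standardized geometry", {
  pt <- blob_table(n_per = 20)
  sol <- cluster_parameters(pt, seed = 47)
  # with 2 of 3 PCs retained, pairwise distances are reproduced up to the
  # variance captured by the dropped component
  d_full <- dist(sol$data)
  d_pca <- dist(sol$pca)
  expect_true(all(d_pca <= d_full + 1e-8))
  expect_gt(cor(as.vector(d_full), as.vector(d_pca)), 0.95)
})

test_that("non-positive parameters trigger the offset transform", {
  pt <- blob_table(n_per = 10)
  pt$alpha[1] <- -0.5
  expect_warning(sol <- cluster_parameters(pt, k_range = 2:4, seed = 48),
                 "offset")
  expect_equal(length(sol$assignments), nrow(pt))
})

test_that("Cramer's V matches its chi-squared closed form", {
  expect_equal(cramers_v(rep(1:2, each = 20), rep(1:2, each = 20)), 1)
  expect_equal(cramers_v(rep(1:2, each = 10), rep(1:2, times = 10)), 0)
  # 2x2 diagonal vs uniform tables
  a <- rep(c("x", "y"), each = 20)
  expect_equal(cramers_v(a, a), 1)
  set.seed(49)
  big_a <- sample(1:3, 6000, TRUE)
  big_b <- sample(1:4, 6000, TRUE)
  expect_lt(cramers_v(big_a, big_b), 0.05)
  expect_warning(v <- cramers_v(rep(1, 10), rep(1:2, 5)), "degenerate")
  expect_equal(v, 0)
})

test_that("bootstrap stability is near 1 on blobs and near chance on noise", {
  pt <- blob_table(n_per = 25)
  sol <- cluster_parameters(pt, k_range = 2:6, seed = 50)
  sr <- stability_report(pt, sol, n_boot = 25, seed = 51)
  expect_gt(sr$mean, 0.95)
  set.seed(52)
  noise <- as.data.frame(exp(matrix(rnorm(300, 0, 0.3), ncol = 3)))
  names(noise) <- c("alpha", "P", "C")
  soln <- cluster_parameters(noise, k_range = 4:6, seed = 53)
  srn <- stability_report(noise, soln, n_boot = 25, seed = 54)
  expect_lt(srn$mean, 0.6)
  # vacuous case
  sr0 <- stability_report(pt, sol, n_boot = 0)
  expect_length(sr0$agreement, 0)
})
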