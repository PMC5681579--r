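grouped_df <- function(A, B, labels = c("A", "B")) {
  A <- as.matrix(A); B <- as.matrix(B)
  df <- as.data.frame(rbind(A, B))
  names(df) <- paste0("f", seq_len(ncol(df)))
  df$species <- rep(labels, c(nrow(A), nrow(B)))
  df
}

test_that("distance ratio matches exhaustive pair enumeration", {
  # 1D: A = {0, 2}, B = {1, 3}: between (1+3+1+1)/4, within (2+2)/2
  df <- grouped_df(matrix(c(0, 2)), matrix(c(1, 3)))
  expect_equal(distance_ratio(df), 0.75)

  # brute-force oracle on random clouds
  set.seed(8)
  for (r in 1:5) {
    A <- matrix(rnorm(12), 4, 3); B <- matrix(rnorm(15), 5, 3)
    between <- mean(apply(expand.grid(1:4, 1:5), 1, function(ij) {
      sqrt(sum((A[ij[1], ] - B[ij[2], ])^2))
    }))
    wpairs <- c(apply(combn(4, 2), 2, function(ij) {
      sqrt(sum((A[ij[1], ] - A[ij[2], ])^2))
    }), apply(combn(5, 2), 2, function(ij) {
      sqrt(sum((B[ij[1], ] - B[ij[2], ])^2))
    }))
    expect_equal(distance_ratio(grouped_df(A, B)), between / mean(wpairs),
                 tolerance = 1e-12)
  }

  # identical well-spread sets give a computable ratio near 1
  X <- matrix(rnorm(20), 10, 2)
  expect_equal(distance_ratio(grouped_df(X, X)), 1, tolerance = 0.35)

  # coincident points within groups: within mean 0, undefined
  dup <- grouped_df(matrix(c(0, 0)), matrix(c(5, 5)))
  expect_error(distance_ratio(dup), class = "olfactomap_numerical_error")
})

test_that("distance ratio is rigid-motion invariant and grows with separation", {
  set.seed(15)
  A <- matrix(rnorm(20), 10, 2); B <- matrix(rnorm(20), 10, 2)
  r0 <- distance_ratio(grouped_df(A, B))
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  shift <- c(3, -7)
  r1 <- distance_ratio(grouped_df(sweep(A %*% R, 2, -shift),
                                  sweep(B %*% R, 2, -shift)))
  expect_equal(r0, r1, tolerance = 1e-9)

  seps <- c(0, 0.5, 1, 2, 4)
  ratios <- vapply(seps, function(d) {
    distance_ratio(grouped_df(A, sweep(B, 2, -c(d, 0))))
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("bootstrap ratio test is deterministic, calibrated in direction, and powerful", {
  set.seed(30)
  A <- matrix(rnorm(70), 10, 7)
  B <- matrix(rnorm(70), 10, 7)
  df_null <- grouped_df(A, B)
  t1 <- bootstrap_ratio_test(df_null, n_boot = 500, seed = 42)
  t2 <- bootstrap_ratio_test(df_null, n_boot = 500, seed = 42)
  expect_identical(t1$ratio, t2$ratio)
  expect_identical(t1$p_value, t2$p_value)
  expect_identical(t1$boot_ratios, t2$boot_ratios)

  # groups separated by 10x the within-group SD: decisively significant
  df_sep <- grouped_df(A, sweep(B, 2, -rep(10, 7)))
  ts <- bootstrap_ratio_test(df_sep, n_boot = 1000, seed = 7)
  expect_gt(ts$ratio, 1)
  expect_lt(ts$p_value, 0.01)

  expect_error(bootstrap_ratio_test(df_null, n_boot = 50),
               class = "olfactomap_validation_error")
})

test_that("pairwise ratio matrix covers all pairs with raw p-values", {
  set.seed(31)
  df <- rbind(grouped_df(matrix(rnorm(10), 5, 2),
                         matrix(rnorm(10), 5, 2), c("s1", "s2")),
              grouped_df(matrix(rnorm(10, 5), 5, 2),
                         matrix(rnorm(10, 5), 5, 2), c("s3", "s3"))[1:5, ])
  res <- distance_ratio_matrix(df, n_boot = 200, seed = 2)
  expect_identical(nrow(res), 3L)  # choose(3, 2)
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  res2 <- distance_ratio_matrix(df, n_boot = 200, seed = 2)
  expect_identical(res$p_value, res2$p_value)
})

test_that("LDA separates well-separated clouds and degenerates on identical groups", {
  set.seed(40)
  A <- matrix(rnorm(60, 0, 1), 30, 2)
  B <- matrix(rnorm(60, 5, 1), 30, 2)  # 5 sigma separation
  proj <- lda_projection(grouped_df(A, B), n_components = 1)
  sA <- proj$scores$LD1[proj$scores$species == "A"]
  sB <- proj$scores$LD1[proj$scores$species == "B"]
  expect_true(max(sA) < min(sB) || min(sA) > max(sB))  # zero overlap

  # identical groups: between-scatter ~ 0
  proj0 <- lda_projection(grouped_df(A, A))
  expect_lt(abs(proj0$eigenvalues[1]), 1e-8)

  # consistent feature permutation leaves the projection equal up to sign
  perm <- c(2, 1)
  df <- grouped_df(A, B)
  dfp <- df; dfp[, 1:2] <- df[, perm]; names(dfp)[1:2] <- names(df)[1:2]
  p1 <- lda_projection(df, n_components = 1)$scores$LD1
  p2 <- lda_projection(dfp, n_components = 1)$scores$LD1
  expect_equal(abs(cor(p1, p2)), 1, tolerance = 1e-9)

  expect_error(lda_projection(grouped_df(A, A[0, , drop = FALSE],
                                         c("A", "A"))),
               class = "olfactomap_validation_error")
})

test_that("LDA agrees with the standard reference implementation when well-posed", {
  skip_if_not_installed("MASS")
  set.seed(41)
  df <- grouped_df(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 2), 20, 2))
  ours <- lda_projection(df, n_components = 1)
  ref <- MASS::lda(species ~ f1 + f2, data = df)
  ref_scores <- as.matrix(df[, 1:2]) %*% ref$scaling[, 1]
  expect_equal(abs(cor(ours$scores$LD1, as.numeric(ref_scores))), 1,
               tolerance = 1e-6)
})

test_that("ridge regularization engages when features exceed residual df", {
  set.seed(43)
  # 8 features, 3 + 3 individuals: within scatter is singular
  df <- grouped_df(matrix(rnorm(24), 3, 8), matrix(rnorm(24, 2), 3, 8))
  proj <- lda_projection(df, n_components = 1)
  expect_true(all(is.finite(proj$scores$LD1)))
  expect_gt(proj$eigenvalues[1], 0)
})

test_that("profile PCA recovers planted structure and orders variance", {
  # rank-1 profiles: first component explains everything
  set.seed(50)
  v <- sin(seq(0, pi, length.out = 40))
  X <- outer(rnorm(12), v) + matrix(rep(runif(40), each = 12), 12, 40)
  # add the same mean to every profile so centring removes it
  p <- pca_profiles(X)
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-9)
  expect_gt(abs(sum(p$components[, 1] * v) /
                  sqrt(sum(v^2) * sum(p$components[, 1]^2))), 0.999)

  # general data: fractions sum to 1, non-increasing
  Y <- matrix(rnorm(200), 10, 20)
  py <- pca_profiles(Y)
  expect_equal(sum(py$explained_variance), 1, tolerance = 1e-9)
  expect_true(all(diff(py$explained_variance) <= 1e-12))

  Yna <- Y; Yna[1, 1] <- NA
  expect_error(pca_profiles(Yna), class = "olfactomap_validation_error")
  expect_error(pca_profiles(Y[1, , drop = FALSE]),
               class = "olfactomap_validation_error")
})
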