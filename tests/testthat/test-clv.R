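test_that("standardization matches the z-score definition", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 0, 5))
  s <- standardize(m)
  expect_equal(unname(s$Z[, "a"]), c(-1, 0, 1))
  expect_equal(colMeans(s$Z), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(s$Z, 2, sd), c(a = 1, b = 1), tolerance = 1e-12)

  m2 <- withr::with_seed(1, matrix(rnorm(20 * 50), 20))
  colnames(m2) <- paste0("V", 1:50)
  s2 <- standardize(m2)
  expect_lt(max(abs(colMeans(s2$Z))), 1e-10)
  expect_equal(unname(apply(s2$Z, 2, sd)), rep(1, 50), tolerance = 1e-10)

  m3 <- cbind(m, const = 7)
  expect_warning(s3 <- standardize(m3), "zero-variance")
  expect_equal(s3$dropped, "const")
  expect_error(suppressWarnings(standardize(cbind(k = rep(1, 5)))),
               "zero variance")
})

test_that("cluster latent matches an eigen oracle and handles edge cases", {
  # single variable: the latent is the variable itself, t = 1
  z1 <- standardize(matrix(c(3, 1, 4, 1, 5), dimnames = list(NULL, "x")))
  cl1 <- cluster_latent(z1)
  expect_equal(cl1$lambda, 1)
  expect_equal(cl1$scores, unname(z1$Z[, 1]))

  # two identical variables: t = 2
  v <- c(0.3, -1, 2, 0.5, -0.8)
  z2 <- standardize(cbind(a = v, b = v))
  expect_equal(cluster_latent(z2)$lambda, 2)

  # random block: t equals the leading eigenvalue of the correlation matrix
  m <- withr::with_seed(7, matrix(rnorm(20 * 6), 20))
  colnames(m) <- paste0("V", 1:6)
  cl <- cluster_latent(standardize(m))
  oracle <- eigen(cor(m), symmetric = TRUE, only.values = TRUE)$values[1]
  expect_equal(cl$lambda, oracle, tolerance = 1e-8)
  # loadings are the variable-latent correlations; squared normalized
  # loadings sum to one
  expect_equal(unname(cl$loadings),
               unname(cor(m, cl$scores)[, 1]), tolerance = 1e-8)
  expect_equal(sum(cl$norm_loadings^2), 1)
  expect_equal(var(cl$scores), 1, tolerance = 1e-10)
})

test_that("eigen computation on the subject-side cross-product agrees", {
  # p > n path (n x n cross-product) against the direct p x p decomposition
  m <- withr::with_seed(8, matrix(rnorm(10 * 25), 10))
  colnames(m) <- paste0("V", 1:25)
  z <- standardize(m)
  cl <- cluster_latent(z)
  e <- eigen(cor(m), symmetric = TRUE)
  expect_equal(cl$lambda, e$values[1], tolerance = 1e-8)
  v <- e$vectors[, 1]
  if (sum(v) < 0) v <- -v
  expect_equal(unname(cl$norm_loadings), unname(v), tolerance = 1e-8)
})

test_that("hierarchy merges perfectly correlated variables first", {
  f <- withr::with_seed(2, rnorm(15))
  m <- cbind(x1 = f, x2 = 2 * f + 3, y = withr::with_seed(3, rnorm(15)))
  h <- clv_hierarchy(m)
  p2 <- h$partitions[[2]]
  expect_equal(p2[1], p2[2])
  expect_false(p2[3] == p2[1])
  expect_equal(h$delta$delta[1], 0, tolerance = 1e-12)
  expect_true(all(h$delta$delta >= -1e-12))
  # K = p partition scores T = p
  expect_equal(unname(h$criterion[as.character(3)]), 3)
})

test_that("hierarchy criterion is bounded by exhaustive enumeration", {
  m <- planted_blocks(n = 20, sizes = c(3, 2), rho = 0.85, seed = 5)
  h <- clv_hierarchy(m)
  for (K in 1:4) {
    best <- oracle_best_partition(scale(m), K)
    hier_T <- oracle_criterion(m, h$partitions[[K]])
    expect_lte(hier_T, best + 1e-8)
  }
})

test_that("consolidation recovers planted blocks from an adversarial start", {
  m <- planted_blocks(n = 40, sizes = c(4, 4), rho = 0.9, seed = 9)
  # adversarial init: blocks split across both clusters
  init <- rep(c(1L, 2L), 4)
  fit <- clv_consolidate(m, init)
  truth <- rep(1:2, each = 4)
  expect_equal(partition_agreement(fit$assignment$cluster, truth), 1)
  # matches the exhaustive optimum at K = 2
  expect_equal(fit$criterion, oracle_best_partition(scale(m), 2),
               tolerance = 1e-8)
  # already-optimal init returns unchanged at once
  fit2 <- clv_consolidate(m, truth)
  expect_identical(fit2$assignment$cluster, as.integer(truth))
  expect_equal(fit2$iterations, 1)
  expect_true(fit2$converged)
})

test_that("consolidation criterion is monotone and K=1 equals the eigen oracle", {
  m <- withr::with_seed(11, matrix(rnorm(25 * 12), 25))
  colnames(m) <- paste0("V", 1:12)
  fit1 <- clv(m, K = 1)
  expect_equal(fit1$criterion,
               eigen(cor(m), symmetric = TRUE, only.values = TRUE)$values[1],
               tolerance = 1e-8)
  for (K in c(2, 3, 4)) {
    fit <- clv(m, K = K)
    expect_true(all(diff(fit$trace) >= -1e-8))
    # consolidation can only improve on the hierarchy partition
    h_T <- oracle_criterion(m, clv_hierarchy(m)$partitions[[K]])
    expect_gte(fit$criterion, h_T - 1e-8)
    expect_lte(fit$criterion, ncol(m))  # T <= p always
  }
})

test_that("consolidated small-p criterion is sandwiched by the enumeration optimum", {
  m <- planted_blocks(n = 18, sizes = c(4, 3), rho = 0.8, seed = 21)
  h <- clv_hierarchy(m)
  for (K in 2:3) {
    fit <- clv_consolidate(m, h$partitions[[K]])
    expect_gte(fit$criterion, oracle_criterion(m, h$partitions[[K]]) - 1e-8)
    expect_lte(fit$criterion, oracle_best_partition(scale(m), K) + 1e-8)
  }
})

test_that("criterion and memberships are invariant to sign flips", {
  m <- planted_blocks(n = 30, sizes = c(3, 3), rho = 0.8, seed = 4)
  flipped <- m
  flipped[, c(1, 4)] <- -flipped[, c(1, 4)]
  f1 <- clv(m, K = 2)
  f2 <- clv(flipped, K = 2)
  expect_equal(f1$criterion, f2$criterion, tolerance = 1e-10)
  expect_equal(partition_agreement(f1$assignment$cluster,
                                   f2$assignment$cluster), 1)
})

test_that("variable order does not change the fitted partition", {
  m <- planted_blocks(n = 30, sizes = c(4, 3), rho = 0.8, seed = 6)
  perm <- withr::with_seed(2, sample(ncol(m)))
  f1 <- clv(m, K = 2)
  f2 <- clv(m[, perm], K = 2)
  back <- f2$assignment$cluster[match(colnames(m), f2$assignment$variable)]
  expect_equal(partition_agreement(f1$assignment$cluster, back), 1)
  expect_equal(f1$criterion, f2$criterion, tolerance = 1e-10)
})

test_that("projection reproduces training scores and scales new subjects", {
  voi <- small_voi(seed = 17)
  fit <- clv(voi, K = 2)
  reproj <- project(fit, voi)
  expect_equal(unname(reproj), unname(fit$scores), tolerance = 1e-8)

  # a duplicated subject projects to identical scores
  dup <- voi[c(1, 1), ]
  pd <- project(fit, dup)
  expect_equal(pd[1, ], pd[2, ])

  # new subjects from the training distribution have ~unit score variance,
  # averaging over training and new samples (low-dimensional setting so
  # eigenvector overfitting is negligible; a single training sample's
  # standardization noise would otherwise dominate)
  vars <- vapply(1:30, function(s) {
    train <- planted_blocks(n = 60, sizes = c(3, 3), rho = 0.8,
                            seed = 40 + s)
    fit_lo <- clv(train, K = 2)
    new <- planted_blocks(n = 60, sizes = c(3, 3), rho = 0.8, seed = 500 + s)
    apply(project(fit_lo, new), 2, var)
  }, numeric(2))
  expect_equal(mean(vars), 1, tolerance = 0.1)

  expect_error(project(fit, voi[, 1:20]), "lacks model variable")
})

test_that("tidy and glance expose the fit in broom style", {
  m <- planted_blocks(n = 20, sizes = c(3, 2), rho = 0.8, seed = 1)
  fit <- clv(m, K = 2)
  td <- tidy(fit)
  expect_true(all(c("variable", "cluster", "importance", "sign") %in%
                    names(td)))
  sums <- as.numeric(tapply(td$importance, td$cluster, sum))
  expect_equal(sums, rep(1, 2), tolerance = 1e-10)
  g <- glance(fit)
  expect_equal(g$K, 2)
  expect_true(g$converged)
})
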