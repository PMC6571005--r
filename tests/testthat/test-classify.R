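ref_labels <- function(n_control, n_case) {
  tibble::tibble(
    subject = sprintf("S%03d", seq_len(n_control + n_case)),
    group = factor(rep(c("control", "case"), c(n_control, n_case)),
                   levels = c("control", "case"))
  )
}

test_that("k-means separates well-separated 1-D pairs deterministically", {
  sc <- matrix(c(-2, -1.9, 2, 2.1), dimnames = list(paste0("S", 1:4), NULL))
  cl <- kmeans_two(sc, seed = 1)
  expect_equal(cl$cluster, c(1L, 1L, 2L, 2L))
  expect_identical(kmeans_two(sc, seed = 1), kmeans_two(sc, seed = 1))
  expect_error(kmeans_two(matrix(rep(1, 4))), "identical")
})

test_that("1-D two-cluster k-means equals exhaustive threshold search", {
  for (i in 1:100) {
    x <- withr::with_seed(1000 + i, {
      n <- sample(4:12, 1)
      round(rnorm(n, sd = sample(c(0.5, 1, 3), 1)), 2)
    })
    if (length(unique(x)) < 2) next
    km <- kmeans_two(matrix(x), seed = i)
    oracle <- oracle_threshold_split(x)
    expect_equal(partition_agreement(km$cluster, oracle$cluster), 1,
                 info = paste("instance", i))
  }
})

test_that("alignment resolves label switching and ties deterministically", {
  ref <- ref_labels(3, 3)
  pred_same <- tibble::tibble(subject = ref$subject,
                              cluster = c(1L, 1L, 1L, 2L, 2L, 2L))
  al <- align_labels(pred_same, ref)
  expect_equal(mean(al$group_pred == ref$group), 1)
  pred_flip <- dplyr::mutate(pred_same, cluster = 3L - cluster)
  al2 <- align_labels(pred_flip, ref)
  expect_equal(mean(al2$group_pred == ref$group), 1)
  # exact tie: cluster 1 maps to control
  pred_tie <- tibble::tibble(subject = ref$subject,
                             cluster = c(1L, 2L, 1L, 2L, 1L, 2L))
  al3 <- align_labels(pred_tie, ref)
  expect_equal(as.character(al3$group_pred[al3$cluster == 1]),
               rep("control", 3))
  expect_error(align_labels(pred_same[1:4, ], ref), "different subjects")
})

test_that("aligned agreement of random labelings matches enumeration optimism", {
  # alignment picks max(B, n - B)/n for B matches under the identity mapping;
  # its expectation under independent balanced labels exceeds 1/2
  n <- 10
  ref <- ref_labels(5, 5)
  sim <- vapply(1:500, function(s) {
    cl <- withr::with_seed(s, sample(1:2, n, replace = TRUE))
    if (length(unique(cl)) < 2) return(NA_real_)
    al <- align_labels(tibble::tibble(subject = ref$subject, cluster = cl),
                       ref)
    mean(al$group_pred == ref$group)
  }, numeric(1))
  sim <- sim[!is.na(sim)]
  # exact expectation of max(B, n-B)/n, B ~ Binom(n, 1/2), via enumeration
  b <- 0:n
  exact <- sum(pmax(b, n - b) / n * dbinom(b, n, 0.5))
  expect_gt(mean(sim), 0.5)
  expect_equal(mean(sim), exact, tolerance = 0.05)
})

test_that("concordance reproduces hand-computed indices on fixed counts", {
  cc <- concordance_from_counts(4, 4, 1, 0)
  expect_equal(cc$n, 8)
  expect_equal(cc$agreement, 7 / 8)
  expect_equal(cc$sensitivity, 1)
  expect_equal(cc$specificity, 3 / 4)
  # kappa by the direct formula
  po <- 7 / 8
  pe <- (4 * 3 + 4 * 5) / 64
  expect_equal(cc$kappa, (po - pe) / (1 - pe))
  # perfect agreement
  cc2 <- concordance_from_counts(5, 5, 0, 0)
  expect_equal(cc2$kappa, 1)
  expect_equal(cc2$agreement, 1)
})

test_that("chi-square matches the generic contingency-table oracle", {
  for (i in 1:20) {
    counts <- withr::with_seed(i, {
      repeat {
        x <- sample(1:15, 4, replace = TRUE)
        if (all(rowSums(matrix(x, 2)) > 0) && all(colSums(matrix(x, 2)) > 0))
          break
      }
      x
    })
    tab <- matrix(counts, 2)
    cc <- concordance_from_counts(sum(tab[1, ]), sum(tab[2, ]),
                                  tab[1, 2], tab[2, 1])
    expect_equal(cc$chisq,
                 unname(suppressWarnings(
                   chisq.test(tab, correct = FALSE)$statistic)),
                 tolerance = 1e-8)
    expect_equal(cc$chisq_yates,
                 unname(suppressWarnings(
                   chisq.test(tab, correct = TRUE)$statistic)),
                 tolerance = 1e-8)
  }
})

test_that("kappa is centred at zero for independent labelings", {
  kappas <- vapply(1:1000, function(s) {
    pred <- withr::with_seed(s, sample(1:2, 20, replace = TRUE))
    if (length(unique(pred)) < 2) return(NA_real_)
    ref <- ref_labels(10, 10)
    al <- align_labels(tibble::tibble(subject = ref$subject,
                                      cluster = pred), ref)
    # kappa on the unaligned prediction (alignment inflates agreement, so
    # use the raw cluster-as-class mapping for the independence check)
    pd <- tibble::tibble(subject = ref$subject,
                         group = factor(ifelse(pred == 1, "control", "case"),
                                        levels = c("control", "case")))
    concordance(pd, ref)$kappa
  }, numeric(1))
  expect_lt(abs(mean(kappas, na.rm = TRUE)), 0.05)
})

test_that("agreement and kappa are invariant to cluster-label permutation", {
  voi <- small_voi(seed = 23)
  fit <- clv(voi, K = 2)
  pred <- kmeans_two(fit$scores, seed = 2)
  ref <- voi[, c("subject", "group")]
  a1 <- concordance(align_labels(pred, ref), ref)
  flipped <- dplyr::mutate(pred, cluster = 3L - cluster)
  a2 <- concordance(align_labels(flipped, ref), ref)
  expect_equal(a1$agreement, a2$agreement)
  expect_equal(a1$kappa, a2$kappa)
})

test_that("variable importance reflects construction", {
  # single-variable cluster
  m <- planted_blocks(20, c(1, 3), rho = 0.9, seed = 2)
  fit <- clv(m, K = 2)
  sizes <- table(fit$assignment$cluster)
  solo <- as.integer(names(sizes)[sizes == 1])
  expect_equal(variable_importance(fit, solo)$importance, 1)

  # two equally correlated variables split importance evenly
  f <- withr::with_seed(3, rnorm(30))
  m2 <- cbind(a = f + withr::with_seed(4, rnorm(30, sd = 0.3)),
              b = f + withr::with_seed(5, rnorm(30, sd = 0.3)))
  fit2 <- clv(m2, K = 1)
  expect_equal(variable_importance(fit2, 1)$importance, c(0.5, 0.5),
               tolerance = 1e-10)

  # a dominant variable receives the largest importance
  m3 <- cbind(dom = f,
              w1 = 0.3 * f + withr::with_seed(6, rnorm(30)),
              w2 = 0.3 * f + withr::with_seed(7, rnorm(30)),
              w3 = 0.3 * f + withr::with_seed(8, rnorm(30)))
  fit3 <- clv(m3, K = 1)
  imp <- variable_importance(fit3, 1)
  expect_equal(imp$variable[1], "dom")
  expect_error(variable_importance(fit3, 5), "No cluster")
})
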