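# Small fixture builders and independent oracles shared across test files.

# compact generator configuration for fast end-to-end runs: the six
# electrodes feeding the C3-C4/F8/F4/Fz/Pz analysis set, coarse sampling
small_cfg <- function(seed = 1, d = 1.5, n_factors = 1, ...) {
  sim_config(channels = c("C3", "C4", "F8", "F4", "Fz", "Pz"),
             n_factors = n_factors, effect_sizes = d,
             sampling_rate = 100, seed = seed, ...)
}

# VOI table for the 130-variable analysis set (5 channels x 26 variables)
small_voi <- function(seed = 1, d = 1.5, ...) {
  cfg <- small_cfg(seed = seed, d = d, ...)
  ep <- difference_channel(generate_waveforms(cfg))
  drop_redundant(build_voi_table(ep))
}

# block-correlated standardized-scale data: `sizes[k]` variables sharing a
# latent with loading sqrt(rho); returns a plain matrix with V1.. names
planted_blocks <- function(n, sizes, rho = 0.8, seed = 1) {
  withr::with_seed(seed, {
    cols <- unlist(lapply(seq_along(sizes), function(k) {
      f <- rnorm(n)
      replicate(sizes[k], sqrt(rho) * f + sqrt(1 - rho) * rnorm(n),
                simplify = FALSE)
    }), recursive = FALSE)
    m <- do.call(cbind, cols)
    colnames(m) <- paste0("V", seq_len(ncol(m)))
    m
  })
}

# --- independent oracles -----------------------------------------------------

# CLV criterion of one partition: sum over clusters of the leading eigenvalue
# of the cluster correlation matrix, from a plain eigen decomposition
oracle_criterion <- function(x, assignment) {
  sum(vapply(unique(assignment), function(k) {
    sub <- x[, assignment == k, drop = FALSE]
    if (ncol(sub) == 1) 1 else eigen(cor(sub), symmetric = TRUE,
                                     only.values = TRUE)$values[1]
  }, numeric(1)))
}

# all set partitions of 1..p (restricted growth strings)
all_partitions <- function(p) {
  out <- list()
  rec <- function(assign, next_block) {
    i <- length(assign) + 1
    if (i > p) {
      out[[length(out) + 1]] <<- assign
      return()
    }
    for (b in seq_len(next_block)) {
      rec(c(assign, b), max(next_block, b + 1))
    }
  }
  rec(integer(0), 1L)
  out
}

# best criterion over every partition with exactly K blocks (p <= 8)
oracle_best_partition <- function(x, K) {
  parts <- Filter(function(a) max(a) == K, all_partitions(ncol(x)))
  best <- -Inf
  for (a in parts) {
    val <- oracle_criterion(x, a)
    if (val > best) best <- val
  }
  best
}

# optimal 1-D two-cluster split by exhaustive threshold search (sorted data;
# every contiguous split is a candidate; k-means optima are contiguous in 1-D)
oracle_threshold_split <- function(x) {
  ord <- order(x)
  n <- length(x)
  best <- NULL
  best_ss <- Inf
  for (cut in 1:(n - 1)) {
    left <- x[ord[1:cut]]
    right <- x[ord[(cut + 1):n]]
    ss <- sum((left - mean(left))^2) + sum((right - mean(right))^2)
    if (ss < best_ss) {
      best_ss <- ss
      cl <- integer(n)
      cl[ord[1:cut]] <- 1L
      cl[ord[(cut + 1):n]] <- 2L
      best <- cl
    }
  }
  list(cluster = best, withinss = best_ss)
}

# agreement of two binary partitions up to label switching
partition_agreement <- function(a, b) {
  max(mean(a == b), mean(a != b))
}
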