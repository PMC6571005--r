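#' Standardize a subjects-by-variables table
#'
#' Column-wise z-scoring with the sample SD (n-1). The training means and SDs
#' are retained so held-out subjects can later be projected onto the same
#' scale. Zero-variance columns cannot be standardized and are removed with a
#' warning.
#'
#' @param x A VOI tibble (columns `subject`, `group`, variables) or a numeric
#'   matrix with subject rownames.
#' @return An object of class `std_matrix`: list with `Z` (n x p matrix),
#'   `center`, `scale` (named numeric) and `dropped` (character).
#' @export
standardize <- function(x) {
  m <- if (is.data.frame(x)) voi_matrix(x) else as.matrix(x)
  if (nrow(m) < 2) abort("Standardization needs at least 2 subjects.")
  if (anyNA(m)) abort("Standardization input contains missing values.")
  ctr <- colMeans(m)
  scl <- apply(m, 2, sd)
  dropped <- colnames(m)[scl == 0 | !is.finite(scl)]
  if (length(dropped) == ncol(m)) {
    abort("All columns have zero variance; nothing to standardize.")
  }
  if (length(dropped)) {
    warn(paste0("Dropping ", length(dropped), " zero-variance column(s): ",
                paste(head(dropped, 5), collapse = ", "),
                if (length(dropped) > 5) ", ..." else ""))
    keep <- setdiff(colnames(m), dropped)
    m <- m[, keep, drop = FALSE]
    ctr <- ctr[keep]
    scl <- scl[keep]
  }
  Z <- sweep(sweep(m, 2, ctr, "-"), 2, scl, "/")
  structure(list(Z = Z, center = ctr, scale = scl, dropped = dropped),
            class = "std_matrix")
}

as_std <- function(x) {
  if (inherits(x, "std_matrix")) x else standardize(x)
}

# Leading eigenvalue (and m-side eigenvector) of the correlation matrix of a
# standardized block, computed on the smaller of the p x p or n x n
# cross-products. Sign convention: loading sum >= 0 (first nonzero positive on
# an exact tie).
leading_component <- function(Z) {
  n <- nrow(Z)
  m <- ncol(Z)
  if (m == 1) {
    return(list(lambda = 1, v = 1))
  }
  if (m <= n) {
    e <- eigen(crossprod(Z) / (n - 1), symmetric = TRUE)
    lambda <- e$values[1]
    v <- e$vectors[, 1]
  } else {
    e <- eigen(tcrossprod(Z) / (n - 1), symmetric = TRUE)
    lambda <- e$values[1]
    v <- drop(crossprod(Z, e$vectors[, 1]))
    nv <- sqrt(sum(v^2))
    if (nv == 0) abort("Degenerate cluster: zero leading component.")
    v <- v / nv
  }
  s <- sum(v)
  if (s < 0 || (s == 0 && v[which(v != 0)[1]] < 0)) v <- -v
  list(lambda = lambda, v = v)
}

#' Latent variable of one cluster of variables
#'
#' The cluster's latent is the first standardized principal component of its
#' (already standardized) variables, scaled to unit variance and sign-oriented
#' so the loading sum is non-negative. The cluster's contribution to the CLV
#' criterion is the sum of squared variable-latent correlations, i.e. the
#' leading eigenvalue of the cluster's correlation matrix (1 for a single
#' variable).
#'
#' @param Z Standardized matrix (or `std_matrix`) restricted to the cluster's
#'   variables.
#' @return List: `scores` (length-n latent, unit variance), `loadings`
#'   (variable-latent correlations), `norm_loadings` (unit-norm eigenvector;
#'   squares sum to 1), `weights` (projection weights), `lambda` (criterion
#'   contribution t).
#' @export
cluster_latent <- function(Z) {
  if (inherits(Z, "std_matrix")) Z <- Z$Z
  Z <- as.matrix(Z)
  lc <- leading_component(Z)
  w <- lc$v / sqrt(lc$lambda)
  scores <- drop(Z %*% w)
  list(scores = scores,
       loadings = sqrt(lc$lambda) * lc$v,
       norm_loadings = lc$v,
       weights = w,
       lambda = lc$lambda)
}

#' Agglomerative hierarchy of variable clusters
#'
#' Starts from singleton clusters and, at each step, merges the pair of
#' clusters whose fusion least decreases the CLV criterion
#' T = sum over clusters of the leading eigenvalue of the cluster correlation
#' matrix. The criterion decrease of merging A and B is
#' Delta = t(A) + t(B) - t(A union B) >= 0. Because variables are
#' standardized, eigenvalues are computed additively from per-cluster
#' n x n Gram matrices, so each candidate costs one small symmetric
#' eigenvalue problem. Ties are broken toward the lowest cluster indices.
#'
#' @param x A VOI tibble, numeric matrix or `std_matrix` (p >= 2 variables).
#' @return An object of class `clv_hierarchy`: list with `partitions` (named
#'   list, `partitions[[K]]` = integer cluster assignment at K clusters),
#'   `delta` (tibble of merge steps), `criterion` (named numeric, T at each
#'   K), `var_names`.
#' @export
clv_hierarchy <- function(x) {
  std <- as_std(x)
  Z <- std$Z
  n <- nrow(Z)
  p <- ncol(Z)
  if (p < 2) abort("The hierarchy needs at least 2 variables.")
  vars <- colnames(Z)

  members <- as.list(seq_len(p))
  grams <- lapply(seq_len(p), function(j) tcrossprod(Z[, j]))
  tval <- rep(1, p)
  active <- rep(TRUE, p)

  lam_max <- function(G) {
    eigen(G / (n - 1), symmetric = TRUE, only.values = TRUE)$values[1]
  }

  # initial pairwise decreases: for singletons t(A u B) = 1 + |r|
  R <- crossprod(Z) / (n - 1)
  delta <- matrix(Inf, p, p)
  ut <- upper.tri(R)
  delta[ut] <- 1 - abs(R[ut])

  partitions <- vector("list", p)
  assignment <- seq_len(p)
  partitions[[p]] <- assignment
  steps <- vector("list", p - 1)

  for (step in seq_len(p - 1)) {
    k_now <- p - step + 1
    d_min <- min(delta[upper.tri(delta)])
    cand <- which(delta == d_min & upper.tri(delta), arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]
    j <- cand[1, 2]
    d_ij <- delta[i, j]

    grams[[i]] <- grams[[i]] + grams[[j]]
    members[[i]] <- c(members[[i]], members[[j]])
    tval[i] <- tval[i] + tval[j] - d_ij
    active[j] <- FALSE
    grams[j] <- list(NULL)
    delta[j, ] <- Inf
    delta[, j] <- Inf

    for (k in which(active)) {
      if (k == i) next
      d <- tval[i] + tval[k] - lam_max(grams[[i]] + grams[[k]])
      if (k < i) delta[k, i] <- d else delta[i, k] <- d
    }

    assignment[members[[i]]] <- i
    # renumber clusters 1..K in order of first variable appearance
    relab <- match(assignment, unique(assignment))
    partitions[[k_now - 1]] <- relab
    steps[[step]] <- tibble(step = step, k_after = k_now - 1,
                            delta = max(d_ij, 0))
  }

  delta_tbl <- bind_rows(steps)
  criterion <- p - cumsum(c(0, delta_tbl$delta))
  names(criterion) <- as.character(p:1)
  structure(list(partitions = partitions, delta = delta_tbl,
                 criterion = criterion, var_names = vars),
            class = "clv_hierarchy")
}

#' @export
print.clv_hierarchy <- function(x, ...) {
  p <- length(x$var_names)
  cat("<clv_hierarchy> ", p, " variables; criterion T: ",
      round(x$criterion[as.character(p)], 3), " (K=", p, ") -> ",
      round(x$criterion["1"], 3), " (K=1)\n", sep = "")
  invisible(x)
}

#' Consolidate a variable partition around its latent components
#'
#' Alternating refinement of a CLV partition: (a) recompute every cluster's
#' latent via [cluster_latent()]; (b) reassign each variable to the cluster
#' whose latent it squares-correlates with most (ties to the lowest cluster
#' index). The criterion T is non-decreasing across iterations; iteration
#' stops when the assignment is stable or after `max_iter` sweeps. A cluster
#' emptied by reassignment is re-seeded with the currently worst-fitted
#' variable.
#'
#' @param x A VOI tibble, numeric matrix or `std_matrix`.
#' @param init Integer vector (length p, values in 1..K): initial assignment,
#'   typically `clv_hierarchy(x)$partitions[[K]]`.
#' @param max_iter Maximum sweeps (default 100).
#' @return An object of class `clv_fit`; see [clv()] for its contents.
#' @export
clv_consolidate <- function(x, init, max_iter = 100) {
  if (max_iter < 1) abort("`max_iter` must be >= 1.")
  std <- as_std(x)
  Z <- std$Z
  n <- nrow(Z)
  p <- ncol(Z)
  if (length(init) != p) abort("`init` length must equal the variable count.")
  assignment <- match(init, sort(unique(init)))
  K <- max(assignment)

  trace <- numeric(0)
  converged <- FALSE
  comp <- NULL
  for (iter in seq_len(max_iter)) {
    comp <- lapply(seq_len(K), function(k) {
      cluster_latent(Z[, assignment == k, drop = FALSE])
    })
    t_now <- sum(vapply(comp, `[[`, numeric(1), "lambda"))
    if (length(trace) && t_now < tail(trace, 1) - 1e-8) {
      abort("Internal error: CLV criterion decreased during consolidation.")
    }
    trace <- c(trace, t_now)
    scores <- vapply(comp, `[[`, numeric(n), "scores")
    r2 <- (crossprod(Z, scores) / (n - 1))^2  # p x K squared correlations
    new_assign <- max.col(r2, ties.method = "first")
    # re-seed emptied clusters with the worst-fitted variable
    for (k in setdiff(seq_len(K), unique(new_assign))) {
      fit_of_own <- r2[cbind(seq_len(p), new_assign)]
      worst <- which.min(fit_of_own)
      new_assign[worst] <- k
    }
    if (all(new_assign == assignment)) {
      converged <- TRUE
      break
    }
    assignment <- new_assign
  }
  if (!converged) {
    # max_iter exhausted after a reassignment: refresh latents to match
    comp <- lapply(seq_len(K), function(k) {
      cluster_latent(Z[, assignment == k, drop = FALSE])
    })
    t_now <- sum(vapply(comp, `[[`, numeric(1), "lambda"))
    if (t_now < tail(trace, 1) - 1e-8) {
      abort("Internal error: CLV criterion decreased during consolidation.")
    }
    trace <- c(trace, t_now)
  }

  scores <- vapply(comp, `[[`, numeric(n), "scores")
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = K)
  colnames(scores) <- paste0("LV", seq_len(K))
  rownames(scores) <- rownames(Z)

  loadings <- purrr::map_dfr(seq_len(K), function(k) {
    idx <- which(assignment == k)
    tibble(variable = colnames(Z)[idx], cluster = k,
           loading = comp[[k]]$loadings,
           norm_loading = comp[[k]]$norm_loadings,
           weight = comp[[k]]$weights)
  })

  structure(list(
    K = K,
    assignment = tibble(variable = colnames(Z), cluster = assignment),
    scores = scores,
    loadings = loadings,
    lambda = vapply(comp, `[[`, numeric(1), "lambda"),
    criterion = tail(trace, 1),
    trace = trace,
    center = std$center, scale = std$scale, dropped = std$dropped,
    iterations = length(trace),
    converged = converged,
    n = n, p = p
  ), class = "clv_fit")
}

#' Fit a CLV model
#'
#' Clustering of variables around latent components: variables are
#' standardized, partitioned into `K` clusters by the agglomerative hierarchy
#' ([clv_hierarchy()]), and the partition is refined by alternating
#' consolidation ([clv_consolidate()]). Each cluster is summarized by its
#' first standardized principal component (the latent variable); the fit
#' criterion T is the sum over clusters of squared variable-latent
#' correlations.
#'
#' @param x A VOI tibble (columns `subject`, `group`, variables), numeric
#'   matrix, or `std_matrix`.
#' @param K Number of clusters / latent variables.
#' @param max_iter Consolidation sweep limit.
#' @return A `clv_fit`: `K`, `assignment` (tibble variable/cluster), `scores`
#'   (n x K, unit-variance latents), `loadings` (per-variable correlation
#'   loading, normalized loading with squares summing to 1 per cluster, and
#'   projection weight), `lambda` (per-cluster criterion contributions),
#'   `criterion` (T), `trace`, the training standardization (`center`,
#'   `scale`) and convergence info.
#' @export
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(60), 10)
#' colnames(m) <- paste0("V", 1:6)
#' fit <- clv(m, K = 2)
#' glance(fit)
clv <- function(x, K, max_iter = 100) {
  std <- as_std(x)
  p <- ncol(std$Z)
  if (K < 1 || K > p) abort("`K` must lie in 1..p.")
  init <- if (K == 1) rep(1L, p) else clv_hierarchy(std)$partitions[[K]]
  clv_consolidate(std, init, max_iter = max_iter)
}

#' @export
print.clv_fit <- function(x, ...) {
  cat("<clv_fit> K = ", x$K, "; ", x$p, " variables, ", x$n, " subjects; ",
      "criterion T = ", round(x$criterion, 4),
      if (x$converged) " (converged)" else " (max_iter reached)", "\n",
      sep = "")
  cat("  cluster sizes: ",
      paste(table(x$assignment$cluster), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname clv
#' @param x,object A `clv_fit`.
#' @param ... Unused.
#' @method tidy clv_fit
#' @export
tidy.clv_fit <- function(x, ...) {
  x$loadings |>
    mutate(importance = .data$norm_loading^2,
           sign = ifelse(.data$loading >= 0, "+", "-"))
}

#' @rdname clv
#' @method glance clv_fit
#' @export
glance.clv_fit <- function(x, ...) {
  tibble(K = x$K, n = x$n, p = x$p, criterion = x$criterion,
         iterations = x$iterations, converged = x$converged)
}

#' Project new subjects onto a fitted CLV model
#'
#' Standardizes the new rows with the model's stored training means and SDs,
#' then applies the stored per-cluster projection weights, yielding latent
#' scores on the training scale. Projecting the training subjects themselves
#' reproduces the training scores.
#'
#' @param model A `clv_fit`.
#' @param newdata A VOI tibble or numeric matrix carrying every variable the
#'   model uses.
#' @return A numeric matrix (rows = new subjects, columns = LV1..LVK).
#' @export
project <- function(model, newdata) {
  stopifnot(inherits(model, "clv_fit"))
  m <- if (is.data.frame(newdata)) voi_matrix(newdata) else as.matrix(newdata)
  vars <- names(model$center)
  missing_vars <- setdiff(vars, colnames(m))
  if (length(missing_vars)) {
    abort(paste0("New data lacks model variable(s): ",
                 paste(head(missing_vars, 5), collapse = ", "),
                 if (length(missing_vars) > 5) ", ..." else ""))
  }
  m <- m[, vars, drop = FALSE]
  Z <- sweep(sweep(m, 2, model$center, "-"), 2, model$scale, "/")
  W <- matrix(0, length(vars), model$K,
              dimnames = list(vars, paste0("LV", seq_len(model$K))))
  W[cbind(match(model$loadings$variable, vars), model$loadings$cluster)] <-
    model$loadings$weight
  Z %*% W
}
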