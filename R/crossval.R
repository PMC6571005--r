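#' Stratified train/test split
#'
#' Draws a test set of `round(n * test_fraction)` subjects whose class
#' composition mirrors the whole sample: per-class targets start at the floor
#' of `class_n * test_fraction` and remaining seats are assigned by largest
#' fractional remainder (ties toward the larger class, then class order), so
#' 39 subjects (20 control / 19 case) at 20% yield an 8-subject test set with
#' 4 of each class and a 31-subject training set.
#'
#' @param labels Tibble `subject`, `group`.
#' @param test_fraction Fraction of subjects held out, in (0, 1).
#' @param seed Integer seed.
#' @return List with character vectors `train` and `test` (subject ids).
#' @export
stratified_split <- function(labels, test_fraction = 0.2, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("`test_fraction` must lie strictly between 0 and 1.")
  }
  counts <- table(labels$group)
  if (any(counts < 2)) abort("Need at least 2 subjects per class.")
  n <- nrow(labels)
  n_test <- round(n * test_fraction)
  quota <- as.numeric(counts) * test_fraction
  base <- floor(quota)
  extra <- n_test - sum(base)
  if (extra > 0) {
    pri <- order(-(quota - base), -as.numeric(counts))
    base[pri[seq_len(extra)]] <- base[pri[seq_len(extra)]] + 1
  }
  test_ids <- with_seed(seed, {
    unlist(purrr::map2(names(counts), base, function(g, k) {
      pool <- labels$subject[labels$group == g]
      sample(pool, k)
    }))
  })
  list(train = setdiff(labels$subject, test_ids), test = sort(test_ids))
}

# cluster -> class mapping implied by an aligned labeling
cluster_map <- function(aligned) {
  distinct(aligned[, c("cluster", "group_pred")])
}

# latent-space centroids of the training clusters
cluster_centroids <- function(scores, clusters) {
  rbind(colMeans(scores[clusters == 1, , drop = FALSE]),
        colMeans(scores[clusters == 2, , drop = FALSE]))
}

#' Select the number of latent variables on a training set
#'
#' For each candidate K, fits the CLV partition (hierarchy computed once,
#' then consolidated at each K), reclassifies the training subjects with
#' two-cluster k-means on the K latent scores, aligns clusters to classes and
#' records the training agreement. Returns the K with the highest training
#' agreement, the smallest such K on ties.
#'
#' @param voi Training VOI tibble (`subject`, `group`, variables).
#' @param k_range Candidate numbers of latent variables (default 1:6).
#' @param restarts,seed Passed to [kmeans_two()].
#' @param max_iter Consolidation sweep limit.
#' @return List: `best_k`, `by_k` (tibble K / criterion / train_agreement),
#'   `fits` (named list of `clv_fit`s), `labelings` (per-K aligned tibbles).
#' @export
select_n_lv <- function(voi, k_range = 1:6, restarts = 50, seed = 1L,
                        max_iter = 100) {
  labels <- voi[, id_cols()]
  if (dplyr::n_distinct(labels$group) < 2) {
    abort("Training set must contain both classes.")
  }
  std <- standardize(voi)
  p <- ncol(std$Z)
  k_range <- sort(unique(pmin(k_range, p)))
  hier <- if (max(k_range) > 1) clv_hierarchy(std) else NULL
  fits <- list()
  labelings <- list()
  rows <- purrr::map(k_range, function(k) {
    init <- if (k == 1) rep(1L, p) else hier$partitions[[k]]
    fit <- clv_consolidate(std, init, max_iter = max_iter)
    pred <- kmeans_two(fit$scores, restarts = restarts, seed = seed)
    aligned <- align_labels(pred, labels)
    agree <- mean(aligned$group_pred == labels$group[
      match(aligned$subject, labels$subject)])
    fits[[paste0("K", k)]] <<- fit
    labelings[[paste0("K", k)]] <<- aligned
    tibble(K = k, criterion = fit$criterion, train_agreement = agree)
  })
  by_k <- bind_rows(rows)
  best_k <- by_k$K[which.max(by_k$train_agreement)]  # first max = smallest K
  list(best_k = best_k, by_k = by_k, fits = fits, labelings = labelings)
}

#' Stratified repeated cross-validation of the reclassification pipeline
#'
#' Per repetition: a stratified split; standardization, CLV fitting and
#' latent-count selection on the training subjects only; projection of the
#' held-out subjects onto the training latents; assignment of each test
#' subject to the nearest training k-means centroid (Euclidean distance in
#' latent space); and the training and test agreement with the reference
#' labeling under the training cluster-to-class alignment. The master seed
#' expands to per-repetition substreams.
#'
#' @param voi VOI tibble (`subject`, `group`, variables).
#' @param reps Number of repetitions (default 100).
#' @param test_fraction Held-out fraction (default 0.2).
#' @param k_range Candidate numbers of latent variables (default 1:6).
#' @param restarts k-means restarts.
#' @param seed Master integer seed.
#' @return An object of class `cv_result`: `reps` (tibble: rep, seed,
#'   k, train_agreement, test_agreement, assignment list-col with per-subject
#'   role/cluster/prediction), plus the call parameters. [glance()] gives
#'   the aggregates (modal K with frequency, mean train/test agreement).
#' @export
run_cv <- function(voi, reps = 100, test_fraction = 0.2, k_range = 1:6,
                   restarts = 50, seed = 1L) {
  vars <- setdiff(names(voi), id_cols())
  if (length(vars) < 2) abort("The VOI subset must carry at least 2 variables.")
  labels <- voi[, id_cols()]

  one_rep <- function(r) {
    seed_r <- substream_seed(seed, r, 7L)
    split <- stratified_split(labels, test_fraction, seed = seed_r)
    train <- voi[voi$subject %in% split$train, , drop = FALSE]
    test <- voi[voi$subject %in% split$test, , drop = FALSE]

    sel <- select_n_lv(train, k_range = k_range, restarts = restarts,
                       seed = seed_r)
    fit <- sel$fits[[paste0("K", sel$best_k)]]
    aligned_train <- sel$labelings[[paste0("K", sel$best_k)]]
    map <- cluster_map(aligned_train)

    train_clusters <- aligned_train$cluster[
      match(rownames(fit$scores), aligned_train$subject)]
    centroids <- cluster_centroids(fit$scores, train_clusters)
    test_scores <- project(fit, test)
    d2 <- vapply(1:2, function(k) {
      rowSums(sweep(test_scores, 2, centroids[k, ], "-")^2)
    }, numeric(nrow(test_scores)))
    test_cluster <- max.col(-d2, ties.method = "first")
    test_pred <- map$group_pred[match(test_cluster, map$cluster)]

    train_agree <- mean(aligned_train$group_pred ==
                          labels$group[match(aligned_train$subject,
                                             labels$subject)])
    test_agree <- mean(test_pred == test$group)

    assignment <- bind_rows(
      tibble(subject = aligned_train$subject, role = "train",
             cluster = aligned_train$cluster,
             group_pred = aligned_train$group_pred),
      tibble(subject = test$subject, role = "test",
             cluster = as.integer(test_cluster), group_pred = test_pred)
    )
    tibble(rep = r, seed = seed_r, k = sel$best_k,
           train_agreement = train_agree, test_agreement = test_agree,
           assignment = list(assignment))
  }

  res <- purrr::map_dfr(seq_len(reps), one_rep)
  structure(list(reps = res, labels = labels,
                 params = list(reps = reps, test_fraction = test_fraction,
                               k_range = k_range, restarts = restarts,
                               seed = seed, n_variables = length(vars))),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  g <- glance(x)
  cat("<cv_result> ", g$reps, " repetitions, ", x$params$n_variables,
      " variables\n", sep = "")
  cat(sprintf("  modal K = %d (%.0f%%); mean agreement: train %.1f%%, test %.1f%%\n",
              g$modal_k, 100 * g$modal_k_freq, 100 * g$mean_train,
              100 * g$mean_test))
  invisible(x)
}

#' @rdname run_cv
#' @param x,object A `cv_result`.
#' @param ... Unused.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) {
  select(x$reps, -"assignment")
}

#' @rdname run_cv
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  ktab <- sort(table(x$reps$k), decreasing = TRUE)
  tibble(reps = nrow(x$reps),
         modal_k = as.integer(names(ktab)[1]),
         modal_k_freq = as.numeric(ktab[1]) / nrow(x$reps),
         mean_train = mean(x$reps$train_agreement),
         mean_test = mean(x$reps$test_agreement))
}

#' Subset a VOI table to a channel set
#'
#' Keeps the ERP variables of the named channels (metadata parsed from the
#' column names) and optionally the behavioral and/or WISC blocks.
#'
#' @param voi VOI tibble.
#' @param channels Character vector of channel names (`NULL` = all ERP
#'   channels; `character(0)` = none).
#' @param include_behavior,include_wisc Keep the `BEH_*` / `WISC_*` columns?
#' @return The VOI subset (ids retained).
#' @export
select_variable_set <- function(voi, channels = NULL,
                                include_behavior = FALSE,
                                include_wisc = FALSE) {
  meta <- voi_metadata(voi)
  if (is.null(channels)) {
    channels <- unique(meta$channel[meta$source == "ERP"])
  }
  missing_ch <- setdiff(channels, meta$channel[meta$source == "ERP"])
  if (length(missing_ch)) {
    abort(paste0("Channel(s) not in VOI table: ",
                 paste(missing_ch, collapse = ", ")))
  }
  keep <- meta$variable[(meta$source == "ERP" & meta$channel %in% channels) |
                          (include_behavior & meta$source == "BEH") |
                          (include_wisc & meta$source == "WISC")]
  voi[, c(id_cols(), keep), drop = FALSE]
}

#' Scan candidate channel sets by cross-validated agreement
#'
#' Runs [run_cv()] for every configured channel set (and the composite
#' behavioral/WISC rows) on the peak-amplitude + peak-latency variables and
#' returns a ranked table of mean test agreement. A set that fails is
#' recorded with `NA` results and the scan continues.
#'
#' @param voi VOI tibble (mean-amplitude columns are dropped internally via
#'   [drop_redundant()]).
#' @param sets Channel-set configuration, as from [channel_sets_default()].
#' @param reps,test_fraction,k_range,restarts,seed Passed to [run_cv()].
#' @return Tibble, one row per set, sorted by decreasing mean test agreement:
#'   id, label, n_variables, modal_k, modal_k_freq, mean_train, mean_test,
#'   failed.
#' @export
channel_set_scan <- function(voi, sets = channel_sets_default(), reps = 100,
                             test_fraction = 0.2, k_range = 1:6,
                             restarts = 50, seed = 1L) {
  voi <- drop_redundant(voi)
  rows <- purrr::map(seq_len(nrow(sets)), function(i) {
    row <- sets[i, ]
    out <- tibble(id = row$id, label = row$label,
                  n_variables = NA_integer_, modal_k = NA_integer_,
                  modal_k_freq = NA_real_, mean_train = NA_real_,
                  mean_test = NA_real_, failed = TRUE)
    tryCatch({
      sub <- select_variable_set(voi, channels = row$channels[[1]],
                                 include_behavior = row$include_behavior,
                                 include_wisc = row$include_wisc)
      cv <- run_cv(sub, reps = reps, test_fraction = test_fraction,
                   k_range = k_range, restarts = restarts, seed = seed)
      g <- glance(cv)
      out <- tibble(id = row$id, label = row$label,
                    n_variables = length(setdiff(names(sub), id_cols())),
                    modal_k = g$modal_k, modal_k_freq = g$modal_k_freq,
                    mean_train = g$mean_train, mean_test = g$mean_test,
                    failed = FALSE)
    }, error = function(e) {
      warn(paste0("Channel set ", row$id, " (", row$label, ") failed: ",
                  conditionMessage(e)))
    })
    out
  })
  bind_rows(rows) |> arrange(dplyr::desc(.data$mean_test))
}

#' Fit the final reclassification model on all subjects
#'
#' Fits the CLV model at the chosen K on every subject, reclassifies with
#' two-cluster k-means on the latent scores, aligns clusters to the
#' reference classes, and reports the concordance and the squared-loading
#' variable importance of each latent.
#'
#' @param voi VOI tibble (already subset to the chosen variable set).
#' @param K Number of latent variables.
#' @param restarts,seed Passed to [kmeans_two()].
#' @return An object of class `final_fit`: list with `model` (`clv_fit`),
#'   `labeling` (aligned tibble), `concordance` and `importance` (list of
#'   per-cluster tibbles).
#' @export
fit_final <- function(voi, K = 1, restarts = 50, seed = 1L) {
  if (K < 1) abort("`K` must be >= 1.")
  labels <- voi[, id_cols()]
  model <- clv(voi, K = K)
  pred <- kmeans_two(model$scores, restarts = restarts, seed = seed)
  aligned <- align_labels(pred, labels)
  conc <- concordance(aligned, labels)
  imp <- lapply(seq_len(model$K), function(k) variable_importance(model, k))
  structure(list(model = model, labeling = aligned, concordance = conc,
                 importance = imp),
            class = "final_fit")
}

#' @export
print.final_fit <- function(x, ...) {
  cat("<final_fit> K =", x$model$K, "\n")
  print(x$concordance)
  invisible(x)
}

#' @rdname fit_final
#' @param x,object A `final_fit`.
#' @param ... Unused.
#' @method glance final_fit
#' @export
glance.final_fit <- function(x, ...) {
  bind_cols(glance(x$model)[, c("K", "n", "p", "criterion")],
            glance(x$concordance)[, c("agreement", "kappa", "sensitivity",
                                      "specificity")])
}
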