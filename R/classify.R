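#' Two-cluster k-means reclassification of subjects
#'
#' Partitions subjects into two clusters from their latent scores with
#' `restarts` seeded random initializations, keeping the lowest
#' within-cluster-sum-of-squares solution. Cluster numbering is canonicalized
#' (cluster 1 = the cluster containing the first subject), so the result is a
#' pure function of (scores, restarts, seed). On one-dimensional scores with
#' this many restarts the search is effectively exhaustive over threshold
#' splits.
#'
#' @param scores Numeric matrix of latent scores (rows = subjects, rownames =
#'   subject ids) or a tibble with a `subject` column.
#' @param restarts Number of k-means initializations (default 50).
#' @param seed Integer seed for the initializations.
#' @return Tibble: `subject`, `cluster` (integer 1/2).
#' @export
kmeans_two <- function(scores, restarts = 50, seed = 1L) {
  if (is.data.frame(scores)) {
    ids <- scores$subject
    m <- as.matrix(scores[, setdiff(names(scores), "subject"), drop = FALSE])
  } else {
    m <- as.matrix(scores)
    ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  }
  storage.mode(m) <- "double"
  if (nrow(m) < 2) abort("k-means needs at least 2 subjects.")
  if (nrow(unique(m)) < 2) {
    abort("All subjects have identical scores; two clusters are undefined.")
  }
  km <- with_seed(seed, kmeans(m, centers = 2, nstart = restarts,
                               iter.max = 100))
  cl <- km$cluster
  if (cl[1] != 1L) cl <- 3L - cl
  tibble(subject = ids, cluster = as.integer(cl))
}

#' Align data-driven clusters to reference classes
#'
#' k-means clusters carry no class meaning; of the two possible
#' cluster-to-class mappings this returns the one maximizing agreement with
#' the reference labeling (ties resolved toward mapping cluster 1 to
#' control).
#'
#' @param predicted Tibble `subject`, `cluster` (1/2), as from
#'   [kmeans_two()].
#' @param reference Tibble `subject`, `group` (control/case).
#' @return Tibble: `subject`, `cluster`, `group_pred` (factor control/case).
#' @export
align_labels <- function(predicted, reference) {
  if (!setequal(predicted$subject, reference$subject)) {
    abort("Predicted and reference labelings cover different subjects.")
  }
  d <- left_join(predicted, reference, by = "subject")
  agree_12 <- mean((d$cluster == 1) == (d$group == "control"))
  map_control <- if (agree_12 >= 0.5) 1L else 2L
  d$group_pred <- factor(ifelse(d$cluster == map_control, "control", "case"),
                         levels = c("control", "case"))
  d[, c("subject", "cluster", "group_pred")]
}

#' Concordance between a data-driven and a reference labeling
#'
#' Cross-tabulates the two labelings and reports: agreement (matches / n),
#' Cohen's kappa (po - pe)/(1 - pe) with pe from the marginal products,
#' sensitivity (reference cases assigned to the case cluster / reference
#' cases), specificity (analogous for controls), and the Pearson chi-square
#' statistic on the 2x2 table (1 d.f.), with the Yates-corrected value
#' alongside.
#'
#' @param predicted Aligned labeling: tibble `subject`, `group_pred`
#'   (as from [align_labels()]), or `subject`, `group` when comparing two
#'   reference-style labelings.
#' @param reference Tibble `subject`, `group`.
#' @return An object of class `concordance`.
#' @export
#' @examples
#' ref <- tibble::tibble(subject = sprintf("S%02d", 1:6),
#'                       group = factor(rep(c("control", "case"), each = 3),
#'                                      levels = c("control", "case")))
#' concordance(dplyr::rename(ref, group_pred = group), ref)
concordance <- function(predicted, reference) {
  if (!"group_pred" %in% names(predicted)) {
    predicted <- rename(predicted, group_pred = "group")
  }
  if (nrow(reference) == 0) abort("Empty labeling.")
  if (!setequal(predicted$subject, reference$subject)) {
    abort("Predicted and reference labelings cover different subjects.")
  }
  d <- left_join(reference, predicted, by = "subject")
  lv <- c("control", "case")
  tab <- table(reference = factor(d$group, lv),
               predicted = factor(d$group_pred, lv))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 1
  sens <- tab["case", "case"] / sum(tab["case", ])
  spec <- tab["control", "control"] / sum(tab["control", ])
  # Pearson chi-square, 1 d.f., with the Yates-corrected companion
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; dd <- tab[2, 2]
  marg <- prod(c(sum(tab[1, ]), sum(tab[2, ]), sum(tab[, 1]), sum(tab[, 2])))
  chisq <- if (marg > 0) n * (a * dd - b * c_)^2 / marg else NA_real_
  chisq_yates <- if (marg > 0) {
    n * max(abs(a * dd - b * c_) - n / 2, 0)^2 / marg
  } else NA_real_
  p_value <- if (is.na(chisq)) NA_real_ else
    stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  misclassified <- d$subject[d$group != d$group_pred]
  structure(list(table = tab, n = n, agreement = po, kappa = kappa,
                 sensitivity = sens, specificity = spec,
                 chisq = chisq, chisq_yates = chisq_yates,
                 p_value = p_value, misclassified = misclassified),
            class = "concordance")
}

#' @export
print.concordance <- function(x, digits = 4, ...) {
  cat("<concordance> n =", x$n, "\n")
  print(x$table)
  cat(sprintf("agreement %.2f%%  kappa %.3f  sensitivity %.2f%%  specificity %.2f%%\n",
              100 * x$agreement, x$kappa, 100 * x$sensitivity,
              100 * x$specificity))
  cat(sprintf("chi-square (1 d.f.) %.3f (Yates %.3f), p = %.4g\n",
              x$chisq, x$chisq_yates, x$p_value))
  if (length(x$misclassified)) {
    cat("misclassified:", paste(x$misclassified, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname concordance
#' @param x,object A `concordance`.
#' @param ... Unused.
#' @method tidy concordance
#' @export
tidy.concordance <- function(x, ...) {
  as_tibble(as.data.frame(x$table)) |>
    rename(count = "Freq")
}

#' @rdname concordance
#' @method glance concordance
#' @export
glance.concordance <- function(x, ...) {
  tibble(n = x$n, agreement = x$agreement, kappa = x$kappa,
         sensitivity = x$sensitivity, specificity = x$specificity,
         chisq = x$chisq, chisq_yates = x$chisq_yates, p_value = x$p_value,
         n_misclassified = length(x$misclassified))
}

#' Concordance from printed 2x2 counts
#'
#' Convenience constructor for desk-checking published cross-tables: builds
#' the subject-level labelings implied by the four cell counts and calls
#' [concordance()].
#'
#' @param n_control,n_case Reference class sizes.
#' @param controls_in_case_cluster,cases_in_control_cluster The two
#'   off-diagonal counts.
#' @return A `concordance`.
#' @export
#' @examples
#' # 20 controls / 19 cases; 5 controls and 2 cases cross over
#' glance(concordance_from_counts(20, 19, 5, 2))
concordance_from_counts <- function(n_control, n_case,
                                    controls_in_case_cluster,
                                    cases_in_control_cluster) {
  ref <- tibble(
    subject = sprintf("S%03d", seq_len(n_control + n_case)),
    group = factor(rep(c("control", "case"), c(n_control, n_case)),
                   levels = c("control", "case"))
  )
  pred <- ref
  flip_ctrl <- seq_len(controls_in_case_cluster)
  flip_case <- n_control + seq_len(cases_in_control_cluster)
  pred$group <- as.character(pred$group)
  pred$group[flip_ctrl] <- "case"
  pred$group[flip_case] <- "control"
  pred$group <- factor(pred$group, levels = c("control", "case"))
  concordance(pred, ref)
}

#' Per-variable importance of a latent component
#'
#' Squared normalized loadings of one cluster's variables (they sum to one
#' within the cluster), with each variable's loading sign, merged with the
#' parsed variable metadata for channel/window/measure reporting.
#'
#' @param model A `clv_fit`.
#' @param cluster Cluster (latent variable) index.
#' @return Tibble: `variable`, `importance`, `sign`, plus metadata columns,
#'   sorted by decreasing importance.
#' @export
variable_importance <- function(model, cluster = 1L) {
  stopifnot(inherits(model, "clv_fit"))
  if (!cluster %in% model$loadings$cluster) {
    abort(paste0("No cluster ", cluster, " in this fit (K = ", model$K, ")."))
  }
  ld <- model$loadings[model$loadings$cluster == cluster, ]
  out <- tibble(variable = ld$variable,
                importance = ld$norm_loading^2,
                sign = ifelse(ld$loading >= 0, "+", "-"))
  meta <- tryCatch(voi_metadata(out$variable), error = function(e) NULL)
  if (!is.null(meta)) out <- left_join(out, meta, by = "variable")
  arrange(out, dplyr::desc(.data$importance))
}
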