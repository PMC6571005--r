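#' Compute ANT behavioral variables per subject
#'
#' Summarises a trial table into the 29-column behavioral schema used for
#' classification: accuracy (AC), mean reaction time (RT) and intra-individual
#' variation of RT (IVRT, the within-subject SD of RT) for the overall task
#' and for each cue (no/neutral/spatial) and target-congruency condition;
#' the three attention-network scores; mean RT of correct and of incorrect
#' responses; first- and last-block RT and IVRT; and the two learning-rate
#' ratios. RT summaries use correct trials only (except `BEH_RT_incorrect`);
#' IVRT is the sample SD (n-1 denominator).
#'
#' Network scores are the standard child-ANT contrasts on correct-trial means:
#' alerting = RT(no cue) - RT(neutral cue); orienting = RT(neutral) -
#' RT(spatial); conflict = RT(incongruent) - RT(congruent).
#'
#' @param trials Tibble with columns `subject`, `block`, `cue`, `congruency`,
#'   `rt`, `correct` (as from [generate_trials()]).
#' @param learning_direction `"first_over_last"` (default) or
#'   `"last_over_first"`: orientation of the learning-rate ratios (the second
#'   matches the layout of some deposited spreadsheets).
#' @return A tibble, one row per subject, with 29 `BEH_*` columns. Conditions
#'   with no correct trial yield `NA` and an informative message.
#' @export
#' @examples
#' cfg <- sim_config(n_control = 2, n_case = 2, seed = 2)
#' beh <- compute_behavior(generate_trials(cfg))
#' ncol(beh) - 1  # 29 behavioral variables
compute_behavior <- function(trials,
                             learning_direction = c("first_over_last",
                                                    "last_over_first")) {
  learning_direction <- match.arg(learning_direction)
  if (nrow(trials) == 0) abort("Empty trial table.")
  need <- c("subject", "block", "cue", "congruency", "rt", "correct")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    abort(paste0("Trial table lacks column(s): ", paste(miss, collapse = ", ")))
  }

  conds <- list(
    all = function(d) d,
    no = function(d) d[d$cue == "no", ],
    neutral = function(d) d[d$cue == "neutral", ],
    spatial = function(d) d[d$cue == "spatial", ],
    congruent = function(d) d[d$congruency == "congruent", ],
    incongruent = function(d) d[d$congruency == "incongruent", ]
  )

  rt_sum <- function(d, who) {
    ok <- d[d$correct, ]
    if (nrow(ok) == 0) {
      inform(paste0("Subject ", who, ": no correct trials in a condition; ",
                    "RT/IVRT set to NA."))
      return(c(rt = NA_real_, ivrt = NA_real_))
    }
    c(rt = mean(ok$rt), ivrt = if (nrow(ok) > 1) sd(ok$rt) else 0)
  }

  one <- function(d) {
    subj <- d$subject[1]
    out <- list()
    for (cn in names(conds)) {
      dd <- conds[[cn]](d)
      out[[paste0("BEH_AC_", cn)]] <-
        if (nrow(dd)) mean(dd$correct) else NA_real_
      s <- rt_sum(dd, subj)
      out[[paste0("BEH_RT_", cn)]] <- unname(s["rt"])
      out[[paste0("BEH_IVRT_", cn)]] <- unname(s["ivrt"])
    }
    out$BEH_alerting <- out$BEH_RT_no - out$BEH_RT_neutral
    out$BEH_orienting <- out$BEH_RT_neutral - out$BEH_RT_spatial
    out$BEH_conflict <- out$BEH_RT_incongruent - out$BEH_RT_congruent
    out$BEH_RT_correct <- out$BEH_RT_all
    inc <- d[!d$correct, ]
    out$BEH_RT_incorrect <- if (nrow(inc)) mean(inc$rt) else NA_real_
    b1 <- rt_sum(d[d$block == min(d$block), ], subj)
    bl <- rt_sum(d[d$block == max(d$block), ], subj)
    out$BEH_RT_block_first <- unname(b1["rt"])
    out$BEH_RT_block_last <- unname(bl["rt"])
    out$BEH_IVRT_block_first <- unname(b1["ivrt"])
    out$BEH_IVRT_block_last <- unname(bl["ivrt"])
    ratio <- function(a, b) {
      if (learning_direction == "first_over_last") a / b else b / a
    }
    out$BEH_learning_RT <- ratio(out$BEH_RT_block_first, out$BEH_RT_block_last)
    out$BEH_learning_IVRT <- ratio(out$BEH_IVRT_block_first,
                                   out$BEH_IVRT_block_last)
    as_tibble(c(list(subject = subj), out))
  }

  trials |>
    dplyr::group_split(.data$subject) |>
    purrr::map_dfr(one)
}

#' Apply the subject exclusion rules
#'
#' Excludes subjects with overall accuracy below `ac_min`, then (in the same
#' single pass) subjects whose speed-accuracy tradeoff AC x RT falls more than
#' `tradeoff_sd` sample SDs below the sample mean of that product. The
#' tradeoff mean and SD are computed once on all supplied subjects; the rule
#' is deliberately not iterated on the survivors.
#'
#' @param behavior Tibble from [compute_behavior()] (needs `BEH_AC_all` and
#'   `BEH_RT_all`).
#' @param ac_min Minimum accepted accuracy (default 0.70).
#' @param tradeoff_sd SD multiplier of the tradeoff rule (default 2).
#' @return A list with tibbles `kept` and `excluded`; `excluded` carries a
#'   `reason` column.
#' @export
qc_filter <- function(behavior, ac_min = 0.70, tradeoff_sd = 2) {
  if (nrow(behavior) < 3) {
    abort("qc_filter needs at least 3 subjects (tradeoff SD needs d.f.).")
  }
  tradeoff <- behavior$BEH_AC_all * behavior$BEH_RT_all
  cutoff <- mean(tradeoff) - tradeoff_sd * sd(tradeoff)
  reason <- dplyr::case_when(
    behavior$BEH_AC_all < ac_min ~ sprintf("AC < %d%%", round(100 * ac_min)),
    tradeoff < cutoff ~ sprintf("AC x RT below mean - %g SD", tradeoff_sd),
    TRUE ~ NA_character_
  )
  list(
    kept = behavior[is.na(reason), , drop = FALSE],
    excluded = bind_cols(behavior[!is.na(reason), , drop = FALSE],
                         tibble(reason = reason[!is.na(reason)]))
  )
}
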