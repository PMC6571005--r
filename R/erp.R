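#' Default analysis windows
#'
#' One row per (channel, window): the three late intervals of interest —
#' cue-related potential (CUE), the contingent voltage variation between cue
#' and target (CVV), and the target-related potential (TGT) — with boundaries
#' in ms relative to target onset (0 = target onset, negative = pre-target)
#' and the polarity of the wave sought in each. Boundaries are per-channel so
#' a laboratory's own window table can be swapped in; the shipped defaults
#' use the same late-component spans for every channel (CUE -1400..-1100 ms
#' positive, CVV -600..0 ms negative, TGT 200..600 ms positive).
#'
#' @param channels Character vector of channel names (may include `"C3-C4"`).
#' @return Tibble with columns `channel`, `window`, `start`, `end`,
#'   `polarity` (`"positive"`/`"negative"`).
#' @export
default_windows <- function(channels) {
  tidyr::expand_grid(
    channel = channels,
    tibble(window = c("CUE", "CVV", "TGT"),
           start = c(-1400, -600, 200),
           end = c(-1100, 0, 600),
           polarity = c("positive", "negative", "positive"))
  )
}

#' Default window-by-condition measurement schedule
#'
#' The 13 (window, condition) combinations measured on every channel:
#' cue-locked potentials only in conditions where a cue was shown (neutral,
#' spatial, overall), the cue-target interval (CVV) in every cue condition
#' plus overall, and target potentials in every cue and congruency condition
#' plus overall. With three measures each (peak amplitude, peak latency, mean
#' amplitude) this yields 39 ERP variables per channel.
#'
#' @return Tibble with columns `window` and `condition` (13 rows).
#' @export
default_schedule <- function() {
  bind_rows(
    tibble(window = "CUE", condition = c("all", "neutral", "spatial")),
    tibble(window = "CVV", condition = c("all", "no", "neutral", "spatial")),
    tibble(window = "TGT", condition = c("all", "no", "neutral", "spatial",
                                         "congruent", "incongruent"))
  )
}

#' Add a difference channel to an epoch set
#'
#' Appends the sample-wise difference `minuend - subtrahend` as a synthetic
#' channel named `"<minuend>-<subtrahend>"` (e.g. `"C3-C4"`, used when C3+C4
#' is the recording reference). The original channels are retained.
#'
#' @param epochs An `erp_epochs` object.
#' @param minuend,subtrahend Channel names.
#' @return The augmented `erp_epochs`.
#' @export
difference_channel <- function(epochs, minuend = "C3", subtrahend = "C4") {
  stopifnot(inherits(epochs, "erp_epochs"))
  for (ch in c(minuend, subtrahend)) {
    if (!ch %in% epochs$key$channel) {
      abort(paste0("Channel '", ch, "' not present in the epoch set."))
    }
  }
  i_m <- which(epochs$key$channel == minuend)
  i_s <- which(epochs$key$channel == subtrahend)
  km <- epochs$key[i_m, ]
  ks <- epochs$key[i_s, ]
  ord_m <- order(km$subject, km$condition)
  ord_s <- order(ks$subject, ks$condition)
  if (!identical(km$subject[ord_m], ks$subject[ord_s]) ||
      !identical(km$condition[ord_m], ks$condition[ord_s])) {
    abort("Minuend and subtrahend channels do not share subject/condition rows.")
  }
  diff_amp <- epochs$amplitude[i_m[ord_m], , drop = FALSE] -
    epochs$amplitude[i_s[ord_s], , drop = FALSE]
  diff_key <- km[ord_m, ]
  diff_key$channel <- paste0(minuend, "-", subtrahend)
  new_erp_epochs(bind_rows(epochs$key, diff_key),
                 rbind(epochs$amplitude, diff_amp),
                 epochs$time, epochs$sampling_rate)
}

#' Window measures of a single waveform
#'
#' Peak amplitude is the signed value at the extremum matching the window's
#' polarity (maximum for positive windows, minimum for negative) over samples
#' with `start <= t <= end` (closed interval after snapping to the sample
#' grid); peak latency is the time of that extremum in ms relative to target
#' onset (ties, e.g. on a plateau, resolve to the earliest sample); mean
#' amplitude is the arithmetic mean over the same samples.
#'
#' @param wave Numeric amplitude vector (microvolts).
#' @param time Numeric time axis, ms, same length as `wave`.
#' @param start,end Window boundaries, ms.
#' @param polarity `"positive"` or `"negative"`.
#' @return Named numeric vector: `peak_amplitude`, `peak_latency`,
#'   `mean_amplitude`.
#' @export
#' @examples
#' t <- seq(0, 800, by = 4)
#' w <- 10 * exp(-(t - 400)^2 / (2 * 80^2))
#' window_measures(w, t, 300, 500, "positive")
window_measures <- function(wave, time, start, end,
                            polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  idx <- which(time >= start & time <= end)
  if (!length(idx)) {
    abort(sprintf("Window [%g, %g] ms contains no samples.", start, end))
  }
  w <- wave[idx]
  pk <- if (polarity == "positive") which.max(w) else which.min(w)
  c(peak_amplitude = w[pk],
    peak_latency = time[idx][pk],
    mean_amplitude = mean(w))
}

#' Build the variables-of-interest (VOI) table
#'
#' Assembles the subjects x variables table fed to the latent-variable
#' analysis: for every channel (except the raw C3 and C4 leads, which are
#' represented by their difference channel) and every (window, condition)
#' entry in the schedule, the three window measures; plus the behavioral and
#' WISC columns and the reference group label. Column names encode the
#' metadata as `ERP_<channel>_<window>_<condition>_<measure>`.
#'
#' With the default 13-entry schedule, 18 scalp channels plus `C3-C4`, 29
#' behavioral and 4 WISC columns, the table has 774 variables.
#'
#' @param epochs An `erp_epochs` object (run [difference_channel()] first if
#'   a difference lead is wanted).
#' @param windows Window table as from [default_windows()]; must cover every
#'   (channel, window) the schedule requires.
#' @param schedule Measurement schedule as from [default_schedule()].
#' @param behavior Optional tibble from [compute_behavior()] (`subject` +
#'   `BEH_*`).
#' @param wisc Optional tibble of `subject` + `WISC_*` columns.
#' @param labels Optional reference labeling tibble (`subject`, `group`);
#'   defaults to the `group` column of the epoch key.
#' @param exclude_channels Channels dropped as individual leads
#'   (default C3, C4).
#' @return A VOI tibble: `subject`, `group`, then variable columns.
#' @export
build_voi_table <- function(epochs, windows = NULL, schedule = default_schedule(),
                            behavior = NULL, wisc = NULL, labels = NULL,
                            exclude_channels = c("C3", "C4")) {
  stopifnot(inherits(epochs, "erp_epochs"))
  channels <- setdiff(unique(epochs$key$channel), exclude_channels)
  if (is.null(windows)) windows <- default_windows(channels)
  bad_cond <- setdiff(schedule$condition, unique(epochs$key$condition))
  if (length(bad_cond)) {
    abort(paste0("Schedule references unknown condition(s): ",
                 paste(bad_cond, collapse = ", ")))
  }
  span <- range(epochs$time)
  subjects <- unique(epochs$key$subject)
  measures <- c("peak_amplitude", "peak_latency", "mean_amplitude")

  cols <- list()
  for (ch in channels) {
    for (r in seq_len(nrow(schedule))) {
      wname <- schedule$window[r]
      cond <- schedule$condition[r]
      wrow <- windows[windows$channel == ch & windows$window == wname, ]
      if (nrow(wrow) != 1) {
        abort(paste0("No (or ambiguous) window spec for channel '", ch,
                     "', window '", wname, "'."))
      }
      if (wrow$start >= wrow$end) {
        abort(paste0("Window '", wname, "' on ", ch, " has start >= end."))
      }
      if (wrow$start < span[1] || wrow$end > span[2]) {
        abort(paste0("Window '", wname, "' on ", ch, " [", wrow$start, ", ",
                     wrow$end, "] ms lies outside the epoch span [",
                     span[1], ", ", span[2], "] ms."))
      }
      sel <- which(epochs$key$channel == ch & epochs$key$condition == cond)
      sel <- sel[match(subjects, epochs$key$subject[sel])]
      if (anyNA(sel)) {
        abort(paste0("Channel ", ch, ", condition ", cond,
                     ": missing subjects in the epoch set."))
      }
      tidx <- which(epochs$time >= wrow$start & epochs$time <= wrow$end)
      sub <- epochs$amplitude[sel, tidx, drop = FALSE]
      pk_i <- if (wrow$polarity == "positive") {
        max.col(sub, ties.method = "first")
      } else {
        max.col(-sub, ties.method = "first")
      }
      vals <- cbind(sub[cbind(seq_len(nrow(sub)), pk_i)],
                    epochs$time[tidx][pk_i],
                    rowMeans(sub))
      for (m in 1:3) {
        cols[[voi_name_erp(ch, wname, cond, measures[m])]] <- vals[, m]
      }
    }
  }
  out <- bind_cols(tibble(subject = subjects), as_tibble(cols))

  if (is.null(labels)) {
    labels <- distinct(epochs$key[, c("subject", "group")])
  }
  out <- left_join(labels, out, by = "subject")
  if (!is.null(behavior)) out <- left_join(out, behavior, by = "subject")
  if (!is.null(wisc)) out <- left_join(out, wisc, by = "subject")
  # behavioral/WISC blocks go between the ids and the ERP block, mirroring
  # the deposited-spreadsheet layout
  var_names <- setdiff(names(out), id_cols())
  ord <- c(var_names[is_wisc_col(var_names)], var_names[is_beh_col(var_names)],
           var_names[is_erp_col(var_names)])
  if (anyDuplicated(ord)) abort("Duplicated variable names in VOI table.")
  out[, c(id_cols(), ord)]
}

#' Parse VOI metadata from column names
#'
#' @param voi A VOI tibble (or a character vector of its variable names).
#' @return Tibble: `variable`, `source` (ERP/BEH/WISC), `channel`, `window`,
#'   `condition`, `measure` (NA where not applicable).
#' @export
voi_metadata <- function(voi) {
  vars <- if (is.character(voi)) voi else setdiff(names(voi), id_cols())
  parse_one <- function(v) {
    if (is_erp_col(v)) {
      parts <- strsplit(sub("^ERP_", "", v), "_")[[1]]
      if (length(parts) < 4) {
        abort(paste0("Unparseable ERP column name: ", v))
      }
      tibble(variable = v, source = "ERP", channel = parts[1],
             window = parts[2], condition = parts[3],
             measure = paste(parts[-(1:3)], collapse = "_"))
    } else if (is_beh_col(v)) {
      tibble(variable = v, source = "BEH", channel = NA, window = NA,
             condition = NA, measure = sub("^BEH_", "", v))
    } else if (is_wisc_col(v)) {
      tibble(variable = v, source = "WISC", channel = NA, window = NA,
             condition = NA, measure = sub("^WISC_", "", v))
    } else {
      abort(paste0("Column name does not follow the ERP_/BEH_/WISC_ ",
                   "convention: ", v))
    }
  }
  purrr::map_dfr(vars, parse_one)
}

#' Drop redundant mean-amplitude variables
#'
#' Removes every `mean_amplitude` column from the VOI table; the mean
#' amplitude is near-collinear with the peak amplitude inside a fixed window
#' and carries no extra classification information, so each channel
#' contributes 26 variables (peak amplitude + peak latency) afterwards.
#'
#' @param voi A VOI tibble.
#' @return The reduced VOI tibble.
#' @seealso [diagnose_mean_amplitude()] for the correlation diagnostic that
#'   motivates the drop.
#' @export
drop_redundant <- function(voi) {
  keep <- !grepl("_mean_amplitude$", names(voi))
  voi[, keep, drop = FALSE]
}

#' Mean-vs-peak amplitude redundancy diagnostic
#'
#' Pearson correlation, across subjects, between the mean-amplitude and
#' peak-amplitude measure of every (channel, window, condition) cell.
#'
#' @param voi A VOI tibble containing both measures.
#' @return Tibble: `channel`, `window`, `condition`, `r`.
#' @export
diagnose_mean_amplitude <- function(voi) {
  meta <- voi_metadata(voi)
  erp <- meta[meta$source == "ERP" &
                meta$measure %in% c("mean_amplitude", "peak_amplitude"), ]
  if (!any(erp$measure == "mean_amplitude")) {
    abort("VOI table has no mean_amplitude columns.")
  }
  erp |>
    tidyr::pivot_wider(id_cols = c("channel", "window", "condition"),
                       names_from = "measure", values_from = "variable") |>
    mutate(r = purrr::map2_dbl(.data$mean_amplitude, .data$peak_amplitude,
                               function(a, b) cor(voi[[a]], voi[[b]]))) |>
    select("channel", "window", "condition", "r")
}
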