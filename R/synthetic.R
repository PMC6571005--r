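#' Configuration for the synthetic two-group study generator
#'
#' Builds a validated configuration describing a simulated cued-attention
#' (ANT-style) study: two groups of boys, trial-level behavior and
#' epoch-averaged ERP waveforms per subject, channel and condition, with a
#' planted latent factor structure. Variables mapped to a factor are
#' block-correlated through shared per-subject factor scores; the case group's
#' scores are mean-shifted by `effect_sizes` (standardized units), which is how
#' the group difference enters both the ERP window amplitudes and behavior.
#'
#' @param n_control,n_case Number of control / case subjects (defaults 20/19).
#' @param channels Character vector of scalp electrode names (10-20 system).
#' @param conditions Condition labels for the epoch-averaged waveforms. The
#'   default six are the overall average plus the cue (no/neutral/spatial) and
#'   target-congruency (congruent/incongruent) marginals.
#' @param n_blocks,trials_per_block Trial-count layout of the behavioral task.
#' @param n_factors Number of latent factors.
#' @param effect_sizes Numeric vector (length `n_factors`): standardized group
#'   mean shift (Cohen's-d-like) planted on every variable deviate mapped to
#'   that factor (case subjects' bump amplitudes move by
#'   `effect_size * amp_sd`).
#' @param factor_cor Within-factor correlation of mapped variable deviates
#'   beyond the group effect, in `[0, 1]`: a mapped deviate is
#'   `sqrt(factor_cor) * F_ik + sqrt(1 - factor_cor) * u + effect_size * case`,
#'   with `F_ik` the subject's shared factor score and `u` idiosyncratic, so
#'   every mapped deviate has unit within-group SD.
#' @param factor_map Tibble with columns `channel`, `window`, `factor`
#'   assigning ERP (channel, window) amplitudes to factors; unmapped
#'   amplitudes get independent subject noise. `NULL` uses a default map
#'   placing factor 1 on late target/cue windows of midline-frontal,
#'   mid-parietal, right-frontal and left-central sites and factor 2 (if any)
#'   on frontal slow-wave (CVV) amplitudes.
#' @param behavior_factor Factor index driving subject-level reaction-time
#'   shifts (NA for none).
#' @param wisc_factor Factor index driving WISC subtest scores (NA for none).
#' @param noise_sd Waveform measurement noise SD, microvolts per sample.
#' @param wave_params Tibble with one row per window (`window`, `center`,
#'   `width`, `base_amplitude`, `amp_sd`, `polarity`): Gaussian bump center and
#'   width (ms), baseline amplitude and between-subject amplitude SD
#'   (microvolts), and polarity (+1/-1).
#' @param sampling_rate Sampling rate of the epoch average, Hz.
#' @param epoch_span Length-2 numeric, epoch start/end in ms relative to
#'   target onset (0 = target onset; the cue precedes the target by 1650 ms).
#' @param rt_base Population mean reaction time, ms.
#' @param rt_sigma Lognormal shape parameter of trial RTs.
#' @param rt_shift Shift of the shifted-lognormal RT distribution, ms.
#' @param rt_subject_sd Between-subject SD of mean RT, ms.
#' @param rt_factor_load RT shift (ms) per unit of the behavior factor score.
#' @param rt_group_shift Additive case-group RT effect, ms.
#' @param rt_group_sd_mult Multiplier on `rt_sigma` for case subjects.
#' @param cue_offsets,congruency_offsets Named numeric condition offsets (ms)
#'   added to the expected RT; defaults plant an alerting advantage of 25 ms,
#'   an orienting advantage of 25 ms and a conflict cost of 70 ms.
#' @param block_slope Practice effect on expected RT, ms per block.
#' @param hit_rate Named numeric `c(control=, case=)` per-trial probability of
#'   a correct response.
#' @param incongruent_penalty Drop in hit probability on incongruent trials.
#' @param wisc_mean,wisc_sd Scaled-score mean and SD of the four WISC subtests.
#' @param wisc_factor_load Scaled-score shift per unit of the WISC factor.
#' @param seed Master integer seed; expands to per-subject substreams so
#'   adding subjects does not perturb existing ones.
#'
#' @return An object of class `sim_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(n_control = 4, n_case = 4, sampling_rate = 100)
#' cfg$n_factors
sim_config <- function(n_control = 20,
                       n_case = 19,
                       channels = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                                    "T3", "C3", "Cz", "C4", "T4", "T5", "P3",
                                    "Pz", "P4", "T6", "O1", "O2", "Oz"),
                       conditions = c("all", "no", "neutral", "spatial",
                                      "congruent", "incongruent"),
                       n_blocks = 8,
                       trials_per_block = 24,
                       n_factors = 2,
                       effect_sizes = c(1.5, 0),
                       factor_cor = 0.3,
                       factor_map = NULL,
                       behavior_factor = 1L,
                       wisc_factor = 1L,
                       noise_sd = 0.5,
                       wave_params = NULL,
                       sampling_rate = 1000,
                       epoch_span = c(-1600, 800),
                       rt_base = 560,
                       rt_sigma = 0.22,
                       rt_shift = 180,
                       rt_subject_sd = 45,
                       rt_factor_load = 30,
                       rt_group_shift = 20,
                       rt_group_sd_mult = 1.25,
                       cue_offsets = c(no = 25, neutral = 0, spatial = -25),
                       congruency_offsets = c(congruent = -35, incongruent = 35),
                       block_slope = -3,
                       hit_rate = c(control = 0.95, case = 0.90),
                       incongruent_penalty = 0.03,
                       wisc_mean = 10,
                       wisc_sd = 3,
                       wisc_factor_load = -1,
                       seed = 1L) {
  if (n_control < 2 || n_case < 2) {
    abort("Need at least 2 subjects per group.")
  }
  if (n_factors < 1) abort("`n_factors` must be >= 1.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (factor_cor < 0 || factor_cor > 1) {
    abort("`factor_cor` must lie in [0, 1].")
  }
  if (sampling_rate <= 0) abort("`sampling_rate` must be > 0.")
  if (length(epoch_span) != 2 || epoch_span[1] >= epoch_span[2]) {
    abort("`epoch_span` must be c(start, end) with start < end (ms).")
  }
  effect_sizes <- rep_len(effect_sizes, n_factors)
  if (is.null(wave_params)) {
    wave_params <- tibble(
      window = c("CUE", "CVV", "TGT"),
      center = c(-1250, -250, 400),
      width = c(90, 220, 90),
      base_amplitude = c(6, 4, 10),
      amp_sd = c(1.5, 1.5, 2),
      polarity = c(1, -1, 1)
    )
  }
  wave_params <- as_tibble(wave_params)
  needed <- c("window", "center", "width", "base_amplitude", "amp_sd", "polarity")
  if (!all(needed %in% names(wave_params))) {
    abort(paste0("`wave_params` must have columns: ",
                 paste(needed, collapse = ", ")))
  }
  for (w in seq_len(nrow(wave_params))) {
    ctr <- wave_params$center[w]
    if (ctr < epoch_span[1] || ctr > epoch_span[2]) {
      abort(paste0("Window '", wave_params$window[w],
                   "' bump center ", ctr, " ms lies outside epoch_span [",
                   epoch_span[1], ", ", epoch_span[2], "]."))
    }
  }
  if (is.null(factor_map)) {
    factor_map <- default_factor_map(channels, n_factors)
  }
  factor_map <- as_tibble(factor_map)
  if (nrow(factor_map) > 0) {
    bad_ch <- setdiff(factor_map$channel, channels)
    if (length(bad_ch)) {
      abort(paste0("factor_map references unknown channel(s): ",
                   paste(bad_ch, collapse = ", ")))
    }
    bad_w <- setdiff(factor_map$window, wave_params$window)
    if (length(bad_w)) {
      abort(paste0("factor_map references unknown window(s): ",
                   paste(bad_w, collapse = ", ")))
    }
    if (any(factor_map$factor < 1 | factor_map$factor > n_factors)) {
      abort("factor_map factor indices must lie in 1..n_factors.")
    }
  }
  structure(list(
    n_control = as.integer(n_control), n_case = as.integer(n_case),
    channels = channels, conditions = conditions,
    n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    n_factors = as.integer(n_factors), effect_sizes = effect_sizes,
    factor_cor = factor_cor, factor_map = factor_map,
    behavior_factor = behavior_factor, wisc_factor = wisc_factor,
    noise_sd = noise_sd, wave_params = wave_params,
    sampling_rate = sampling_rate, epoch_span = epoch_span,
    rt_base = rt_base, rt_sigma = rt_sigma, rt_shift = rt_shift,
    rt_subject_sd = rt_subject_sd, rt_factor_load = rt_factor_load,
    rt_group_shift = rt_group_shift, rt_group_sd_mult = rt_group_sd_mult,
    cue_offsets = cue_offsets, congruency_offsets = congruency_offsets,
    block_slope = block_slope, hit_rate = hit_rate,
    incongruent_penalty = incongruent_penalty,
    wisc_mean = wisc_mean, wisc_sd = wisc_sd,
    wisc_factor_load = wisc_factor_load,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# factor 1: late target- and cue-locked amplitudes over midline-frontal,
# mid-parietal, right-frontal and left-central sites (the discriminative
# block); factor 2: frontal slow-wave (CVV) amplitudes (a nuisance block).
default_factor_map <- function(channels, n_factors) {
  f1_ch <- intersect(c("Fz", "Pz", "F4", "F8", "C3"), channels)
  map <- tibble(
    channel = rep(f1_ch, each = 2),
    window = rep(c("TGT", "CUE"), length(f1_ch)),
    factor = 1L
  )
  if (n_factors >= 2) {
    f2_ch <- intersect(c("Fp1", "Fp2", "F3", "F7", "T3", "T5"), channels)
    map <- bind_rows(map, tibble(channel = f2_ch, window = "CVV", factor = 2L))
  }
  map
}

#' Subject ids and planted group labels
#'
#' Returns the generating (ground-truth) group of every synthetic subject:
#' control ids are prefixed `C`, case ids `T`. Labels depend only on the group
#' counts, never on the seed, so they can anchor parameter-recovery tests.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `subject` and `group`
#'   (factor: control/case).
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tibble(
    subject = c(sprintf("C%03d", seq_len(config$n_control)),
                sprintf("T%03d", seq_len(config$n_case))),
    group = factor(rep(c("control", "case"),
                       c(config$n_control, config$n_case)),
                   levels = c("control", "case"))
  )
}

# Stable per-subject stream index: controls count from 1, cases from a fixed
# offset, so enlarging one group never perturbs the other group's draws.
subject_stream_index <- function(labs) {
  idx <- integer(nrow(labs))
  is_ctrl <- labs$group == "control"
  idx[is_ctrl] <- seq_len(sum(is_ctrl))
  idx[!is_ctrl] <- 100000L + seq_len(sum(!is_ctrl))
  idx
}

# Per-subject shared factor scores (stream 1 of each subject's substream),
# N(0,1) and group-free: the group effect is added per mapped deviate, see
# factor_deviate().
factor_scores <- function(config) {
  labs <- planted_truth(config)
  n <- nrow(labs)
  f <- matrix(0, n, config$n_factors)
  sidx <- subject_stream_index(labs)
  for (i in seq_len(n)) {
    f[i, ] <- with_seed(substream_seed(config$seed, sidx[i], 1L),
                        rnorm(config$n_factors))
  }
  rownames(f) <- labs$subject
  f
}

# Standardized deviate of one variable mapped to factor k for subject i:
# correlated within the factor block through the shared score, unit
# within-group SD, case mean shifted by the factor's effect size. `u` is the
# variable's idiosyncratic standard-normal draw.
factor_deviate <- function(config, fs, i, k, u, is_case) {
  sqrt(config$factor_cor) * fs[i, k] +
    sqrt(1 - config$factor_cor) * u +
    config$effect_sizes[k] * as.numeric(is_case)
}

#' Generate epoch-averaged ERP waveforms
#'
#' Each subject x channel x condition waveform is a sum of one Gaussian bump
#' per configured window plus white measurement noise. A subject's bump
#' amplitude on a (channel, window) pair is
#' `polarity * (base_amplitude + amp_sd * z)`, where `z` is a unit-SD subject
#' deviate: idiosyncratic standard normal for unmapped pairs, and for pairs
#' mapped to factor k a mix of the subject's shared factor score
#' (weight `sqrt(factor_cor)`) and idiosyncratic noise, plus the factor's
#' group effect — so the mean case-control amplitude shift equals
#' `effect_size * amp_sd` exactly on mapped pairs, and mapped pairs of the
#' same factor are correlated across subjects. The cue-locked (CUE) bump is
#' omitted in the no-cue condition, where no cue was presented.
#'
#' @param config A [sim_config()].
#' @return An `erp_epochs` object: list with `key` (tibble: subject, group,
#'   channel, condition), `amplitude` (matrix, rows matching `key`, columns =
#'   time samples, microvolts), `time` (ms relative to target onset) and
#'   `sampling_rate` (Hz).
#' @export
#' @examples
#' cfg <- sim_config(n_control = 2, n_case = 2, channels = c("Fz", "Pz"),
#'                   sampling_rate = 100, seed = 7)
#' ep <- generate_waveforms(cfg)
#' dim(ep$amplitude)
generate_waveforms <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  labs <- planted_truth(config)
  step <- 1000 / config$sampling_rate
  time <- seq(config$epoch_span[1], config$epoch_span[2], by = step)
  wp <- config$wave_params
  n_w <- nrow(wp)
  # window x time bump shapes
  g <- vapply(seq_len(n_w), function(w) {
    exp(-(time - wp$center[w])^2 / (2 * wp$width[w]^2))
  }, numeric(length(time)))
  g <- t(g)  # n_w x n_t

  n_ch <- length(config$channels)
  n_cond <- length(config$conditions)
  fs <- factor_scores(config)

  key <- tidyr::expand_grid(subject = labs$subject,
                            channel = config$channels,
                            condition = config$conditions) |>
    left_join(labs, by = "subject") |>
    relocate("subject", "group", "channel", "condition")

  map_key <- paste(config$factor_map$channel, config$factor_map$window)
  map_fac <- config$factor_map$factor

  amp <- matrix(0, nrow(key), length(time))
  rows_per_subj <- n_ch * n_cond
  cue_absent <- which(wp$window == "CUE")
  sidx <- subject_stream_index(labs)
  for (i in seq_len(nrow(labs))) {
    seed_i <- substream_seed(config$seed, sidx[i], 2L)
    rows <- ((i - 1) * rows_per_subj + 1):(i * rows_per_subj)
    amp[rows, ] <- with_seed(seed_i, {
      # per-(channel, window) amplitude deviate: factor score if mapped,
      # else an independent subject-specific draw
      z <- matrix(rnorm(n_ch * n_w), n_ch, n_w)
      is_case <- labs$group[i] == "case"
      for (m in seq_along(map_key)) {
        ch_i <- match(config$factor_map$channel[m], config$channels)
        w_i <- match(config$factor_map$window[m], wp$window)
        z[ch_i, w_i] <- factor_deviate(config, fs, i, map_fac[m],
                                       z[ch_i, w_i], is_case)
      }
      a <- sweep(sweep(z, 2, wp$amp_sd, "*"), 2, wp$base_amplitude, "+")
      a <- sweep(a, 2, wp$polarity, "*")  # n_ch x n_w signed amplitudes
      # expand channels over conditions; drop the cue bump where no cue shown
      a_rows <- a[rep(seq_len(n_ch), each = n_cond), , drop = FALSE]
      cond_rep <- rep(config$conditions, n_ch)
      if (length(cue_absent) && "no" %in% config$conditions) {
        a_rows[cond_rep == "no", cue_absent] <- 0
      }
      a_rows %*% g +
        matrix(rnorm(rows_per_subj * length(time), 0, config$noise_sd),
               rows_per_subj)
    })
  }
  # key above expands condition fastest within channel, matching a_rows
  new_erp_epochs(key, amp, time, config$sampling_rate)
}

new_erp_epochs <- function(key, amplitude, time, sampling_rate) {
  stopifnot(nrow(key) == nrow(amplitude), length(time) == ncol(amplitude))
  structure(list(key = key, amplitude = amplitude, time = time,
                 sampling_rate = sampling_rate),
            class = "erp_epochs")
}

#' @export
print.erp_epochs <- function(x, ...) {
  cat("<erp_epochs> ", dplyr::n_distinct(x$key$subject), " subjects x ",
      dplyr::n_distinct(x$key$channel), " channels x ",
      dplyr::n_distinct(x$key$condition), " conditions; ",
      length(x$time), " samples (", x$time[1], "..", x$time[length(x$time)],
      " ms @ ", x$sampling_rate, " Hz)\n", sep = "")
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @method as_tibble erp_epochs
#' @export
as_tibble.erp_epochs <- function(x, ...) {
  nt <- length(x$time)
  out <- x$key[rep(seq_len(nrow(x$key)), each = nt), ]
  out$time_ms <- rep(x$time, nrow(x$key))
  out$amplitude <- as.vector(t(x$amplitude))
  as_tibble(out)
}

#' Generate trial-level ANT behavior
#'
#' Simulates the cued two-choice task: `n_blocks` blocks of
#' `trials_per_block` trials per subject, cue condition equiprobable in
#' {no, neutral, spatial}, target congruency balanced. Reaction times follow a
#' shifted lognormal whose expectation is the subject mean plus cue,
#' congruency and practice (block) offsets; case subjects get an additive
#' group shift, a lognormal-scale inflation, and (through the behavior
#' factor) the planted factor effect. Accuracy is Bernoulli with a per-group
#' hit rate, reduced on incongruent trials.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `subject`, `group`, `block`, `trial`,
#'   `cue` (no/neutral/spatial), `congruency` (congruent/incongruent),
#'   `rt` (ms) and `correct` (logical).
#' @export
#' @examples
#' cfg <- sim_config(n_control = 2, n_case = 2, seed = 3)
#' tr <- generate_trials(cfg)
#' nrow(tr) / 4  # 8 blocks x 24 trials each
generate_trials <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  labs <- planted_truth(config)
  fs <- factor_scores(config)
  n_trials <- config$n_blocks * config$trials_per_block
  cues <- names(config$cue_offsets)
  congs <- names(config$congruency_offsets)

  sidx <- subject_stream_index(labs)
  one_subject <- function(i) {
    subj <- labs$subject[i]
    is_case <- labs$group[i] == "case"
    u3 <- with_seed(substream_seed(config$seed, sidx[i], 3L), rnorm(2))
    mu_i <- config$rt_base +
      config$rt_subject_sd * u3[1] +
      (if (is_case) config$rt_group_shift else 0) +
      (if (!is.na(config$behavior_factor))
        config$rt_factor_load *
          factor_deviate(config, fs, i, config$behavior_factor, u3[2],
                         is_case) else 0)
    sigma_i <- config$rt_sigma * (if (is_case) config$rt_group_sd_mult else 1)
    hit_i <- unname(config$hit_rate[if (is_case) "case" else "control"])
    with_seed(substream_seed(config$seed, sidx[i], 4L), {
      cue <- sample(cues, n_trials, replace = TRUE)
      congruency <- sample(congs, n_trials, replace = TRUE)
      block <- rep(seq_len(config$n_blocks), each = config$trials_per_block)
      m <- mu_i + config$cue_offsets[cue] +
        config$congruency_offsets[congruency] +
        config$block_slope * (block - 1)
      m <- pmax(m, config$rt_shift + 50)
      rt <- config$rt_shift +
        rlnorm(n_trials, log(m - config$rt_shift) - sigma_i^2 / 2, sigma_i)
      p_hit <- pmin(pmax(
        hit_i - config$incongruent_penalty * (congruency == "incongruent"),
        0), 1)
      tibble(subject = subj, group = labs$group[i], block = block,
             trial = seq_len(n_trials), cue = cue, congruency = congruency,
             rt = unname(rt), correct = rbinom(n_trials, 1, p_hit) == 1)
    })
  }
  purrr::map_dfr(seq_len(nrow(labs)), one_subject)
}

#' Generate WISC subtest scaled scores
#'
#' Draws the four subtest scores (Block Design, Vocabulary, Arithmetic,
#' Digit Span) as scaled scores around `wisc_mean`; when `wisc_factor` is set
#' the subject's factor score shifts all four by `wisc_factor_load` scaled
#' points per factor unit (negative by default: cases score lower).
#'
#' @param config A [sim_config()].
#' @return A tibble: `subject` plus four `WISC_*` columns.
#' @export
generate_wisc <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  labs <- planted_truth(config)
  fs <- factor_scores(config)
  subtests <- c("BlockDesign", "Vocabulary", "Arithmetic", "DigitSpan")
  sidx <- subject_stream_index(labs)
  rows <- purrr::map(seq_len(nrow(labs)), function(i) {
    draws <- with_seed(substream_seed(config$seed, sidx[i], 5L), rnorm(5))
    base <- config$wisc_mean +
      (if (!is.na(config$wisc_factor))
        config$wisc_factor_load *
          factor_deviate(config, fs, i, config$wisc_factor, draws[5],
                         labs$group[i] == "case") else 0)
    vals <- base + config$wisc_sd * draws[1:4]
    setNames(as.list(vals), paste0("WISC_", subtests))
  })
  bind_cols(labs["subject"], purrr::map_dfr(rows, as_tibble))
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: trials, epoch-averaged waveforms, WISC scores and the
#' planted labels under one configuration and seed.
#'
#' @param config A [sim_config()].
#' @return A list with elements `trials`, `epochs`, `wisc`, `labels` and
#'   `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  list(trials = generate_trials(config),
       epochs = generate_waveforms(config),
       wisc = generate_wisc(config),
       labels = planted_truth(config),
       config = config)
}
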