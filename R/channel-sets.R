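#' Default channel-set configuration for the model search
#'
#' The 40 candidate EEG channel sets examined in the reclassification search
#' (ids 1-40; set 1 is the full 19-lead montage with the C3-C4 difference
#' channel replacing the raw central leads), plus the two composite rows:
#' behavioral + WISC variables alone, and behavioral + WISC combined with the
#' best frontal/mid-parietal set.
#'
#' @param all_channels Channels meant by "all channels" (default: the 18
#'   scalp leads of the 10-20 montage without C3/C4, plus `C3-C4`).
#' @return Tibble: `id`, `label`, `channels` (list-column),
#'   `include_behavior`, `include_wisc`.
#' @export
channel_sets_default <- function(all_channels = c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "Cz", "T4", "T5",
  "P3", "Pz", "P4", "T6", "O1", "O2", "Oz", "C3-C4")) {
  sets <- list(
    `1` = all_channels,
    `2` = c("Fz", "Cz", "Pz", "Oz"),
    `3` = c("F7", "T3", "T5", "Fp1", "F3", "C3-C4", "P3", "O1", "Fz", "Pz"),
    `4` = c("C3-C4", "F8", "T4", "T6", "Fp2", "F4", "P4", "O2", "Fz", "Pz"),
    `5` = c("F7", "T3", "T5", "F8", "T4", "T6", "Fz", "Cz", "Pz"),
    `6` = c("F7", "T3", "T5", "C3-C4", "F8", "T4", "T6", "Fz", "Cz", "Pz"),
    `7` = c("F7", "T3", "T5", "Fp1", "C3-C4", "F8", "T4", "T6", "Fp2",
            "Fz", "Cz", "Pz"),
    `8` = c("C3-C4", "Fz", "Cz", "Pz"),
    `9` = c("F7", "T3", "T5", "C3-C4", "Fz", "Pz"),
    `10` = c("C3-C4", "F8", "T4", "T6", "Fz", "Pz"),
    `11` = c("F7", "T3", "C3-C4", "Fz", "Pz"),
    `12` = c("C3-C4", "F8", "T4", "Fz", "Pz"),
    `13` = c("C3-C4", "Fz", "Pz"),
    `14` = c("F7", "T3", "T5", "C3-C4", "F8", "T4", "T6", "Fz", "Pz"),
    `15` = c("F7", "C3-C4", "F8", "Fz", "Pz"),
    `16` = c("F7", "F3", "F8", "F4", "Fz", "Pz"),
    `17` = c("F7", "F3", "C3-C4", "F8", "F4", "Fz", "Pz"),
    `18` = c("F7", "F3", "F8", "F4", "Fz"),
    `19` = c("F7", "F3", "F8", "T4", "F4", "Fz", "Pz"),
    `20` = c("F7", "F3", "C3-C4", "F8", "F4", "Fz"),
    `21` = c("F7", "Fp1", "F3", "C3-C4", "F8", "Fp2", "F4", "Fz", "Pz"),
    `22` = c("F7", "Fp1", "F3", "F8", "Fp2", "F4", "Fz", "Pz"),
    `23` = c("F7", "Fp1", "F3", "C3-C4", "F8", "Fp2", "F4", "Fz"),
    `24` = c("F7", "Fp1", "F3", "F8", "Fp2", "F4", "Fz"),
    `25` = c("F7", "F3", "C3-C4", "P3", "F8", "F4", "P4", "Fz", "Pz"),
    `26` = c("F7", "F3", "P3", "F8", "F4", "P4", "Fz", "Pz"),
    `27` = c("F7", "F3", "C3-C4", "P3", "Fz", "Pz"),
    `28` = c("F7", "F3", "P3", "Fz", "Pz"),
    `29` = c("C3-C4", "F8", "F4", "P4", "Fz", "Pz"),
    `30` = c("F8", "F4", "P4", "Fz", "Pz"),
    `31` = c("F7", "F3", "C3-C4", "Fz", "Pz"),
    `32` = c("F7", "F3", "Fz", "Pz"),
    `33` = c("C3-C4", "F8", "F4", "Fz", "Pz"),
    `34` = c("F8", "F4", "Fz", "Pz"),
    `35` = c("C3-C4", "F8", "T4", "F4", "P4", "Fz", "Pz"),
    `36` = c("F7", "T3", "F3", "C3-C4", "P3", "Fz", "Pz"),
    `37` = c("C3-C4", "F8", "T4", "F4", "Fz", "Pz"),
    `38` = c("F7", "T3", "F3", "C3-C4", "Fz", "Pz"),
    `39` = c("Fz", "Pz"),
    `40` = c("Fz", "Cz", "Pz")
  )
  base <- tibble(
    id = as.integer(names(sets)),
    label = purrr::map_chr(sets, paste, collapse = " "),
    channels = unname(sets),
    include_behavior = FALSE,
    include_wisc = FALSE
  )
  base$label[base$id == 1] <- "All channels"
  composites <- tibble(
    id = 41:42,
    label = c("ANT+WISC", "WISC+ANT+[C3-C4 F8 F4 Fz Pz]"),
    channels = list(character(0), sets[["33"]]),
    include_behavior = TRUE,
    include_wisc = TRUE
  )
  bind_rows(base, composites)
}
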