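#' Run code with a private RNG stream
#'
#' Evaluates `expr` after seeding the RNG, then restores the caller's RNG
#' state, so package functions never disturb the user's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a substream seed from a master seed
#'
#' Counter-based scheme: stream `s` for unit `i` under master `seed` maps to a
#' fixed 31-bit integer, so adding units (subjects, repetitions) never perturbs
#' the streams of existing ones.
#'
#' @param seed Master integer seed.
#' @param i Unit index (subject or repetition), >= 1.
#' @param stream Small integer distinguishing draws within a unit.
#' @return An integer seed < 2^31.
#' @noRd
substream_seed <- function(seed, i, stream = 0L) {
  base <- (as.numeric(seed) %% 2147483647) * 48271 + i * 16807 + stream * 2971
  as.integer(base %% 2147483629) + 1L
}

# single source of truth for the variable-name convention:
# ERP_<channel>_<window>_<condition>_<measure>, BEH_<measure>_<condition>, WISC_<subtest>
voi_name_erp <- function(channel, window, condition, measure) {
  paste("ERP", channel, window, condition, measure, sep = "_")
}

is_erp_col <- function(x) startsWith(x, "ERP_")
is_beh_col <- function(x) startsWith(x, "BEH_")
is_wisc_col <- function(x) startsWith(x, "WISC_")

id_cols <- function() c("subject", "group")

#' Split a VOI tibble into ids and numeric variable matrix
#' @noRd
voi_matrix <- function(voi) {
  vars <- setdiff(names(voi), id_cols())
  m <- as.matrix(voi[, vars, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- voi$subject
  m
}
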