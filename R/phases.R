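#' Gait phases, locomotion modes and muscle channels
#'
#' The pipeline works with a fixed vocabulary:
#' * four gait phases per cycle, in order: `DS1` (first double support),
#'   `SS` (single support), `DS2` (second double support), `SW` (swing);
#' * five locomotion modes: `LW` (level walking), `SA`/`SD` (stairs
#'   ascending/descending), `RA`/`RD` (ramp ascending/descending);
#' * twelve sEMG channels: left then right leg, each with RF (rectus
#'   femoris), VM (vastus medialis), ST (semitendinosus), BF (biceps
#'   femoris), TA (tibialis anterior) and MG (medial gastrocnemius).
#'
#' Channel order is fixed: `L_RF, L_VM, L_ST, L_BF, L_TA, L_MG,
#' R_RF, ..., R_MG`. All matrices of sEMG data use this row order.
#'
#' @name gait-vocabulary
#' @examples
#' gait_phases()
#' muscle_channels()
NULL

#' @rdname gait-vocabulary
#' @return `gait_phases()`: character vector of the 4 phase codes in
#'   within-cycle order.
#' @export
gait_phases <- function() c("DS1", "SS", "DS2", "SW")

#' @rdname gait-vocabulary
#' @return `movement_modes()`: character vector of the 5 mode codes.
#' @export
movement_modes <- function() c("LW", "SA", "SD", "RA", "RD")

#' @rdname gait-vocabulary
#' @return `muscles()`: character vector of the 6 muscle codes.
#' @export
muscles <- function() c("RF", "VM", "ST", "BF", "TA", "MG")

#' @rdname gait-vocabulary
#' @return `muscle_channels()`: data frame with columns `channel`
#'   (e.g. `"L_RF"`), `side` and `muscle`, one row per sEMG channel,
#'   in the fixed 12-channel order.
#' @export
muscle_channels <- function() {
  side <- rep(c("left", "right"), each = 6L)
  muscle <- rep(muscles(), times = 2L)
  data.frame(
    channel = paste(ifelse(side == "left", "L", "R"), muscle, sep = "_"),
    side = side,
    muscle = muscle,
    stringsAsFactors = FALSE
  )
}

#' @rdname gait-vocabulary
#' @param x character vector (or factor) of phase codes.
#' @return `phase_factor()`: factor with levels `DS1 < SS < DS2 < SW`.
#' @export
phase_factor <- function(x) {
  f <- factor(as.character(x), levels = gait_phases())
  if (anyNA(f) && !anyNA(x)) {
    bad <- setdiff(unique(as.character(x)), gait_phases())
    stop("unknown gait phase label(s): ", paste(bad, collapse = ", "))
  }
  f
}

assert_mode <- function(mode) {
  if (!is.character(mode) || length(mode) != 1L || !mode %in% movement_modes())
    stop("mode must be one of: ", paste(movement_modes(), collapse = ", "))
  mode
}
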