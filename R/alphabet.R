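#' Posture code alphabet and posture groups
#'
#' The monitor emits one posture recording every 15 seconds. A recording is a
#' single code (e.g. \code{"WLK"}) or a space-separated permutation of codes
#' (e.g. \code{"U45 U90"}) when the posture changed within the 15-second slot.
#' Self-reported postures carry an \code{"S-"} prefix (e.g. \code{"S-U90"}).
#'
#' The base alphabet used throughout the package is the set of codes the
#' pipeline distinguishes: four lying codes (supine \code{LSP}, prone
#' \code{LPR}, right side \code{LRS}, left side \code{LLS}), reclined
#' \code{U45}, upright \code{U90}, walking \code{WLK}, \code{UNK} for
#' undetermined posture and \code{FALL} for a suspected fall, plus the
#' \code{"S-"} variants of the seven physical codes. The full proprietary
#' code list is longer; any token outside this alphabet is still accepted by
#' the tokenizer and falls through to the Unknown group during consolidation,
#' so the alphabet here is a convenience, not a gate.
#'
#' @format \code{posture_codes} is a named list with elements \code{lying},
#'   \code{reclined}, \code{upright}, \code{unknown}, \code{fall} and
#'   \code{self_reported}. \code{posture_group_levels} is the character
#'   vector of the five consolidated posture groups, in the package's
#'   canonical order.
#' @name posture_codes
NULL

#' @rdname posture_codes
#' @export
posture_codes <- list(
  lying         = c("LSP", "LPR", "LRS", "LLS"),
  reclined      = "U45",
  upright       = c("U90", "WLK"),
  unknown       = "UNK",
  fall          = "FALL",
  self_reported = paste0("S-", c("LSP", "LPR", "LRS", "LLS", "U45", "U90", "WLK"))
)

#' @rdname posture_codes
#' @export
posture_group_levels <- c("Lying", "Reclined", "Upright", "Unknown", "UserDefined")

# 15-second recording grid
GRID_SECONDS <- 15L
RECORDINGS_PER_DAY <- 24L * 3600L / 15L      # 5760
ANALYSIS_DAY_MIN_RECORDINGS <- 22L * 3600L / 15L  # 5280

# Daytime window [07:00:00, 19:00:00) in seconds since local midnight;
# nighttime is the complement.
DT_START_SEC <- 7L * 3600L
DT_END_SEC <- 19L * 3600L
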