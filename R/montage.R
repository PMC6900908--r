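#' The 19-channel 10-10 montage and its seven-region grouping
#'
#' Returns the channel set and region map used throughout the analysis:
#' prefrontal (Fp1, Fp2, F7, F8), frontal (F3, Fz, F4), central (C3, Cz, C4),
#' temporal (T7, T8, P7, P8), parietal (P3, Pz, P4), occipital (O1, O2) and
#' midline (Fz, Cz, Pz). The midline channels belong both to their lobe region
#' and to the midline set; midline theta is the sleep-transition marker the
#' pipeline keys on.
#'
#' @return A `montage` object: list with `channels` (character, length 19) and
#'   `regions` (named list of channel vectors).
#' @export
default_montage <- function() {
  regions <- list(
    prefrontal = c("Fp1", "Fp2", "F7", "F8"),
    frontal    = c("F3", "Fz", "F4"),
    central    = c("C3", "Cz", "C4"),
    temporal   = c("T7", "T8", "P7", "P8"),
    parietal   = c("P3", "Pz", "P4"),
    occipital  = c("O1", "O2"),
    midline    = c("Fz", "Cz", "Pz")
  )
  structure(list(channels = unique(unlist(regions, use.names = FALSE)),
                 regions = regions),
            class = "montage")
}

#' Restrict a montage to a subset of regions
#'
#' Useful for simulation studies where only some regions enter the statistic
#' (e.g. midline-only power calibration), which cuts synthesis cost.
#'
#' @param montage A `montage` object.
#' @param regions Character vector of region names to keep.
#' @return A reduced `montage`.
#' @export
montage_subset <- function(montage, regions) {
  stopifnot(inherits(montage, "montage"), all(regions %in% names(montage$regions)))
  r <- montage$regions[regions]
  structure(list(channels = unique(unlist(r, use.names = FALSE)), regions = r),
            class = "montage")
}

validate_montage <- function(montage) {
  stopifnot(inherits(montage, "montage"))
  if (!all(unlist(montage$regions) %in% montage$channels))
    stop("montage regions reference unknown channels")
  invisible(montage)
}

#' Hemisphere channel sets for the alpha laterality index
#'
#' The laterality index is computed over the lateralized members of the
#' prefrontal and frontal regions; midline channels are excluded.
#'
#' @return List with `left` = Fp1, F7, F3 and `right` = Fp2, F8, F4.
#' @export
laterality_channels <- function() {
  list(left = c("Fp1", "F7", "F3"), right = c("Fp2", "F8", "F4"))
}
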