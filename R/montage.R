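.montage64 <- c(
  "Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8",
  "FC5", "FC1", "FC2", "FC6", "M1", "T7", "C3", "Cz",
  "C4", "T8", "M2", "CP5", "CP1", "CP2", "CP6", "P7",
  "P3", "Pz", "P4", "P8", "POz", "O1", "Oz", "O2",
  "AF7", "AF3", "AF4", "AF8", "F5", "F1", "F2", "F6",
  "FT7", "FC3", "FCz", "FC4", "FT8", "C5", "C1", "C2",
  "C6", "TP7", "CP3", "CPz", "CP4", "TP8", "P5", "P1",
  "P2", "P6", "PO7", "PO5", "PO3", "PO4", "PO6", "PO8")

#' The 63-channel 10-10 montage
#'
#' Channel labels of the 64-electrode international 10-10 cap with the
#' midline CPz position removed: CPz is wired as the electrooculography
#' (EOG) channel in this recording setup, leaving 63 functional EEG
#' channels.
#'
#' @param excludeCPz drop CPz (default); with \code{FALSE} the full
#'   64-channel montage is returned.
#' @return Character vector of channel labels (length 63, or 64).
#' @export
#' @examples
#' length(montage1010())
montage1010 <- function(excludeCPz = TRUE) {
  if (excludeCPz) setdiff(.montage64, "CPz") else .montage64
}
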