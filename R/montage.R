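#' Standard 63-channel 10-10 montage
#'
#' Channel labels for a 64-electrode cap referenced at FCz (the reference
#' itself is not recorded, leaving 63 scalp channels).  Labels follow the
#' international 10-10 nomenclature used by actiCAP-style systems.
#'
#' @return Character vector of 63 unique channel labels.
#' @export
montage_1010 <- function() {
  c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT9", "FT7", "FC5", "FC3", "FC1", "FC2", "FC4", "FC6", "FT8", "FT10",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "TP10",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2")[-2]
}

#' Motor and sensorimotor channels excluded from workload features
#'
#' The 14 central-strip electrodes (Cz, C1-C6, CPz, CP1-CP6) are dropped for
#' workload decoding so that motor-response differences between easy and
#' difficult arithmetic cannot drive the classifier.
#'
#' @return Character vector of 14 channel labels.
#' @export
motor_channels <- function() {
  c("Cz", "C1", "C2", "C3", "C4", "C5", "C6",
    "CPz", "CP1", "CP2", "CP3", "CP4", "CP5", "CP6")
}

#' Posterior channels used for individual alpha frequency estimation
#'
#' @return Character vector of occipital/parieto-occipital labels.
#' @export
posterior_channels <- function() {
  c("O1", "Oz", "O2", "PO3", "POz", "PO4", "PO7", "PO8")
}

# Coarse scalp regions by label prefix; used by the synthetic signal model
# to place condition effects (e.g. frontal theta) topographically.
channel_region <- function(labels) {
  region <- rep("central", length(labels))
  region[grepl("^(Fp|AF|F)", labels)] <- "frontal"
  region[grepl("^(FT|T|TP)", labels)] <- "temporal"
  region[grepl("^(P|PO)", labels)] <- "parietal"
  region[grepl("^(O)", labels)] <- "occipital"
  region[labels %in% posterior_channels()] <- "occipital"
  region
}
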