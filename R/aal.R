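#' AAL-90 region labels
#'
#' Abbreviated names of the 90 cortical and subcortical regions (45 per
#' hemisphere) of the Automated Anatomical Labeling atlas, in standard atlas
#' order with left/right interleaved. Used as default node labels for
#' 90-region tables; arbitrary label sets are accepted for other
#' parcellations.
#'
#' @return Character vector of length 90.
#' @export
aal90_labels <- function() {
  base <- c(
    "PreCG", "SFGdor", "ORBsup", "MFG", "ORBmid", "IFGoperc", "IFGtriang",
    "ORBinf", "ROL", "SMA", "OLF", "SFGmed", "ORBsupmed", "REC", "INS",
    "ACG", "DCG", "PCG", "HIP", "PHG", "AMYG", "CAL", "CUN", "LING",
    "SOG", "MOG", "IOG", "FFG", "PoCG", "SPG", "IPL", "SMG", "ANG",
    "PCUN", "PCL", "CAU", "PUT", "PAL", "THA", "HES", "STG", "TPOsup",
    "MTG", "TPOmid", "ITG"
  )
  paste0(rep(base, each = 2), c(".L", ".R"))
}
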