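#' Weed-seed attribute codes
#'
#' The six functional attribute combinations used to characterise weed seeds
#' with respect to crop processing: Big vs Small (relative to the fine-sieve
#' mesh), Headed vs Free (tendency to remain in seed heads after threshing),
#' and Heavy vs Light (aerodynamic behaviour during winnowing). Only six of
#' the eight combinations occur in practice; big seeds are never light.
#'
#' @format A character vector of length six, in the fixed column order used
#'   throughout the package: `BHH`, `BFH`, `SHH`, `SHL`, `SFH`, `SFL`.
#' @export
ATTRIBUTE_CODES <- c("BHH", "BFH", "SHH", "SHL", "SFH", "SFL")

#' Sentinel code for weed taxa that could not be classified
#'
#' Weed taxa whose attribute combination is unknown (blank or unparseable in
#' the input) carry this sentinel. They never contribute to attribute scores
#' and are removed by [drop_unclassified()] before analysis.
#'
#' @format A character scalar, `"UNCLASSIFIED"`.
#' @export
UNCLASSIFIED <- "UNCLASSIFIED"

#' Crop-processing group labels
#'
#' The four ethnographic crop-processing (by-)products, numbered 1-4, plus
#' the fifth "archaeological" group used by the five-group classification
#' method.
#'
#' @format A named character vector mapping group numbers to labels.
#' @export
GROUP_LABELS <- c(
  "1" = "winnowing by-product",
  "2" = "coarse sieve by-product",
  "3" = "fine sieve by-product",
  "4" = "fine sieve product",
  "5" = "archaeological"
)

# normalise a raw code string: trimmed, upper-cased; anything not one of the
# six valid codes becomes UNCLASSIFIED
normalise_code <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[is.na(x) | !(x %in% ATTRIBUTE_CODES)] <- UNCLASSIFIED
  x
}
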