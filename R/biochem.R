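# Sedimentary organic matter: carbon equivalents and biopolymeric carbon.
#
# Protein, carbohydrate and lipid concentrations are converted to carbon
# equivalents with 0.49, 0.40 and 0.75 mgC per mg respectively; their sum is
# the biopolymeric carbon (BPC), a standard proxy of the trophic resources
# available to benthic communities.  Total phytopigments (PIG) are the sum
# of chlorophyll-a and phaeopigments.

#' Carbon-equivalent conversion factors (mgC per mg)
#' @format named numeric vector with elements \code{PRT}, \code{CHO},
#'   \code{LIP}.
#' @export
bpc_conversion_factors <- c(PRT = 0.49, CHO = 0.40, LIP = 0.75)

#' Total phytopigment concentration
#'
#' @param chla chlorophyll-a concentration (ug/g), non-negative.
#' @param pheo phaeopigment concentration (ug/g), non-negative.
#' @return chla + pheo (ug/g).
#' @export
total_phytopigments <- function(chla, pheo) {
  assert_that(all(chla >= 0) && all(pheo >= 0),
              "pigment concentrations must be non-negative")
  chla + pheo
}

#' Biopolymeric carbon
#'
#' @param prt protein concentration (mg/g), non-negative.
#' @param cho carbohydrate concentration (mg/g), non-negative.
#' @param lip lipid concentration (mg/g), non-negative.
#' @return biopolymeric carbon (mgC/g), \code{0.49 prt + 0.40 cho + 0.75 lip}.
#' @export
biopolymeric_carbon <- function(prt, cho, lip) {
  assert_that(all(prt >= 0) && all(cho >= 0) && all(lip >= 0),
              "component concentrations must be non-negative")
  f <- bpc_conversion_factors
  f[["PRT"]] * prt + f[["CHO"]] * cho + f[["LIP"]] * lip
}

#' Add derived PIG and BPC columns to a biochemistry table
#'
#' @param b data.frame with columns PRT, CHO, LIP (mg/g) and CHLA, PHEO
#'   (ug/g).
#' @return the same data.frame with PIG (ug/g) and BPC (mg/g) recomputed.
#' @export
augment_biochem <- function(b) {
  for (col in c("PRT", "CHO", "LIP", "CHLA", "PHEO"))
    assert_that(all(b[[col]] >= 0), "negative ", col, " concentration")
  b$PIG <- total_phytopigments(b$CHLA, b$PHEO)
  b$BPC <- biopolymeric_carbon(b$PRT, b$CHO, b$LIP)
  b
}
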