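#' Biolog Eco-plate carbon sources
#'
#' The 31 sole carbon sources of a Biolog Eco plate (each present in
#' triplicate on a physical plate, alongside a water blank). `substrate` is
#' the stable identifier used throughout the package; `scored` marks the 22
#' substrates that enter the default attribute set of the synthetic study
#' (amines and most polymers are excluded: rhizobia typically cannot
#' metabolize them, so they carry no discriminating information).
#'
#' @return A tibble with columns `substrate` (`S01`..`S31`), `number`,
#'   `name`, `scored`.
#' @export
eco_substrates <- function() {
  names31 <- c(
    "alpha-D-lactose", "beta-methyl-D-glucoside", "D-cellobiose",
    "D-galactonic acid gamma-lactone", "D,L-alpha-glycerol phosphate",
    "i-erythritol", "glucose-1-phosphate", "D-mannitol",
    "N-acetyl-D-glucosamine", "D-xylose", "2-hydroxybenzoic acid",
    "4-hydroxybenzoic acid", "alpha-ketobutyric acid",
    "D-galacturonic acid", "D-glucosaminic acid", "D-malic acid",
    "gamma-hydroxybutyric acid", "pyruvic acid methyl ester", "Tween 40",
    "alpha-cyclodextrin", "glycogen", "itaconic acid", "L-phenylalanine",
    "phenylethylamine", "Tween 80", "glycyl-L-glutamic acid", "L-arginine",
    "L-asparagine", "putrescine", "L-serine", "L-threonine"
  )
  scored_numbers <- c(1:4, 6:10, 12:18, 25:28, 30, 31)
  tibble(
    substrate = sprintf("S%02d", 1:31),
    number = 1:31,
    name = names31,
    scored = 1:31 %in% scored_numbers
  )
}

# Default substrate-usability pattern of the calibrated synthetic study:
# which of the 31 carbon sources each synthetic strain can metabolize
# (17 for the L3-like strain, 15 for B02-like, 13 for Sp20-like; 13
# substrates unusable by all three).
default_usable_pattern <- function(strains = c("B02", "L3", "Sp20")) {
  core13 <- c(2, 3, 4, 7, 8, 9, 10, 12, 14, 15, 16, 18, 28)
  sets <- list(
    B02 = c(core13, 27, 31),
    L3 = c(core13, 1, 26, 30, 31),
    Sp20 = core13
  )
  ids <- sprintf("S%02d", 1:31)
  out <- matrix(FALSE, nrow = length(strains), ncol = 31,
                dimnames = list(strains, ids))
  for (i in seq_along(strains)) {
    template <- sets[[((i - 1) %% 3) + 1]]
    out[i, template] <- TRUE
  }
  out
}
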