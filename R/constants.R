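#' Physico-chemical constants used by the buffer module
#'
#' Dissociation constants are standard 25 degree C reference values
#' (concentration scale, zero ionic strength); molar masses are for the
#' anhydrous disodium salt and the monohydrate acid actually weighed out
#' when the stocks are prepared.
#'
#' @format A named list:
#' \describe{
#'   \item{pka_citric}{citric acid pKa1-pKa3: 3.13, 4.76, 6.40}
#'   \item{pka_phosphoric}{phosphoric acid pKa1-pKa3: 2.15, 7.20, 12.35}
#'   \item{kw}{ion product of water at 25 degrees C, 1e-14}
#'   \item{davies_A}{Debye-Huckel A coefficient at 25 degrees C}
#'   \item{mm_na2hpo4}{molar mass of anhydrous disodium hydrogen phosphate, g/mol}
#'   \item{mm_citric_monohydrate}{molar mass of citric acid monohydrate, g/mol}
#' }
#' @export
buffer_constants <- list(
  pka_citric            = c(3.13, 4.76, 6.40),
  pka_phosphoric        = c(2.15, 7.20, 12.35),
  kw                    = 1e-14,
  davies_A              = 0.5085,
  mm_na2hpo4            = 141.96,
  mm_citric_monohydrate = 210.14
)

#' Fluorophore dissociation constants of the extended-range pH nanosensor
#'
#' The dual-fluorophore sensor combines 5(6)-carboxyfluorescein (FAM,
#' pKa 6.5, optimally responsive near neutral) and Oregon Green (pKa 4.8,
#' optimally responsive in the acidic range) with a pH-insensitive TAMRA
#' reference, giving a working range of roughly pH 3.5-7.5.
#'
#' @format Named numeric vector with elements `fam` and `oregon_green`.
#' @export
fluorophore_pka <- c(fam = 6.5, oregon_green = 4.8)

#' Citrate-phosphate universal buffer series recipes
#'
#' Bench volumes of the two stocks (0.2 M disodium hydrogen phosphate and
#' 0.1 M citric acid monohydrate, 20 ml total) used to prepare the twelve
#' calibration buffers spanning pH 2.5-8.0. These are the classic
#' McIlvaine-style mixing volumes used for the sensor calibration series.
#'
#' @format A data.frame with columns `ph`, `phosphate_ml`, `citrate_ml`.
#' @export
buffer_series_recipes <- data.frame(
  ph           = c(2.5, 3.0, 3.5, 4.0, 4.5, 5.0, 5.5, 6.0, 6.5, 7.0, 7.5, 8.0),
  phosphate_ml = c(2.16, 4.08, 6.04, 7.72, 9.00, 10.28, 11.36, 12.84,
                   14.20, 17.44, 17.98, 19.53),
  citrate_ml   = c(17.84, 15.92, 13.96, 12.28, 11.00, 9.72, 8.64, 7.16,
                   5.80, 2.56, 2.02, 0.47)
)
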