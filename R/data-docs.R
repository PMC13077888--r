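#' Packaged OGRI fixture: Rhizobiaceae type-strain pairs with ANI >= 95%
#'
#' A curated table of overall genome relatedness indices for the ten
#' Rhizobiaceae type-strain pairs whose whole-genome ANI reaches the 95%
#' screening threshold: FastANI values and digital DNA-DNA hybridization
#' values (GGDC formula 2) with their model confidence intervals. Running
#' [synonymyReport()] on this table reproduces the published synonymy
#' screen: ten screened pairs, eight distinct species pairs (ANI between
#' 95 and 96.02%, all dDDH below 70%), and two heterotypic-synonym calls
#' (ANI 98.43 / dDDH 86.6 and ANI 96.55 / dDDH 72).
#'
#' @format TSV with columns strain_a, strain_b, ani, dddh, dddh_ci_lo,
#'   dddh_ci_hi; load with [readOgriTable()].
#' @name rhizobiaceae_type_strain_ogri
#' @examples
#' tab <- readOgriTable(system.file("extdata",
#'   "rhizobiaceae_type_strain_ogri.tsv", package = "cpaaiDelimit"))
#' synonymyReport(tab)$counts
NULL
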