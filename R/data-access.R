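#' Published subfamily mean trait values for eight conifer subfamilies
#'
#' Species-mean trait values aggregated to subfamily for eight conifer
#' clades (Piceoideae, Pinoideae, Laricoideae, Abietoideae, Cupressoideae,
#' Taxodioideae, Sequoioideae, Taxaceae), transcribed from a published
#' 28-species comparative study: pit dimensions (DPM, DT, DPA, um), the
#' derived sealing ratios (TO, MF, VE), tracheid traits (Dh, TD, Tw, TSR),
#' wood density, pit aperture resistance, |P50| and Ks. These anchor the
#' worked-example checks that pin the trait formulas to their published
#' values, and the default ranges of the synthetic generator.
#'
#' @return data.frame, one row per subfamily.
#' @export
subfamily_means <- function() {
  utils::read.csv(system.file("extdata", "conifer_subfamily_means.csv",
                              package = "xylemcomp"),
                  stringsAsFactors = FALSE)
}
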