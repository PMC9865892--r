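#' Published reference tables for UL/ML DPPS (+5\% DPPG) systems
#'
#' Small bundled tables of published per-system hydrogen-bond totals (with
#' molecule counts for the normalised classes) and water / lipid diffusion
#' coefficients, used as arithmetic inputs for normalisation and
#' ratio-reporting checks. These are literature values, not outputs of
#' this package's generators.
#'
#' @return a data.frame
#' @export
reference_hbond_table <- function() {
  path <- system.file("extdata", "reference_hbonds.csv",
                      package = "lamellipid", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE)
}

#' @rdname reference_hbond_table
#' @export
reference_diffusion_table <- function() {
  path <- system.file("extdata", "reference_diffusion.csv",
                      package = "lamellipid", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE)
}
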