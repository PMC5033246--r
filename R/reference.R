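#' Published group-mean volume summary for the Tc1 study
#'
#' Group-level summary statistics (mean and standard deviation of
#' probabilistic tissue volumes, in mm^3) for wild-type (n = 26) and Tc1
#' (n = 29) cohorts from a 55-brain ex vivo micro-MRI phenotyping study of
#' the Tc1 mouse model of Down syndrome. Used for arithmetic-consistency
#' checks: BV = GM + WM and TIV = BV + vCSF + eCSF.
#'
#' @return tibble with columns `genotype`, `n`, `measure`, `mean_mm3`,
#'   `sd_mm3`.
#' @export
reference_volume_summary <- function() {
  path <- system.file("extdata", "reference_group_volumes.csv",
                      package = "multimorph", mustWork = TRUE)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Arithmetic-consistency quantities from a group volume summary
#'
#' From per-tissue group means, recomputes the derived quantities: brain
#' volume as GM + WM, total intracranial volume as BV + vCSF + eCSF, and
#' the BV/TIV percentage.
#'
#' @param summary tibble as returned by [reference_volume_summary()].
#' @param genotype group to summarise.
#' @return one-row tibble: genotype, bv_mm3, tiv_mm3, bv_tiv_pct.
#' @export
derive_volume_arithmetic <- function(summary = reference_volume_summary(),
                                     genotype = "WT") {
  s <- summary[summary$genotype == genotype, ]
  get <- function(m) s$mean_mm3[s$measure == m]
  bv <- get("GM") + get("WM")
  tiv <- get("BV") + get("vCSF") + get("eCSF")
  tibble::tibble(genotype = genotype, bv_mm3 = bv, tiv_mm3 = tiv,
                 bv_tiv_pct = 100 * get("BV") / get("TIV"))
}
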