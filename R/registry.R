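#' The eleven KEGG metabolic pathway classes
#'
#' The fixed registry of the eleven top-level KEGG metabolism categories used
#' as the multi-label prediction target.  Class codes are the integers 1 to
#' 11; every label vector, score vector and ranking in the package is indexed
#' in this order.
#'
#' @return A data frame with columns `code` (integer, 1--11) and `name`
#'   (character), one row per pathway class.
#' @examples
#' pathway_classes()
#' @export
pathway_classes <- function() {
  data.frame(
    code = 1:11,
    name = c(
      "Carbohydrate Metabolism",
      "Energy Metabolism",
      "Lipid Metabolism",
      "Nucleotide Metabolism",
      "Amino Acid Metabolism",
      "Metabolism of Other Amino Acids",
      "Glycan Biosynthesis and Metabolism",
      "Metabolism of Cofactors and Vitamins",
      "Metabolism of Terpenoids and Polyketides",
      "Biosynthesis of Other Secondary Metabolites",
      "Xenobiotics Biodegradation and Metabolism"
    ),
    stringsAsFactors = FALSE
  )
}

# Number of pathway classes; fixed by the registry.
.N_CLASSES <- 11L
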