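#' Published real-data reference estimates
#'
#' The admixture estimates for the real bovid genome panel that this
#' package's methods were built around. They were obtained from hundreds of
#' modern and ancient genomes available only through external accessions, so
#' they are shipped as documentation-grade reference values: nothing in this
#' package recomputes them, and the test suite treats them as context, not
#' as targets. The synthetic and coalescent benchmarks in
#' \code{\link{fpfnExperiment}}, \code{\link{ghostProportion}} and the
#' vignette mirror the logic of these analyses at desk scale.
#'
#' @return data.frame with columns quantity, value (character, as printed),
#'   and method.
#' @export
referenceEstimates <- function() {
  out <- data.frame(
    quantity = c(
      "deep-taurine ancestry in Muturu (graph fit)",
      "Moroccan-aurochs contribution to Muturu",
      "qpAdm fit P for the 2-way Muturu model",
      "ghost deep-taurine proportion, outgroup proxies",
      "ghost deep-taurine proportion, indicine proxies",
      "Moroccan-aurochs edge into Muturu (TreeMix)",
      "empirical P, gene-flow graphs vs none",
      "Model I adequate fits (Muturu + North-Indian indicine)",
      "Model II adequate fits (Muturu + Southeast-Asian indicine)",
      "Model III adequate fits (Model I refs + Southeast-Asian indicine)"),
    value = c("~13%", "38.2 +/- 2.5%", "0.076", "18-19%", "24-27%",
              "40%", "0.001", "24/27", "7/27", "6/27"),
    method = c("admixture-graph GLS", "qpAdm", "qpAdm", "restricted-reference qpAdm",
               "restricted-reference qpAdm", "TreeMix", "block bootstrap",
               "qpAdm battery", "qpAdm battery", "qpAdm battery"))
  attr(out, "provenance") <- "published real-data analysis; requires accession genotypes"
  out
}
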