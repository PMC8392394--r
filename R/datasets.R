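#' Reference dataset composition of the miRBase 22.1 training compilation
#'
#' The per-species positive-training counts (nine major plant species),
#' the positive testing count, and the CDS-derived pseudo-hairpin
#' negative train/test split used by published plant pre-miRNA
#' classifiers trained on miRBase release 22.1. Shipped as plain TSV in
#' `inst/extdata`; useful for sanity-checking dataset bookkeeping (the
#' nine training counts sum to the positive-training total of 3223 and
#' the negative split sums to 8652).
#'
#' @return data.frame with columns `set`, `species`, `count`.
#' @examples
#' d <- referenceDatasetCounts()
#' sum(d$count[d$set == "training"])
#' @export
referenceDatasetCounts <- function() {
  utils::read.table(
    system.file("extdata", "mirbase22_dataset_counts.tsv",
                package = "hairpinSVM"),
    sep = "\t", header = TRUE, check.names = FALSE)
}
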