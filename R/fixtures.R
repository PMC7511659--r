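#' Packaged ddPCR / RNA-seq benchmark table
#'
#' Eight validated *Arabidopsis thaliana* circRNAs quantified in seedlings,
#' roots, leaves and flowers by droplet digital PCR (mean and sample sd over
#' three biological replicates, copies per microgram of total RNA) alongside
#' the matching RNA-seq back-spliced read abundances under each of the six
#' normalization methods (mean over four biological replicates). This small
#' benchmark is the anchor used to rank normalization methods by their
#' concordance with an absolute quantification method.
#'
#' @return A 32-row tibble with columns `name`, `circ_id`, `organ`,
#'   `ddpcr_cp_ug`, `ddpcr_sd`, and one column per normalization method
#'   (`library_size`, `backspliced_sum`, `size_factor`, `library_size_excl`,
#'   `backspliced_sum_excl`, `marker_gene`).
#' @examples
#' benchmark_table()
#' @export
benchmark_table <- function() {
  path <- system.file("extdata", "ddpcr_rnaseq_benchmark.tsv",
                      package = "circquant",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
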