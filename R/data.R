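#' Demo delta-CT dataset: six MSP markers on a 3 tumor + 3 control design
#'
#' Measured MSP delta-CT values (cycles, target minus ACTB reference) for
#' six candidate hypermethylation markers (FLI1, LHX8, USP44, KCNB1,
#' ZNF529, URAD) assayed on three HNSCC and three control tissue samples -
#' the canonical small worked example for the validation statistics. Lower
#' values indicate more methylated template.
#'
#' @return `data.frame` with columns `sample_id`, `group`, `marker`,
#'   `delta_ct`.
#' @export
#' @examples
#' summarize_markers(example_delta_ct())
example_delta_ct <- function() {
  path <- system.file("extdata", "hnscc_six_marker_delta_ct.tsv",
                      package = "nanomsp", mustWork = TRUE)
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
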