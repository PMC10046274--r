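#' Published NCI-60 clustering benchmark reference values
#'
#' Summary values reported for the clustering comparison of the NCI-60
#' screening panel (50,555 unique molecules as 1024-bit Morgan fingerprints):
#' molecule counts before and after nearest-neighbour outlier filtering at
#' cutoff 0.5, headline cluster counts and largest-cluster sizes per method,
#' and the Ward cutoff-scan quality table (silhouette, Calinski-Harabasz and
#' Davies-Bouldin per linkage cutoff, for both scenarios). Shipped as
#' plain-text tables under `inst/extdata`; useful for arithmetic consistency
#' checks and for comparing a re-run of the protocol against the published
#' benchmark.
#'
#' @return A list with two tibbles: `counts` (columns `quantity`, `value`)
#'   and `ward_quality` (columns `scenario`, `ward_cutoff`, `n_clusters`,
#'   `silhouette`, `calinski_harabasz`, `davies_bouldin`).
#' @examples
#' ref <- nci60_reference()
#' subset(ref$ward_quality, ward_cutoff == 3.0)
#' @export
nci60_reference <- function() {
  dir <- system.file("extdata", package = "molclust")
  list(
    counts = readr::read_tsv(file.path(dir, "nci60_reported_counts.tsv"),
                             col_types = "cd", progress = FALSE),
    ward_quality = readr::read_tsv(file.path(dir, "nci60_ward_quality.tsv"),
                                   col_types = "cdiddd", progress = FALSE)
  )
}
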