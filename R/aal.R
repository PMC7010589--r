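# AAL-116 parcellation metadata shipped with the package: ROI labels plus
# an anatomical assignment of the 26 cerebellar ROIs to the three
# cerebellar lobes used as seeds (anterior = lobules I-V, posterior =
# lobules VI-IX incl. Crus I/II, flocculonodular = lobule X). The table is
# an editable best-effort mapping; users with a different convention can
# pass their own seed indices.

#' AAL-116 ROI labels and cerebellar lobe assignment
#'
#' @return A data.frame with columns `index` (1-116), `label` (standard AAL
#'   region name) and `lobe` (`anterior`, `posterior`, `flocculonodular`
#'   for cerebellar ROIs, `NA` for cerebral ones).
#' @export
aal_labels <- function() {
  path <- system.file("extdata", "aal116_labels.tsv", package = "riemfc",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$lobe[df$lobe == ""] <- NA_character_
  df
}

#' Cerebellar seed ROI indices by lobe
#'
#' Index sets into the AAL-116 ordering for the three cerebellar
#' subdivisions used in seed-based analysis.
#'
#' @return Named list of integer vectors: `flocculonodular`, `anterior`,
#'   `posterior`.
#' @export
cerebellar_seeds <- function() {
  df <- aal_labels()
  lapply(stats::setNames(nm = c("flocculonodular", "anterior", "posterior")),
         function(l) df$index[!is.na(df$lobe) & df$lobe == l])
}
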