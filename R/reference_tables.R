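#' Reference per-class FAD scores from the full ICBHI study
#'
#' Per-class Frechet audio distances reported for the three VAE variants
#' trained on the full ICBHI respiratory-sound corpus (which this package
#' cannot redistribute). Shipped so that aggregate statistics over the
#' published per-class values can be recomputed.
#'
#' @return Data frame with a `model` column (`mlpvae`, `cnnvae`, `cvae`)
#'   and one column per minority class.
#' @export
referenceFad <- function() {
  path <- system.file("extdata", "reference_fad_icbhi.csv",
                      package = "respaug")
  utils::read.csv(path, check.names = FALSE)
}

#' Per-model mean of the reference FAD scores
#'
#' Unweighted mean over the six minority classes for each VAE variant —
#' the per-model average FAD.
#'
#' @return Named numeric vector (one value per model).
#' @export
referenceFadMeans <- function() {
  tab <- referenceFad()
  vals <- as.matrix(tab[, -1])
  stats::setNames(rowMeans(vals), tab$model)
}
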