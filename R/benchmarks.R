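# Published 10-fold-average reference results for DRE-Net and its baselines
# on the public 597-image shoulder implant X-ray dataset (83 Cofield /
# 294 Depuy / 71 Tornier / 149 Zimmer). These constants support arithmetic
# comparisons (augmentation gains, gain over human visual matching); they
# are not recomputed by this package, which does not ship the real dataset.

#' Published reference benchmark averages
#'
#' Reported 10-fold cross-validation averages (percent) on the public
#' shoulder implant X-ray dataset for the DRE-Net configuration under three
#' augmentation regimes, and for the human subjective visual-matching
#' baseline evaluated under the same fold protocol.
#'
#' @return data.frame with columns `method`, `accuracy`, `f1`, `precision`,
#'   `recall`.
#' @examples
#' b <- referenceBenchmarks()
#' performanceGain(b, "drenet_sequential_ria", "drenet_random_augment")
#' @export
referenceBenchmarks <- function() {
  data.frame(
    method = c("drenet_no_augment", "drenet_random_augment",
               "drenet_sequential_ria", "subjective"),
    accuracy = c(58.10, 77.05, 85.92, 52.25),
    f1 = c(50.82, 74.80, 84.69, 49.54),
    precision = c(51.78, 76.93, 85.33, 48.86),
    recall = c(49.96, 73.07, 84.11, 50.28),
    stringsAsFactors = FALSE)
}

#' Performance gain between two benchmarked methods
#'
#' Differences of the published per-method averages, method A minus
#' method B, in percentage points.
#'
#' @param benchmarks a data.frame as from [referenceBenchmarks()].
#' @param methodA,methodB method identifiers.
#' @return named numeric vector (accuracy, f1, precision, recall) of
#'   differences.
#' @export
performanceGain <- function(benchmarks = referenceBenchmarks(), methodA,
                            methodB) {
  a <- benchmarks[benchmarks$method == methodA, ]
  b <- benchmarks[benchmarks$method == methodB, ]
  if (nrow(a) != 1L || nrow(b) != 1L) stop("unknown method identifier")
  cols <- c("accuracy", "f1", "precision", "recall")
  stats::setNames(as.numeric(a[cols]) - as.numeric(b[cols]), cols)
}
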