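#' Published per-class reference results
#'
#' Per-class one-vs-rest metrics (percent) reported for the DTODCNN-CC crop
#' classifier on its six-class drone-imagery dataset, for the 80:20 and
#' 70:30 train/test protocols (`split` tags `TR80`, `TS20`, `TR70`, `TS30`).
#' Shipped as a worked example for [macro_average()]: the published Average
#' rows (e.g. accuracy 98.13 on `TR80`) are the half-up-rounded macro means
#' of these per-class values.
#'
#' @param split Optional split tag to filter on.
#' @return Data frame with columns `split`, `class`, `accuracy`,
#'   `precision`, `recall`, `f_score`, `mcc`.
#' @examples
#' attr(macro_average(reference_per_class_metrics("TR80")), "display")
#' @export
reference_per_class_metrics <- function(split = NULL) {
  path <- system.file("extdata", "reference_per_class_metrics.csv",
                      package = "dtocrop", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(split)) df <- df[df$split == split, , drop = FALSE]
  df
}
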