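# Published per-class hybrid-model benchmark metrics on the ISIC-2019
# dermoscopy classes, shipped as a CSV so the macro aggregation can be
# reproduced without the original imagery.

#' Load the shipped per-class reference metrics
#'
#' Per-class AUC, precision, accuracy, sensitivity and specificity (percent
#' scale) reported for two hybrid radiomics + CNN random-forest models on the
#' eight ISIC-2019 lesion classes.
#'
#' @param model optional model identifier to filter on
#'   (`"mobilenet_v2_radiomics_rf"` or `"efficientnet_b4_radiomics_rf"`).
#' @return data.frame with columns `model`, `class`, `auc`, `precision`,
#'   `accuracy`, `sensitivity`, `specificity`.
#' @export
reference_metrics <- function(model = NULL) {
  path <- system.file("extdata", "isic2019_reference_metrics.csv",
                      package = "lesionlab", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(model)) {
    df <- df[df$model == model, , drop = FALSE]
    if (nrow(df) == 0)
      stop("unknown reference model: ", model, "; available: ",
           paste(unique(read.csv(path)$model), collapse = ", "))
    rownames(df) <- NULL
  }
  df
}
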