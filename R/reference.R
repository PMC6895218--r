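#' Published worked example of the fecundity accounting
#'
#' The class-by-season spawning-dynamics table reported for the Galician
#' shelf hake stock (batch fecundity and potential fecundity in thousands
#' of oocytes, accumulated batches, and season durations in months), used
#' as a frozen arithmetic oracle: feeding its batch-fecundity row and
#' cumulative potential-fecundity column through [accumulate_batches()]
#' must reproduce its batch and duration cells.  Only populated cells are
#' included (the 40-50 cm class has data in one season only).
#'
#' @return Data frame with columns `tl_class`, `season`, `bf_thousands`,
#'   `stage_label`, `pf_thousands`, `batches`, `duration_months`.
#' @export
#' @examples
#' head(reference_fecundity_table())
reference_fecundity_table <- function() {
  path <- system.file("extdata", "fecundity_table_reference.csv",
                      package = "opdensity", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
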