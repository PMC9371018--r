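#' Cell-level fill accuracy
#'
#' Fraction of amputed cells whose imputed value equals the original value.
#' Only cells missing in \code{amputed} are compared.
#'
#' @param original The complete ground-truth \code{discrete_table}.
#' @param amputed The table with planted missing cells.
#' @param imputed The imputer's output on \code{amputed}.
#' @return Scalar in [0, 1].
#' @export
fill_accuracy <- function(original, amputed, imputed) {
  m <- missing_mask(amputed)
  if (!any(m)) stop("the amputed table has no missing cells to score")
  truth <- as.matrix(original$data)[m]
  fills <- as.matrix(imputed$data)[m]
  mean(fills == truth)
}
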