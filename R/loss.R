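#' Composite detection loss
#'
#' Combines the three loss components of an anchor-free detector head —
#' bounding-box regression, classification, and objectness — into the total
#' training loss
#'
#' \deqn{L = w_{reg} \frac{L_{reg}}{N_{pos}} + \frac{L_{cls}}{N_{pos}} +
#'   \frac{L_{obj}}{N_{pos}}}
#'
#' where \eqn{N_{pos}} is the number of positive labels in the batch. The
#' component sums are inputs, not computed here; the regression weight
#' defaults to 5.0.
#'
#' @param l_reg,l_cls,l_obj non-negative component loss sums.
#' @param n_pos positive-label count in the batch; must be >= 1 (the loss is
#'   undefined for a batch with no positives and such a call is rejected).
#' @param reg_weight balancing coefficient on the regression term
#'   (default 5.0).
#' @return non-negative scalar total loss.
#' @examples
#' total_loss(l_reg = 2, l_cls = 3, l_obj = 1, n_pos = 2)  # 7
#' @export
total_loss <- function(l_reg, l_cls, l_obj, n_pos, reg_weight = 5.0) {
  for (v in list(l_reg, l_cls, l_obj)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop("loss components must be single non-negative numbers", call. = FALSE)
    }
  }
  if (!is.numeric(n_pos) || length(n_pos) != 1L || is.na(n_pos) || n_pos < 1) {
    stop("total loss is undefined for n_pos < 1 (no positive labels in batch)",
         call. = FALSE)
  }
  if (!is.numeric(reg_weight) || reg_weight < 0) {
    stop("'reg_weight' must be non-negative", call. = FALSE)
  }
  reg_weight * l_reg / n_pos + l_cls / n_pos + l_obj / n_pos
}
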