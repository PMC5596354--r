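#' Stop with a classed ccrit error
#' @noRd
ccrit_abort <- function(message, class) {
  rlang::abort(message, class = c(paste0("ccrit_", class), "ccrit_error"))
}

#' Check a 2-D numeric matrix argument
#' @noRd
check_image <- function(x, arg = "image") {
  if (!is.matrix(x) || !is.numeric(x)) {
    ccrit_abort(sprintf("`%s` must be a numeric matrix", arg), "type_error")
  }
  invisible(x)
}

#' Coerce to strict logical mask, validating binarity
#' @noRd
check_mask <- function(x, arg = "mask") {
  if (is.logical(x) && is.matrix(x)) return(!is.na(x) & x)
  if (is.numeric(x) && is.matrix(x)) {
    if (!all(x %in% c(0, 1))) {
      ccrit_abort(sprintf("`%s` must be binary (0/1 or logical)", arg), "type_error")
    }
    return(x == 1)
  }
  ccrit_abort(sprintf("`%s` must be a logical or 0/1 matrix", arg), "type_error")
}

#' Internal messaging honouring a quiet option
#' @noRd
ccrit_log <- function(..., verbose = getOption("ccrit.verbose", TRUE)) {
  if (isTRUE(verbose)) rlang::inform(paste0(...))
  invisible(NULL)
}
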