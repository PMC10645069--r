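`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
log1pexp <- function(x) {
  # numerically stable log(1 + exp(x)), single vectorized pass
  pmax(x, 0) + log1p(exp(-abs(x)))
}

inv_logit <- function(x) 1 / (1 + exp(-x))

stop_replistat <- function(msg, class) {
  stop(structure(
    class = c(class, "replistat_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Signif-round a numeric vector, leaving NA untouched
#' @noRd
round_signif <- function(x, digits = 6) {
  ifelse(is.na(x), x, signif(x, digits))
}
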