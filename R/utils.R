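`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg, ...) {
  if (isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

#' @keywords internal
majority_value <- function(x) {
  # majority of a 0/1 vector ignoring NA; ties and empty input -> NA
  ones <- sum(x == 1L, na.rm = TRUE)
  zeros <- sum(x == 0L, na.rm = TRUE)
  if (ones == 0L && zeros == 0L) return(NA_integer_)
  if (ones > zeros) 1L else if (zeros > ones) 0L else NA_integer_
}

#' Complement a 0/1 phase vector, preserving missing values
#' @param p integer vector over {0,1,NA}.
#' @return the complemented vector.
#' @export
flip_phase <- function(p) {
  ifelse(is.na(p), NA_integer_, 1L - as.integer(p))
}
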