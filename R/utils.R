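# Classed conditions so callers/tests can distinguish failure modes.
af_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "af_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

af_warn <- function(msg, class = "af_warning") {
  warning(structure(
    class = c(class, "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Blank-ish strings ("", "NA", ".") become NA; used on free-text columns.
blank_to_na <- function(x) {
  x <- trimws(x)
  x[!nzchar(x) | x %in% c("NA", "na", ".")] <- NA_character_
  x
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

# log(sum(exp(lx))) without overflow; lx may be empty (-> -Inf).
logsumexp <- function(lx) {
  if (length(lx) == 0L) return(-Inf)
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}
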