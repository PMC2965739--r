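# structural comparison of ASTs ignoring the parenthesis bookkeeping attribute
strip_paren_attrs <- function(e) {
  attr(e, "paren") <- NULL
  if (!is.null(e$args)) e$args <- lapply(e$args, strip_paren_attrs)
  e
}
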