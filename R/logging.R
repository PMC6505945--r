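## Minimal stderr logging, switched on with options(adiposeg.verbose = TRUE)
## (the command-line front end maps --verbose onto this option).

.logMsg <- function(...) {
  if (isTRUE(getOption("adiposeg.verbose", FALSE)))
    message("[adiposeg] ", sprintf(...))
  invisible(NULL)
}
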