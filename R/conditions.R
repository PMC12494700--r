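# Classed errors so callers (and the command-line wrapper) can map failure
# modes to distinct exit codes.
geneoStop <- function(class, ...) {
  stop(structure(class = c(class, "geneoError", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
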