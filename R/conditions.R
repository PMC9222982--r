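# Classed error helper so callers can distinguish configuration, shape,
# validation, likelihood and metric failures programmatically.
.roiStop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "roicox_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

.roiWarn <- function(class, fmt, ...) {
  warning(structure(
    class = c(class, "roicox_warning", "warning", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

# Deterministic child-seed derivation: one master seed fans out into the
# seeds for fold assignment, per-model initialization and data generation.
.deriveSeeds <- function(master, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}
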