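#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can distinguish validation, schema, fitting
# and domain failures programmatically.
arc_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "arcfluid_error")))
}

arc_check <- function(ok, msg, class = "arc_domain_error") {
  if (!isTRUE(ok)) arc_abort(msg, class)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ANALYTES <- c("iohexol", "pah", "amikacin")
OCCASIONS <- c("M1", "M2")
GROUPS <- c("control", "treatment")
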