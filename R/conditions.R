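# Structured warnings with stable machine-readable codes so pipeline runs
# (and tests) can assert on emitted diagnostics.
#
# Codes in use:
#   W-COLLIN  ill-conditioned predictor correlation matrix in path analysis
#   W-CLAMP   correlation estimate outside [-1, 1] clamped to the boundary
#   W-NEGVAR  negative method-of-moments genotypic variance truncated to 0
#   W-QC      quality-control flag from derived-trait arithmetic

qg_warn <- function(code, message, class = "qgpanel_warning") {
  cond <- structure(
    class = c(class, "qgpanel_warning", "warning", "condition"),
    list(message = sprintf("[%s] %s", code, message), call = sys.call(-1))
  )
  cond$code <- code
  warning(cond)
  invisible(cond)
}

qg_stop <- function(stage, message) {
  stop(sprintf("stage %s: %s", stage, message), call. = FALSE)
}
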