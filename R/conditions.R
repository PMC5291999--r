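# Classed conditions so callers and tests can discriminate failure modes.

fk_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "footkin_error")))
}

fk_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "footkin_warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_number <- function(x, name, min = -Inf, max = Inf, finite = TRUE,
                         class = "footkin_config_error") {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)) ||
      x < min || x > max) {
    fk_stop(sprintf("`%s` must be a single number in [%s, %s]", name,
                    format(min), format(max)), class)
  }
  invisible(x)
}
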