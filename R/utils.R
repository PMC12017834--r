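# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

# quadrature sum of uncertainties
quad_sum <- function(...) sqrt(sum(unlist(list(...))^2))

# check a numeric scalar
assert_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  stop_if(!is.numeric(x) || length(x) != 1L || !is.finite(x),
          sprintf("`%s` must be a finite numeric scalar", name))
  stop_if(positive && x <= 0, sprintf("`%s` must be > 0", name))
  stop_if(nonneg && x < 0, sprintf("`%s` must be >= 0", name))
  invisible(x)
}

fmt_pm <- function(x, s, digits = 3) {
  sprintf("%s +/- %s", format(signif(x, digits)), format(signif(s, digits)))
}
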