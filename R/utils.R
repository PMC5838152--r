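# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_oxival <- function(msg, class) {
  stop(structure(class = c(class, "oxival_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_pct <- function(x, name) {
  if (any(!is.finite(x) | x < 0 | x > 100)) {
    stop_oxival(sprintf("`%s` must lie in [0, 100] and be finite", name),
                "oxival_value_error")
  }
  invisible(x)
}

# sample SD with the n-1 denominator, NA-free input assumed
sd1 <- function(x) sqrt(sum((x - mean(x))^2) / (length(x) - 1L))
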