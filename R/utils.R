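# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pelnet <- function(..., class = "pelnet_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_pelnet(...)
  invisible(TRUE)
}

# Derive reproducible per-component seeds from one user seed without
# exhausting the 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 10007 + offset) %% .Machine$integer.max)
}

upper_tri_vec <- function(m) m[upper.tri(m)]

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
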