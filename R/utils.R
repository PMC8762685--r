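# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Content-free hex id drawn from the active RNG stream, so that equal seeds
# reproduce identical id sequences (and hence bitwise-identical serializations).
new_id <- function() {
  sprintf("%08x%08x",
          as.integer(floor(stats::runif(1) * 2^31)),
          as.integer(floor(stats::runif(1) * 2^31)))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
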