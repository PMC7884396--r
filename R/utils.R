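# internal helpers shared across modules

# round half away from zero (base round() is round-half-even)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# classed errors so callers can branch on the failing stage
stop_hemochroma <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("hemochroma_", class), "hemochroma_error"), ...)
}

# spans are 0-based, half-open integer intervals c(start, end); row `i` of a
# span corresponds to R matrix row i + 1
span_len <- function(span) span[2] - span[1]

span_seq <- function(span) {
  if (span_len(span) <= 0) return(integer(0))
  seq.int(span[1] + 1L, span[2])
}

check_span <- function(span, limit, what) {
  if (length(span) != 2 || anyNA(span) || span[1] < 0 || span[2] <= span[1] ||
      span[2] > limit) {
    stop_hemochroma(
      sprintf("%s must be a 0-based half-open interval inside [0, %d)", what, limit),
      "invalid_spec"
    )
  }
  invisible(as.integer(span))
}

is_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
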