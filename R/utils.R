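# Internal helpers shared across modules.

# Stop with a classed condition so tests can assert on error classes.
stop_geciq <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "geciq_error"), ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_na = FALSE) {
  if (allow_na && (is.null(x) || all(is.na(x)))) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_geciq(sprintf("`%s` must be a single finite number.", name),
               "geciq_error_domain")
  }
  if (strict_lower && x <= lower) {
    stop_geciq(sprintf("`%s` must be > %g.", name, lower), "geciq_error_domain")
  }
  if (!strict_lower && x < lower) {
    stop_geciq(sprintf("`%s` must be >= %g.", name, lower), "geciq_error_domain")
  }
  if (x > upper) {
    stop_geciq(sprintf("`%s` must be <= %g.", name, upper), "geciq_error_domain")
  }
  invisible(x)
}

# Run `expr` under a fixed RNG seed when `seed` is supplied, otherwise as-is.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) force(expr) else withr::with_seed(as.integer(seed), expr)
}

# Deterministic per-unit sub-seed derived from a master seed (kept < 2^31).
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 7919 + index * 104729) %% 2147483647)
}

# Coerce a trace input (tibble with value column, or bare numeric) to numeric.
trace_values <- function(trace, col = "value") {
  if (is.data.frame(trace)) {
    if (!col %in% names(trace)) {
      stop_geciq(sprintf("trace data frame must have a `%s` column.", col),
                 "geciq_error_input")
    }
    as.numeric(trace[[col]])
  } else if (is.numeric(trace)) {
    as.numeric(trace)
  } else {
    stop_geciq("trace must be a data frame or a numeric vector.",
               "geciq_error_input")
  }
}

trace_frame_rate <- function(trace, frame_rate = NULL) {
  if (!is.null(frame_rate)) return(frame_rate)
  fr <- attr(trace, "frame_rate")
  if (!is.null(fr)) return(fr)
  if (is.data.frame(trace) && "time_s" %in% names(trace) && nrow(trace) > 1) {
    dt <- diff(trace$time_s)
    return(1 / median(dt))
  }
  stop_geciq("frame_rate not supplied and not recoverable from the trace.",
             "geciq_error_input")
}

# Tibble constructor for a regularly sampled trace.
new_trace <- function(values, frame_rate, t0 = 0) {
  check_number(frame_rate, "frame_rate", lower = 0, strict_lower = TRUE)
  n <- length(values)
  out <- tibble::tibble(
    frame = seq_len(n),
    time_s = t0 + (seq_len(n) - 1) / frame_rate,
    value = as.numeric(values)
  )
  attr(out, "frame_rate") <- frame_rate
  out
}
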