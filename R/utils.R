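# Internal condition helpers and small numeric utilities.

flagrot_abort <- function(msg, class) {
  stop(structure(
    class = c(class, "flagrot_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_validation   <- function(msg) flagrot_abort(msg, "flagrot_validation_error")
abort_format       <- function(msg) flagrot_abort(msg, "flagrot_format_error")
abort_parse        <- function(msg) flagrot_abort(msg, "flagrot_parse_error")
abort_insufficient <- function(msg) flagrot_abort(msg, "flagrot_insufficient_data_error")
abort_no_peak      <- function(msg) flagrot_abort(msg, "flagrot_no_peak_error")
abort_domain       <- function(msg) flagrot_abort(msg, "flagrot_domain_error")
abort_io           <- function(msg) flagrot_abort(msg, "flagrot_io_error")

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so simulation helpers do not perturb the session stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Shortest decimal string that parses back to the identical double.
# Tries 15, 16, then 17 significant digits (17 always round-trips IEEE 754).
format_roundtrip <- function(x) {
  out <- sprintf("%.15g", x)
  for (digits in c("%.16g", "%.17g")) {
    bad <- is.finite(x) & (as.numeric(out) != x)
    if (!any(bad)) break
    out[bad] <- sprintf(digits, x[bad])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
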