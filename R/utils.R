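# Internal helpers shared across modules.

# Stop with a classed condition so callers/tests can distinguish user error
# classes: irmarker_domain_error (bad data), irmarker_config_error (bad knobs).
stop_domain <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "irmarker_domain_error")
}

stop_config <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "irmarker_config_error")
}

check_counts_tbl <- function(counts, call_from = "irmarker") {
  req <- c("event_id", "sample_id", "group", "inclusion", "skipping")
  missing <- setdiff(req, names(counts))
  if (length(missing) > 0) {
    stop_domain("%s: count table is missing columns: %s",
                call_from, paste(missing, collapse = ", "))
  }
  if (nrow(counts) == 0) stop_domain("%s: empty count table", call_from)
  if (any(counts$inclusion < 0) || any(counts$skipping < 0)) {
    stop_domain("%s: negative junction counts", call_from)
  }
  invisible(counts)
}

# Draw a seed stream deterministically from one integer; keeps every derived
# seed a valid 32-bit integer.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 1000003 * k) %% 2147483647L)
}

geom_mean <- function(x) exp(mean(log(x)))

`%||%` <- rlang::`%||%`
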