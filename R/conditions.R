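# Classed error conditions so callers (and tests) can distinguish
# malformed files, integrity violations, failed lookups and bad arguments.

cms_abort <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "cmapscreen_error"),
                      call = sys.call(-1)))
}

abort_format    <- function(msg, ...) cms_abort("cmapscreen_format_error", msg, ...)
abort_integrity <- function(msg, ...) cms_abort("cmapscreen_integrity_error", msg, ...)
abort_lookup    <- function(msg, ...) cms_abort("cmapscreen_lookup_error", msg, ...)
abort_args      <- function(msg, ...) cms_abort("cmapscreen_argument_error", msg, ...)

# L1000 metadata files mark missing values with the sentinel -666.
MISSING_SENTINEL <- "-666"

sentinel_to_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & trimws(x) == MISSING_SENTINEL] <- NA_character_
  x
}
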