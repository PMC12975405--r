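# Internal helpers: condition classes, rounding, seeded RNG scopes, hashing.

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("markovcea_config_error", "markovcea_error")))
}

stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("markovcea_data_error", "markovcea_error")))
}

stop_numeric <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("markovcea_numerical_error", "markovcea_error")))
}

#' Round half away from zero
#'
#' Currency display rounding. Unlike [round()], which rounds half to even,
#' ties go up in absolute value (so 0.5 -> 1, 2.5 -> 3), matching how the
#' reported dollar figures are rounded.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(2.5)      # 3
#' round_half_up(1214.664) # 1215
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stratum seed derived from the master seed and the
# stratum label, so adding or reordering strata does not perturb the
# substreams of the others. Result stays below 2^31 - 1.
stratum_seed <- function(master_seed, label) {
  codes <- utf8ToInt(label)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 1000003L
  as.integer((as.numeric(master_seed) * 7919 + h) %% 2147483646 + 1)
}

# FNV-1a 32-bit hash of a character scalar; used for config provenance.
# 32-bit ops are done on 16-bit halves: R's bitwXor only takes values that
# fit in a signed int, and the multiply would overflow double precision.
fnv1a32 <- function(txt) {
  bytes <- utf8ToInt(enc2utf8(txt))
  xor32 <- function(a, b)
    bitwXor(a %/% 65536, b %/% 65536) * 65536 + bitwXor(a %% 65536, b %% 65536)
  mul32 <- function(h, m)
    (((h %/% 65536 * m) %% 65536) * 65536 + h %% 65536 * m) %% 4294967296
  h <- 2166136261
  for (b in bytes) h <- mul32(xor32(h, b), 16777619)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# key=value log line, collected by the pipeline and surfaced as messages.
log_line <- function(level, event, ...) {
  kv <- list(...)
  tail <- if (length(kv)) {
    paste(sprintf("%s=%s", names(kv), vapply(kv, format, "")), collapse = " ")
  } else ""
  trimws(sprintf("level=%s event=%s %s", level, event, tail))
}
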