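# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so generators are pure functions of their spec.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Clamp numeric values into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Lightweight structured logger; messages are suppressible via
# options(sleepose.verbose = FALSE).
sp_log <- function(fmt, ...) {
  if (isTRUE(getOption("sleepose.verbose", TRUE))) {
    message(format(Sys.time(), "%H:%M:%S"), " [sleepose] ", sprintf(fmt, ...))
  }
  invisible(NULL)
}

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
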