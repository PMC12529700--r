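#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global random-number state so that seeded
#' generators do not disturb the caller's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# FNV-1a 32-bit hash of a character scalar; used for config fingerprints in
# manifests (stable across sessions, no external dependency).
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261  # carried as a double in [0, 2^32)
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), b)
    # 32-bit modular multiply, split to stay within double precision
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

#' Calendar-month sequence of first-of-month dates
#' @param from,to Dates (any day within the first/last month).
#' @return vector of Dates, each the 1st of a month.
#' @keywords internal
month_starts <- function(from, to) {
  from <- as.Date(format(as.Date(from), "%Y-%m-01"))
  to <- as.Date(format(as.Date(to), "%Y-%m-01"))
  if (to < from) stop_config("empty month range: %s to %s", from, to)
  seq(from, to, by = "month")
}

date_year <- function(d) as.integer(format(d, "%Y"))
date_month <- function(d) as.integer(format(d, "%m"))
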