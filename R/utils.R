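#' @keywords internal
"_PACKAGE"

# Run code with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic child seed derivation; stays below 2^31.
derive_seed <- function(master, label) {
  h <- 5381
  for (ch in utf8ToInt(paste0(label, ":", master))) {
    h <- (h * 33 + ch) %% 2147483647
  }
  as.integer(h)
}

#' Round to the nearest multiple of a unit
#'
#' Half-way cases follow [round()] (round-half-even), which matches the
#' headline rounding conventions used throughout the tradeoff model
#' (durations to the nearest 100 s, areas to the nearest km^2).
#'
#' @param x numeric vector.
#' @param unit positive rounding unit; `NULL` or 0 returns `x` unchanged.
#' @return numeric vector rounded to multiples of `unit`.
#' @export
round_to <- function(x, unit) {
  if (is.null(unit) || !is.finite(unit) || unit <= 0) return(x)
  round(x / unit) * unit
}

stop_fof <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Short deterministic digest of a configuration list (djb2 over its deparse),
# used in provenance headers.
config_digest <- function(cfg) {
  txt <- paste(deparse(cfg, control = "all"), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(txt)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", h)
}
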