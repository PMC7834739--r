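#' @keywords internal
"_PACKAGE"

# Season blocks used throughout: winter = Dec (previous year), Jan, Feb;
# spring = Mar-May; summer = Jun-Aug; fall = Sep-Nov.
SEASONS <- c("winter", "spring", "summer", "fall")

MONTH_SEASON <- c(
  "winter", "winter", "spring", "spring", "spring", "summer",
  "summer", "summer", "fall", "fall", "fall", "winter"
)

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals do not disturb the
#' caller's RNG stream.
#'
#' @param seed integer seed, or NULL to leave the RNG alone.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Deterministic per-name substream seed derived from a master seed, kept
# below 2^31 so it is a valid R integer.
derive_seed <- function(master, name) {
  h <- sum(utf8ToInt(as.character(name)) * seq_along(utf8ToInt(as.character(name))))
  as.integer((as.numeric(master) * 69069 + h) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
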