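#' Round half away from zero
#'
#' Commercial ("half-up") rounding to a fixed number of decimal places, as
#' used when printing percentages in DLA survey tables. Base R's `round()`
#' rounds half to even, which does not reproduce printed table values such as
#' 96.9697 -> 97.0.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Truncate to a fixed number of decimal places
#'
#' Drops (never rounds) trailing decimal digits, e.g. 23.88 -> 23.8 at one
#' decimal. Some published cohort-level rates are printed truncated rather
#' than rounded.
#'
#' @inheritParams round_half_up
#' @return numeric vector truncated towards zero.
#' @export
truncate_decimal <- function(x, digits = 0) {
  p <- 10^digits
  trunc(x * p) / p
}

#' Format a proportion as a percentage
#'
#' @param x proportion(s) in \[0, 1\].
#' @param digits decimal places to keep.
#' @param mode `"half-up"` (default) or `"truncate"`; see [round_half_up()]
#'   and [truncate_decimal()].
#' @return numeric percentage(s) on the 0-100 scale.
#' @export
percent <- function(x, digits = 1, mode = c("half-up", "truncate")) {
  mode <- match.arg(mode)
  switch(mode,
    "half-up"  = round_half_up(100 * x, digits),
    "truncate" = truncate_decimal(100 * x, digits)
  )
}

# Deterministic 32-bit sub-seed derived from a root seed and a string key.
# Used to give each simulated breed its own RNG stream so that adding or
# reordering breeds does not perturb the draws of the others.
derive_seed <- function(root, key) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(key))
  h <- abs(as.double(root)) %% 2147483647
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
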