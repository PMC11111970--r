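#' @keywords internal
"_PACKAGE"

#' Round half away from zero
#'
#' Fixed-point rounding with ties going up (0.005 -> 0.01), as printed
#' percentages in variant-calling reports conventionally do, rather than
#' banker's rounding as in [round()].
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return numeric vector rounded to `digits`
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# first INFO value for `key`, NA when absent; vectorized over `info`
.info_get <- function(info, key) {
  m <- regexec(paste0("(?:^|;)", key, "=([^;]*)"), info)
  vapply(regmatches(info, m),
         function(x) if (length(x) == 2L) x[2L] else NA_character_,
         character(1))
}

.info_num <- function(info, keys) {
  out <- rep(NA_real_, length(info))
  for (k in keys) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- suppressWarnings(as.numeric(.info_get(info[miss], k)))
  }
  out
}

# TRUE where chromosome `a`:`p1` sorts at or before `b`:`p2`
.bp_le <- function(a, p1, b, p2) {
  ifelse(a == b, p1 <= p2, a <= b)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
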