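# Internal helpers shared across modules.

#' Round half-up
#'
#' Base `round()` uses banker's rounding; atlas-style percent reporting
#' rounds halves away from zero (e.g. 24.5% prints as 25%).
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Report a count as a fraction of a total
#'
#' Formats fractions the way atlas studies report them: integer percent,
#' half-up, switching to one decimal place below 2% so small repertoire
#' fractions (e.g. universal peptides) are not rounded to 0% or 1%.
#'
#' @param count numerator (non-negative)
#' @param total denominator (positive)
#' @return list with `count`, `total`, `fraction` (raw), `percent` (raw,
#'   0-100 scale) and `label` (formatted string such as `"42%"` or `"0.5%"`)
#' @examples
#' report_fraction(3212, 7665)$label
#' report_fraction(35, 7665)$label
#' @export
report_fraction <- function(count, total) {
  stopifnot(is.numeric(count), is.numeric(total), total > 0, count >= 0)
  frac <- count / total
  pct <- 100 * frac
  label <- if (pct < 2) {
    sprintf("%.1f%%", round_half_up(pct, 1))
  } else {
    sprintf("%d%%", as.integer(round_half_up(pct, 0)))
  }
  list(count = count, total = total, fraction = frac, percent = pct,
       label = label)
}

# Message to stderr with a level gate controlled by option mhcatlas.verbose.
atlas_log <- function(..., level = "info") {
  if (isTRUE(getOption("mhcatlas.quiet", FALSE)) && level == "info") {
    return(invisible(NULL))
  }
  message(sprintf("[%s] %s", level, paste0(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Default tokens interpreted as missing when reading matrices.
default_missing_tokens <- function() c("", "NA", "NaN", "nan")
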