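#' Round half away from zero
#'
#' Fixed-precision rounding used for every reported table value. R's
#' \code{round()} rounds half to even (231/12 = 19.25 would become 19.2);
#' published marker tables round halves away from zero, so that convention is
#' centralized here and used by all summary functions.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return numeric vector rounded to \code{digits} places.
#' @export
#' @examples
#' roundHalfUp(19.25)   # 19.3
#' roundHalfUp(-0.05)   # -0.1
roundHalfUp <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

## enumerations used across the package
MARKER_SYSTEMS <- c("SSR", "AFLP", "MSAP")
SAMPLE_ROLES <- c("RECURRENT_PARENT", "DONOR_PARENT", "REFERENCE", "IL")
ORIGIN_CATEGORIES <- c("SHARED_PARENTAL", "RECURRENT_SPECIFIC",
                       "DONOR_SPECIFIC", "ABSENT_IN_PARENTS")
METHYLATION_STATES <- c("A", "B", "C", "D")
METHYLATION_EVENTS <- c("HYPER", "HYPO", "NONE", "UNINFORMATIVE")

## parse a band label as a fragment size in bp; NA when the label is a name
## (named SSR markers are exempt from the size rule)
parseBandSize <- function(label) {
  out <- rep(NA_real_, length(label))
  hit <- grepl("^[0-9]+(\\.[0-9]+)?\\s*(bp)?$", label, ignore.case = TRUE)
  out[hit] <- as.numeric(sub("(?i)\\s*bp$", "", label[hit], perl = TRUE))
  out
}

canonicalLocusId <- function(markerSystem, primerCombo, bandLabel) {
  if (length(bandLabel) == 0L) return(character())
  paste(markerSystem, primerCombo, bandLabel, sep = ":")
}

fmt1 <- function(x) {
  ifelse(is.na(x), "NA", formatC(roundHalfUp(x, 1L), format = "f", digits = 1L))
}
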