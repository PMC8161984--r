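#' Color (sample membership) bit-set helpers
#'
#' Samples are identified by their input order; a "color" is the set of
#' samples whose path uses a node or edge, stored as an integer bit mask
#' (bit 1 = first sample). The printable form is a '0'/'1' string whose
#' first character is the first sample, e.g. `"110"` for samples 1 and 2
#' out of 3.
#'
#' @param bits character string of '0'/'1', first sample first.
#' @param color,a,b integer bit masks.
#' @param n_samples number of samples (string length).
#' @name colors
NULL

# hard cap: masks live in one R integer
MAX_SAMPLES <- 30L

#' @rdname colors
#' @export
color_from_string <- function(bits) {
  v <- strsplit(bits, "", fixed = TRUE)[[1]]
  sum(bitwShiftL(1L, which(v == "1") - 1L))
}

#' @rdname colors
#' @export
color_to_string <- function(color, n_samples) {
  vapply(color, function(cc) {
    paste(ifelse(bitwAnd(cc, bitwShiftL(1L, seq_len(n_samples) - 1L)) != 0L,
                 "1", "0"), collapse = "")
  }, character(1))
}

#' @rdname colors
#' @export
color_samples <- function(color, n_samples) {
  which(bitwAnd(color, bitwShiftL(1L, seq_len(n_samples) - 1L)) != 0L)
}

color_popcount <- function(color, n_samples) {
  vapply(color, function(cc) length(color_samples(cc, n_samples)), integer(1))
}

color_subset <- function(a, b) bitwAnd(a, b) == a

full_color <- function(n_samples) {
  if (n_samples > MAX_SAMPLES) {
    stop("at most ", MAX_SAMPLES, " samples are supported", call. = FALSE)
  }
  as.integer(bitwShiftL(1L, n_samples) - 1L)
}
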