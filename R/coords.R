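#' TSS-relative coordinate system
#'
#' Sequenced fragments are addressed relative to the transcription start site
#' (TSS): upstream positions are negative, downstream positive, and there is
#' no position 0 (position -1 abuts +1).  Internally the package works on
#' 1-based ungapped indices along the fragment; these helpers convert between
#' the two systems.
#'
#' @param tss_position integer vector of TSS-relative positions (never 0).
#' @param tss_start,tss_end integer fragment bounds in TSS coordinates,
#'   `tss_start < tss_end`, neither equal to 0.
#' @return `tss_to_index()` returns the 1-based ordinal rank of each position
#'   among the fragment's positions in ascending order; `index_to_tss()` is
#'   its inverse; `tss_span_length()` returns the number of positions in the
#'   closed interval (excluding the nonexistent position 0).
#' @examples
#' tss_to_index(-1052, -1123, 518)  # 72
#' tss_to_index(518, -1123, 518)    # 1641
#' index_to_tss(1355, -1123, 518)   # +232
#' @export
tss_to_index <- function(tss_position, tss_start, tss_end) {
  check_tss_bounds(tss_start, tss_end)
  if (any(tss_position == 0L))
    stop("TSS position 0 does not exist (-1 abuts +1)")
  if (any(tss_position < tss_start | tss_position > tss_end))
    stop(sprintf("TSS position outside fragment [%d, %d]", tss_start, tss_end))
  idx <- tss_position - tss_start + 1L
  # positions downstream of the TSS lose the slot that 0 would occupy
  idx - as.integer(tss_start < 0L & tss_position > 0L)
}

#' @rdname tss_to_index
#' @param index integer vector of 1-based fragment indices.
#' @export
index_to_tss <- function(index, tss_start, tss_end) {
  check_tss_bounds(tss_start, tss_end)
  n <- tss_span_length(tss_start, tss_end)
  if (any(index < 1L | index > n))
    stop(sprintf("index outside 1..%d", n))
  pos <- tss_start + index - 1L
  pos + as.integer(tss_start < 0L & pos >= 0L)
}

#' @rdname tss_to_index
#' @export
tss_span_length <- function(tss_start, tss_end) {
  check_tss_bounds(tss_start, tss_end)
  tss_end - tss_start + 1L - as.integer(tss_start < 0L & tss_end > 0L)
}

check_tss_bounds <- function(tss_start, tss_end) {
  stopifnot(length(tss_start) == 1L, length(tss_end) == 1L)
  if (tss_start == 0L || tss_end == 0L)
    stop("TSS coordinates have no position 0")
  if (tss_start >= tss_end)
    stop("tss_start must be < tss_end")
  invisible(TRUE)
}
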