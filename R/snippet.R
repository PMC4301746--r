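#' Build a short text excerpt around query matches
#'
#' Extracts a window of `radius` tokens on each side of the first match
#' cluster, with ellipses marking truncation and match positions reported
#' as 0-based token offsets into the excerpt. With no matches, the first
#' `2 * radius + 1` tokens are returned.
#'
#' @param attr_tokens Token vector of the excerpted attribute.
#' @param matched_positions 0-based matched token positions (may be empty).
#' @param radius Window half-width in tokens (default 8).
#' @return A list with `text` (the excerpt string, ellipses included),
#'   `tokens`, `match_offsets` (0-based offsets of matches inside the
#'   excerpt token window) and `leading`/`trailing` ellipsis flags.
#' @export
make_snippet <- function(attr_tokens, matched_positions = integer(0),
                         radius = 8L) {
  n <- length(attr_tokens)
  if (length(matched_positions) &&
      (min(matched_positions) < 0L || max(matched_positions) >= n))
    stop("matched positions outside the attribute")
  if (length(matched_positions) == 0L) {
    lo <- 0L
    hi <- min(n - 1L, 2L * radius)
    in_window <- integer(0)
  } else {
    anchor <- min(matched_positions)
    lo <- max(0L, anchor - radius)
    hi <- min(n - 1L, anchor + radius)
    in_window <- sort(matched_positions[matched_positions >= lo &
                                        matched_positions <= hi])
  }
  if (n == 0L)
    return(list(text = "", tokens = character(0), match_offsets = integer(0),
                leading = FALSE, trailing = FALSE))
  window <- attr_tokens[(lo + 1L):(hi + 1L)]
  leading <- lo > 0L
  trailing <- hi < n - 1L
  text <- paste(window, collapse = " ")
  if (leading) text <- paste0("... ", text)
  if (trailing) text <- paste0(text, " ...")
  list(text = text, tokens = window,
       match_offsets = as.integer(in_window - lo),
       leading = leading, trailing = trailing)
}
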