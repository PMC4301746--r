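#' Tokenize free text
#'
#' Lowercases, splits on any run of non-alphanumeric characters, and discards
#' tokens shorter than two characters. No stemming is applied, so short gene
#' symbols such as "wus" survive while single digits and letters are dropped.
#' Token positions are 0-based and implied by list order.
#'
#' @param text A character scalar (may be empty or `NA`).
#' @return A character vector of tokens, possibly empty.
#' @examples
#' tokenize("Sucrose synthase (EC 2.4.1.13)")
#' @export
tokenize <- function(text) {
  if (length(text) != 1L) stop("tokenize() expects a single string")
  if (is.na(text) || !nzchar(text)) return(character(0))
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nchar(toks) >= 2L]
}

#' @keywords internal
#' Run `code` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}
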