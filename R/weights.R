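#' Parse a CDR loop weighting scheme
#'
#' Parses the field notation `"(a1:a2:a3-b1:b2:b3)"` into six non-negative
#' loop weights: the first triplet weights the three alpha-chain CDR loops
#' (CDR1/2/3), the second the beta-chain loops. Both the ASCII hyphen and
#' the en dash are accepted as triplet separator; surrounding parentheses
#' are optional. At least one weight must be positive.
#'
#' @param text scheme string, e.g. `"(1:1:4-1:1:4)"`.
#' @return an object of class `"weight_scheme"`: a named numeric vector of
#'   length 6 (`a1, a2, a3, b1, b2, b3`) with the original text kept in
#'   attribute `source_text`.
#' @examples
#' parse_weight_scheme("(1:1:4-1:1:4)")
#' @export
parse_weight_scheme <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  body <- gsub("^\\s*\\(|\\)\\s*$", "", trimws(text))
  body <- gsub("–", "-", body)  # en dash
  halves <- strsplit(body, "-", fixed = TRUE)[[1]]
  if (length(halves) != 2L)
    stop("weight scheme must contain two ':'-triplets separated by '-': ",
         sQuote(text), call. = FALSE)
  parse_triplet <- function(h) {
    toks <- strsplit(h, ":", fixed = TRUE)[[1]]
    if (length(toks) != 3L)
      stop("expected three ':'-separated weights, got ", sQuote(h),
           call. = FALSE)
    vals <- suppressWarnings(as.numeric(toks))
    bad <- is.na(vals) | vals < 0
    if (any(bad))
      stop("invalid weight token ", sQuote(toks[which(bad)[1]]),
           " (weights must be non-negative numbers)", call. = FALSE)
    vals
  }
  w <- c(parse_triplet(halves[1]), parse_triplet(halves[2]))
  if (all(w == 0))
    stop("all-zero weight scheme ", sQuote(text), call. = FALSE)
  names(w) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  structure(w, source_text = text, class = "weight_scheme")
}

#' @export
format.weight_scheme <- function(x, ...) {
  sprintf("(%s-%s)",
          paste(formatC(unclass(x)[1:3], format = "g"), collapse = ":"),
          paste(formatC(unclass(x)[4:6], format = "g"), collapse = ":"))
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("CDR loop weight scheme", format(x), "\n")
  invisible(x)
}

as_weight_scheme <- function(x) {
  if (inherits(x, "weight_scheme")) return(x)
  if (is.character(x)) return(parse_weight_scheme(x))
  if (is.numeric(x) && length(x) == 6L) {
    if (any(x < 0) || all(x == 0))
      stop("weights must be non-negative with at least one positive",
           call. = FALSE)
    return(structure(setNames(as.numeric(x),
                              c("a1", "a2", "a3", "b1", "b2", "b3")),
                     source_text = NA_character_, class = "weight_scheme"))
  }
  stop("cannot interpret object as a weight scheme", call. = FALSE)
}

# Chain weight pair "(wa:wb)" used by the SeqID model, e.g. "(0:1)".
parse_chain_weights <- function(text) {
  body <- gsub("^\\s*\\(|\\)\\s*$", "", trimws(text))
  toks <- strsplit(body, ":", fixed = TRUE)[[1]]
  if (length(toks) != 2L)
    stop("chain weights must be of the form '(wa:wb)': ", sQuote(text),
         call. = FALSE)
  w <- suppressWarnings(as.numeric(toks))
  if (anyNA(w) || any(w < 0) || all(w == 0))
    stop("chain weights must be non-negative with at least one positive: ",
         sQuote(text), call. = FALSE)
  setNames(w, c("alpha", "beta"))
}
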