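#' Construct a sentiment lexicon
#'
#' A sentiment lexicon maps lowercase tokens to mean valence ratings on the
#' lexicon's native scale (VADER-style lexicons use -4..+4). Tokens absent
#' from the lexicon are treated as neutral (0) everywhere in the package.
#'
#' @param tokens character vector of tokens; coerced to lowercase, must be
#'   unique after coercion.
#' @param means numeric vector of mean valence ratings, same length as
#'   `tokens`, each within `[-scale_max, scale_max]`.
#' @param scale_max positive scalar; the scale maximum used to normalize
#'   ratings to `[-1, 1]` downstream. Default 4, the VADER convention.
#' @return An object of class `dream_lexicon`: a named numeric vector of mean
#'   valences with a `scale_max` attribute.
#' @examples
#' lex <- dream_lexicon(c("happy", "sad"), c(2.7, -2.1))
#' lexicon_value(lex, c("happy", "sad", "table"))
#' @export
dream_lexicon <- function(tokens, means, scale_max = 4) {
  stopifnot(is.character(tokens), is.numeric(means), length(tokens) == length(means))
  if (!is.numeric(scale_max) || length(scale_max) != 1L || scale_max <= 0) {
    abort("`scale_max` must be a single positive number.")
  }
  tokens <- tolower(tokens)
  if (anyDuplicated(tokens)) abort("lexicon tokens must be unique (after lowercasing).")
  if (any(abs(means) > scale_max + 1e-9)) {
    abort("all |mean valence| must be <= scale_max.")
  }
  structure(setNames(as.numeric(means), tokens),
            scale_max = as.numeric(scale_max),
            class = "dream_lexicon")
}

#' Read a VADER-format lexicon file
#'
#' VADER-format lexicons are tab-separated with columns
#' `token<TAB>mean<TAB>sd<TAB>[raw ratings...]`; only the first two columns
#' are consumed.
#'
#' @param path path to the tab-separated lexicon file.
#' @inheritParams dream_lexicon
#' @return A [dream_lexicon()] object.
#' @examples
#' path <- system.file("extdata", "synthetic_lexicon.tsv", package = "dreamsent")
#' lex <- read_lexicon(path)
#' lexicon_value(lex, "happy")
#' @export
read_lexicon <- function(path, scale_max = 4) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(paste0("empty lexicon file: ", path))
  fields <- stringr::str_split(lines, "\t")
  bad <- lengths(fields) < 2L
  if (any(bad)) abort(paste0("malformed lexicon line(s): ", which(bad)[1L]))
  tokens <- vapply(fields, `[[`, character(1), 1L)
  means <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  if (anyNA(means)) abort("non-numeric mean valence in lexicon file.")
  dream_lexicon(tokens, means, scale_max = scale_max)
}

#' Look up normalized valence ratings
#'
#' @param lexicon a [dream_lexicon()].
#' @param tokens character vector of tokens (matched case-insensitively).
#' @return numeric vector in `[-1, 1]`: the lexicon mean divided by
#'   `scale_max`, 0 for tokens absent from the lexicon.
#' @export
lexicon_value <- function(lexicon, tokens) {
  stopifnot(inherits(lexicon, "dream_lexicon"))
  raw <- unclass(lexicon)[tolower(tokens)]
  raw[is.na(raw)] <- 0
  unname(raw) / attr(lexicon, "scale_max")
}

#' @export
print.dream_lexicon <- function(x, ...) {
  cat(sprintf("<dream_lexicon: %d tokens, scale_max = %g>\n",
              length(x), attr(x, "scale_max")))
  invisible(x)
}
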