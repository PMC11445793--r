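## Word lists for the optional vader_heuristics scoring mode: a representative
## subset of VADER's published negation and booster lists, with VADER's
## published scalars. Only the trailing 3-token context is consulted, matching
## VADER's look-back depth; sentence-level capitalization/punctuation emphasis
## is deliberately not applied.
.negate_words <- c(
  "not", "no", "never", "none", "nor", "neither", "cannot", "cant", "can't",
  "dont", "don't", "doesnt", "doesn't", "didnt", "didn't", "isnt", "isn't",
  "wasnt", "wasn't", "werent", "weren't", "wont", "won't", "wouldnt",
  "wouldn't", "couldnt", "couldn't", "shouldnt", "shouldn't", "aint", "ain't",
  "hardly", "scarcely", "rarely", "seldom", "without", "nothing", "nowhere"
)

.booster_incr <- c(
  "absolutely", "amazingly", "awfully", "completely", "considerably",
  "decidedly", "deeply", "enormously", "entirely", "especially",
  "exceptionally", "extremely", "fantastically", "greatly", "highly",
  "hugely", "incredibly", "intensely", "majorly", "particularly", "purely",
  "quite", "really", "remarkably", "so", "substantially", "thoroughly",
  "totally", "tremendously", "unbelievably", "unusually", "utterly", "very"
)

.booster_decr <- c(
  "almost", "barely", "kind", "kinda", "less", "little", "marginally",
  "occasionally", "partly", "scarce", "slightly", "somewhat", "sort", "sorta"
)

.N_SCALAR <- -0.74     # VADER negation scalar
.B_INCR <- 0.293       # VADER booster increment
.B_DAMP <- c(1, 0.95, 0.9)  # damping by distance 1..3 from the scored token

#' Tokenize a dream report
#'
#' Splits pre-cleaned dream-description text into lowercase word tokens:
#' maximal runs of letters, with internal apostrophes retained (so "don't"
#' survives as one token). Standalone punctuation and digits are dropped.
#' The length of the result is the report's word count.
#'
#' @param text a single UTF-8 string (the dream description).
#' @return character vector of tokens, in report order.
#' @examples
#' tokenize("I was falling.")
#' tokenize("Don't panic!!")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) abort("empty dream report.")
  toks <- stringr::str_extract_all(
    tolower(text), "\\p{L}+(?:'\\p{L}+)*"
  )[[1]]
  if (length(toks) == 0L) abort("report contains no word tokens.")
  toks
}

## Score one token vector. Returns normalized valences in [-1, 1].
.score_one <- function(tokens, lexicon, mode) {
  raw <- unclass(lexicon)[tokens]       # native scale; NA when absent
  raw[is.na(raw)] <- 0
  raw <- unname(raw)
  if (mode == "vader_heuristics") {
    nz <- which(raw != 0)
    for (i in nz) {
      v <- raw[i]
      for (d in seq_len(min(3L, i - 1L))) {
        prev <- tokens[i - d]
        if (prev %in% .booster_incr) {
          s <- .B_INCR * .B_DAMP[d]
          v <- v + if (v < 0) -s else s
        } else if (prev %in% .booster_decr) {
          s <- -.B_INCR * .B_DAMP[d]
          v <- v + if (v < 0) -s else s
        }
        if (prev %in% .negate_words) v <- v * .N_SCALAR
      }
      raw[i] <- v
    }
  }
  out <- raw / attr(lexicon, "scale_max")
  pmin(1, pmax(-1, out))
}

#' Score dream reports word-for-word
#'
#' Tokenizes each report and assigns every token a continuous valence rating
#' from the lexicon, producing the word-for-word valence series the rest of
#' the pipeline consumes. Ratings are normalized to `[-1, 1]` by the
#' lexicon's `scale_max`; a negative value indicates negative emotion, zero
#' neutral, positive values positive emotion.
#'
#' Two scoring modes are available. `"lexicon_only"` (default) is a pure
#' per-token lookup: each value depends on its own token alone.
#' `"vader_heuristics"` additionally applies VADER's negation and booster
#' modifiers within a trailing 3-token context window before normalization
#' (so "not happy" scores negatively), and clamps to `[-1, 1]`.
#'
#' @param reports data frame with columns `id` and `text`, one row per
#'   report; `id` must be unique.
#' @param lexicon a [dream_lexicon()].
#' @param mode `"lexicon_only"` or `"vader_heuristics"`.
#' @return A tibble with columns `report_id`, `position` (1-based token
#'   index), `token`, and `valence`. Reports that are empty after
#'   tokenization are skipped with a warning.
#' @examples
#' lex <- dream_lexicon(c("happy", "terrified"), c(2.7, -2.4))
#' score_dreams(data.frame(id = "d1", text = "I was so happy"), lex)
#' @export
score_dreams <- function(reports, lexicon,
                         mode = c("lexicon_only", "vader_heuristics")) {
  mode <- match.arg(mode)
  reports <- .as_reports(reports)
  stopifnot(inherits(lexicon, "dream_lexicon"))
  out <- purrr::map(seq_len(nrow(reports)), function(i) {
    toks <- tryCatch(tokenize(reports$text[[i]]), error = function(e) NULL)
    if (is.null(toks)) {
      warn(paste0("skipping unusable report '", reports$id[[i]],
                  "': empty after tokenization"))
      return(NULL)
    }
    tibble::tibble(
      report_id = reports$id[[i]],
      position = seq_along(toks),
      token = toks,
      valence = .score_one(toks, lexicon, mode)
    )
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) abort("no usable reports after tokenization.")
  res
}

## Validate/coerce a reports data frame (columns id, text).
.as_reports <- function(reports) {
  if (!is.data.frame(reports) || !all(c("id", "text") %in% names(reports))) {
    abort("`reports` must be a data frame with columns `id` and `text`.")
  }
  if (nrow(reports) == 0L) abort("`reports` has no rows.")
  if (anyDuplicated(reports$id)) abort("report ids must be unique.")
  tibble::as_tibble(reports[, c("id", "text")])
}

#' Read dream reports from files
#'
#' Accepts a directory of plain-text files (one report per file, the file
#' stem becoming the id), a CSV with columns `id,text`, or a JSONL file with
#' one `{"id": ..., "text": ...}` object per line.
#'
#' @param path directory of `.txt` files, a `.csv`, or a `.jsonl` file.
#' @return tibble with columns `id`, `text`.
#' @export
read_reports <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    if (length(files) == 0L) abort(paste0("no .txt files in ", path))
    return(tibble::tibble(
      id = sub("\\.txt$", "", basename(files)),
      text = vapply(files, function(f) {
        paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = " ")
      }, character(1), USE.NAMES = FALSE)
    ))
  }
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
    return(.as_reports(df))
  }
  if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- purrr::map(lines, jsonlite::fromJSON)
    return(.as_reports(tibble::tibble(
      id = vapply(recs, function(r) as.character(r$id), character(1)),
      text = vapply(recs, function(r) as.character(r$text), character(1))
    )))
  }
  abort(paste0("unsupported reports input: ", path))
}
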