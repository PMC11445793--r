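test_that("tokenization keeps word order, apostrophes, and drops the rest", {
  expect_identical(tokenize("I was falling."), c("i", "was", "falling"))
  expect_identical(tokenize("Don't panic!!"), c("don't", "panic"))
  expect_identical(tokenize("Falling -- again; AGAIN?"),
                   c("falling", "again", "again"))
  expect_error(tokenize(""), "empty")
  expect_error(tokenize("   "), "empty")
  expect_error(tokenize("1234 !!"), "no word tokens")
})

test_that("lexicon lookup normalizes by scale_max and absent tokens are neutral", {
  path <- system.file("extdata", "synthetic_lexicon.tsv", package = "dreamsent")
  lex <- read_lexicon(path)
  # read the distributed file independently of read_lexicon
  raw <- read.delim(path, header = FALSE, sep = "\t")
  happy <- raw$V2[raw$V1 == "happy"]
  terrified <- raw$V2[raw$V1 == "terrified"]
  expect_equal(lexicon_value(lex, "happy"), happy / 4)
  expect_equal(lexicon_value(lex, "TERRIFIED"), terrified / 4)
  expect_equal(lexicon_value(lex, "zzz_absent"), 0)

  sc <- score_dreams(data.frame(id = "a", text = "happy nonsenseword HAPPY"), lex)
  expect_equal(sc$valence, c(happy / 4, 0, happy / 4))
  expect_true(all(abs(sc$valence) <= 1))
})

test_that("a text with no lexicon tokens yields an all-zero series", {
  lex <- dream_lexicon(c("good", "bad"), c(2, -2))
  sc <- score_dreams(data.frame(id = "a", text = "the mundane corridor went on"), lex)
  expect_true(all(sc$valence == 0))
})

test_that("lexicon_only scoring is per-token: permuting tokens permutes values", {
  lex <- toy_lexicon()
  toks <- c("posaa", "fillerx", "negba", "posca", "fillery", "negaa")
  perm <- c(4, 1, 6, 2, 3, 5)
  v1 <- score_dreams(data.frame(id = "a", text = paste(toks, collapse = " ")), lex)
  v2 <- score_dreams(data.frame(id = "a", text = paste(toks[perm], collapse = " ")), lex)
  expect_equal(v2$valence, v1$valence[perm])
})

test_that("scoring is deterministic for identical inputs", {
  lex <- read_lexicon(system.file("extdata", "synthetic_lexicon.tsv",
                                  package = "dreamsent"))
  rep <- data.frame(id = "a", text = "a dark storm then a peaceful calm lake")
  expect_identical(score_dreams(rep, lex), score_dreams(rep, lex))
  expect_identical(score_dreams(rep, lex, mode = "vader_heuristics"),
                   score_dreams(rep, lex, mode = "vader_heuristics"))
})

test_that("vader_heuristics applies negation and booster rules in a 3-token window", {
  lex <- dream_lexicon(c("happy", "huge"), c(2.7, 4.0))
  base <- 2.7 / 4

  # negation flips and damps by the published scalar
  sc <- score_dreams(data.frame(id = "a", text = "not happy"), lex,
                     mode = "vader_heuristics")
  expect_equal(sc$valence[2], 2.7 * -0.74 / 4)
  expect_lt(sc$valence[2], 0)
  expect_equal(abs(sc$valence[2]), 0.74 * base)

  # booster adds its increment, damped with distance
  sc1 <- score_dreams(data.frame(id = "a", text = "very happy"), lex,
                      mode = "vader_heuristics")
  expect_equal(sc1$valence[2], (2.7 + 0.293) / 4)
  sc2 <- score_dreams(data.frame(id = "a", text = "very mundane happy"), lex,
                      mode = "vader_heuristics")
  expect_equal(sc2$valence[3], (2.7 + 0.293 * 0.95) / 4)
  # dampener reduces magnitude
  sc3 <- score_dreams(data.frame(id = "a", text = "slightly happy"), lex,
                      mode = "vader_heuristics")
  expect_equal(sc3$valence[2], (2.7 - 0.293) / 4)

  # outputs remain clamped to [-1, 1]
  sc4 <- score_dreams(data.frame(id = "a", text = "very huge"), lex,
                      mode = "vader_heuristics")
  expect_equal(sc4$valence[2], 1)

  # context beyond 3 tokens back has no effect
  sc5 <- score_dreams(data.frame(id = "a", text = "not one two three happy"), lex,
                      mode = "vader_heuristics")
  expect_equal(sc5$valence[5], base)

  expect_error(score_dreams(data.frame(id = "a", text = "happy"), lex,
                            mode = "sentence_compound"))
})

test_that("unusable reports are skipped with a warning in batch mode", {
  lex <- toy_lexicon()
  reps <- data.frame(id = c("ok", "bad"), text = c("posaa fillera", "1234 ..."))
  expect_warning(sc <- score_dreams(reps, lex), "bad")
  expect_identical(unique(sc$report_id), "ok")
  expect_error(suppressWarnings(
    score_dreams(data.frame(id = "bad", text = "..."), lex)
  ), "no usable reports")
})

test_that("reports round-trip through txt directories, CSV, and JSONL", {
  reps <- data.frame(id = c("r1", "r2"), text = c("a calm lake", "a dark cave"))

  d <- withr::local_tempdir()
  for (i in 1:2) writeLines(reps$text[i], file.path(d, paste0(reps$id[i], ".txt")))
  expect_equal(as.data.frame(read_reports(d)), reps)

  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(reps, csv)
  expect_equal(as.data.frame(read_reports(csv)), reps)

  jl <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(vapply(1:2, function(i) {
    jsonlite::toJSON(list(id = reps$id[i], text = reps$text[i]), auto_unbox = TRUE)
  }, character(1)), jl)
  expect_equal(as.data.frame(read_reports(jl)), reps)
})

test_that("malformed lexicons and invalid constructions are rejected", {
  expect_error(dream_lexicon(c("a", "a"), c(1, 2)), "unique")
  expect_error(dream_lexicon("a", 5, scale_max = 4), "scale_max")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("good\t2.0\t0.5", "bad\tnotanumber\t0.5"), f)
  expect_error(read_lexicon(f), "non-numeric")
})
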