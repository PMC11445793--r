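test_that("a purely neutral script yields a flat chart and zero indicators", {
  sc <- emotion_script(data.frame(kind = "neutral", length = 50, amplitude = 0))
  gen <- generate_report(sc)
  expect_equal(gen$series$valence, rep(0, 50))
  expect_equal(gen$truth$n_peaks, 0L)
  expect_equal(gen$truth$n_troughs, 0L)
  ind <- dream_indicators(dream_charts(gen$series))
  expect_equal(unlist(ind[, -1]),
               c(total_peaks = 0, total_troughs = 0, pei = 0, nei = 0,
                 oei = 0, emotion_gradient = 0))
})

test_that("a single planted positive run surfaces as exactly one peak", {
  sc <- emotion_script(data.frame(
    kind = c("neutral", "positive", "neutral"),
    length = c(35, 10, 35),
    amplitude = c(0, 0.5, 0)
  ))
  gen <- generate_report(sc)
  expect_equal(gen$truth$n_peaks, 1L)
  expect_equal(gen$truth$n_troughs, 0L)
  # the pipeline recovers the planted structure from the text itself
  fit <- dream_pipeline(gen$report, toy_lexicon())
  expect_equal(fit$indicators$total_peaks, 1L)
  expect_equal(fit$indicators$total_troughs, 0L)
})

test_that("a time-symmetric script gives a flat emotion gradient", {
  sc <- emotion_script(data.frame(
    kind = c("neutral", "positive", "neutral"),
    length = c(35, 11, 35),
    amplitude = c(0, 0.6, 0)
  ))
  gen <- generate_report(sc)
  ch <- dream_charts(gen$series)
  expect_equal(ch$y, rev(ch$y))  # palindromic chart
  fit <- fit_trends(ch, degree = 2)
  expect_equal(fit$emotion_gradient, 0, tolerance = 1e-9)
})

test_that("mirrored scripts give mirrored indicators", {
  plan <- data.frame(
    kind = c("neutral", "positive", "neutral", "negative", "neutral"),
    length = c(35, 10, 35, 12, 35),
    amplitude = c(0, 0.5, 0, 0.7, 0)
  )
  mirrored <- plan
  mirrored$kind <- c("neutral", "negative", "neutral", "positive", "neutral")
  a <- dream_indicators(dream_charts(generate_report(emotion_script(plan))$series))
  b <- dream_indicators(dream_charts(generate_report(emotion_script(mirrored))$series))
  expect_equal(a$pei, abs(b$nei))
  expect_equal(abs(a$nei), b$pei)
  expect_equal(a$total_peaks, b$total_troughs)
  expect_equal(a$emotion_gradient, -b$emotion_gradient, tolerance = 1e-10)
})

test_that("scripts validate their plans and lexicon coverage", {
  expect_error(emotion_script(data.frame(kind = "odd", length = 5, amplitude = 0)),
               "kinds")
  expect_error(emotion_script(data.frame(kind = "positive", length = 0,
                                         amplitude = 0.5)), "lengths")
  expect_error(emotion_script(data.frame(kind = "positive", length = 5,
                                         amplitude = 1.4)), "amplitudes")
  # amplitude not representable by the toy lexicon
  sc <- emotion_script(data.frame(kind = "positive", length = 5, amplitude = 0.55))
  expect_error(generate_report(sc), "no lexicon token")
})

test_that("identical seeds reproduce reports and cohorts byte-for-byte", {
  sc1 <- emotion_script(data.frame(kind = c("neutral", "positive"),
                                   length = c(20, 10), amplitude = c(0, 0.3)),
                        seed = 99)
  expect_identical(generate_report(sc1), generate_report(sc1))

  g1 <- generate_cohort(n_reports = 4, seed = 17, word_range = c(46, 90))
  g2 <- generate_cohort(n_reports = 4, seed = 17, word_range = c(46, 90))
  expect_identical(g1$reports, g2$reports)
  expect_identical(g1$externals, g2$externals)
  g3 <- generate_cohort(n_reports = 4, seed = 18, word_range = c(46, 90))
  expect_false(identical(g1$reports$text, g3$reports$text))
})

test_that("cohort generation respects word counts and validates its model", {
  g <- generate_cohort(n_reports = 6, seed = 2)
  wc <- g$truth$series |>
    dplyr::count(report_id)
  expect_true(all(wc$n >= 46 & wc$n <= 202))
  expect_equal(nrow(g$reports), 6)
  expect_equal(nrow(g$externals), 6)
  expect_setequal(names(g$externals)[-1],
                  vapply(default_externals_model(), `[[`, "", "name"))
  # the report text reproduces the exact planted series through the scorer
  sc <- score_dreams(g$reports, toy_lexicon())
  expect_equal(sc$valence, g$truth$series$valence)

  expect_error(
    generate_cohort(n_reports = 4, seed = 1, externals_model = list(
      list(name = "flat", indicator = "oei", intercept = 0, slope = 0,
           sigma = 0, integer = FALSE)
    )),
    "degenerate"
  )
  expect_error(generate_cohort(n_reports = 2, seed = 1), "n_reports")
})

test_that("planted external links are recovered with the right sign", {
  g <- generate_cohort(n_reports = 14, seed = 42, externals_model = list(
    list(name = "tracks_oei", indicator = "oei", intercept = 5, slope = 3,
         sigma = 0.2, integer = FALSE)
  ))
  res <- correlate_indicators(g$truth$indicators, g$externals)
  edge <- dplyr::filter(res, indicator == "oei", variable == "tracks_oei")
  expect_true(edge$significant)
  expect_gt(edge$coefficient, 0)
  # noiseless copy: sample correlation exactly 1
  g0 <- generate_cohort(n_reports = 8, seed = 43, externals_model = list(
    list(name = "copy_oei", indicator = "oei", intercept = 0, slope = 1,
         sigma = 0, integer = FALSE)
  ))
  r <- correlate_pair(g0$truth$indicators$oei, g0$externals$copy_oei)
  expect_equal(r$coefficient, 1)
})
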