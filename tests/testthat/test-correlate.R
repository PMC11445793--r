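test_that("overnight change is the percentage change from the evening score", {
  expect_equal(overnight_change(20, 30), 50)
  expect_equal(overnight_change(20, 20), 0)
  expect_equal(overnight_change(40, 30), -25)
  expect_equal(overnight_change(c(20, 40), c(30, 30)), c(50, -25))
  expect_warning(out <- overnight_change(c(0, 20), c(5, 30)), "undefined")
  expect_true(is.na(out[1]))
  expect_equal(out[2], 50)
})

test_that("tie-free pairs use Spearman's rho", {
  r <- correlate_pair(c(1, 2, 3, 4), c(10, 20, 30, 40))
  expect_equal(r$method, "spearman")
  expect_equal(r$coefficient, 1)
  expect_false(r$ties_present)

  r2 <- correlate_pair(c(1, 2, 3, 4), -c(1, 2, 3, 4))
  expect_equal(r2$coefficient, -1)
  expect_equal(r2$method, "spearman")

  # monotone but nonlinear: rank correlation still perfect
  x <- c(0.3, 1.1, 2.9, 5, 9.7)
  r3 <- correlate_pair(x, exp(x))
  expect_equal(r3$coefficient, 1)
})

test_that("ties in either vector flip the method to Pearson", {
  r <- correlate_pair(c(1, 2, 2, 4), c(5, 1, 4, 2))
  expect_equal(r$method, "pearson")
  expect_true(r$ties_present)
  r2 <- correlate_pair(c(5, 1, 4, 2), c(1, 2, 2, 4))  # tie in y
  expect_equal(r2$method, "pearson")
  # under the within-both policy a one-sided tie keeps Spearman
  r3 <- correlate_pair(c(1, 2, 2, 4), c(5, 1, 4, 2), tie_policy = "both")
  expect_equal(r3$method, "spearman")
  r4 <- correlate_pair(c(1, 2, 2, 4), c(5, 1, 4, 4), tie_policy = "both")
  expect_equal(r4$method, "pearson")
})

test_that("correlation is symmetric and invariant to monotone transforms", {
  set.seed(31)
  for (i in 1:10) {
    x <- runif(12)
    y <- runif(12)
    a <- correlate_pair(x, y)
    b <- correlate_pair(y, x)
    expect_equal(a$coefficient, b$coefficient)
    expect_equal(a$method, b$method)
    expect_equal(a$p_value, b$p_value)
    # strictly monotone transform of a tie-free vector preserves rho
    m <- correlate_pair(exp(2 * x), y)
    expect_equal(m$coefficient, a$coefficient)
  }
})

test_that("degenerate correlation inputs are handled explicitly", {
  expect_error(correlate_pair(1:2, 2:1), "at least 3")
  expect_warning(r <- correlate_pair(c(1, 1, 1), c(1, 5, 3)), "constant")
  expect_true(is.na(r$coefficient))
  # missing values are removed pairwise
  r2 <- correlate_pair(c(1, 2, NA, 4, 5), c(2, 4, 9, NA, 10))
  expect_equal(r2$n, 3)
})

test_that("the correlation matrix crosses every indicator with every variable", {
  set.seed(32)
  n <- 12
  ind <- tibble::tibble(
    report_id = sprintf("r%02d", 1:n),
    total_peaks = sample(0:5, n, replace = TRUE),
    pei = runif(n), nei = -runif(n), oei = runif(n, 1, 2),
    total_troughs = sample(0:4, n, replace = TRUE),
    emotion_gradient = rnorm(n, 0, 0.05)
  )
  ext <- tibble::tibble(
    report_id = ind$report_id,
    rem_pct = runif(n, 15, 25),
    tracks_oei = ind$oei + rnorm(n, 0, 0.01),
    self_oei = ind$oei
  )
  res <- correlate_indicators(ind, ext)
  expect_equal(nrow(res), 6 * 3)
  expect_setequal(unique(res$indicator),
                  c("total_peaks", "total_troughs", "pei", "nei", "oei",
                    "emotion_gradient"))
  # an indicator paired with its own copy correlates perfectly
  expect_equal(res$coefficient[res$indicator == "oei" & res$variable == "self_oei"], 1)
  # a planted near-copy is recovered as a significant positive edge
  edges <- significant_edges(res)
  hit <- dplyr::filter(edges, indicator == "oei", variable == "tracks_oei")
  expect_equal(nrow(hit), 1)
  expect_equal(hit$sign, "positive")
  # method dispatch follows the tie rule on every pair
  joined <- dplyr::inner_join(ind, ext, by = "report_id")
  for (k in seq_len(nrow(res))) {
    has_tie <- anyDuplicated(joined[[res$indicator[k]]]) > 0 ||
      anyDuplicated(joined[[res$variable[k]]]) > 0
    expect_equal(res$method[k], if (has_tie) "pearson" else "spearman")
  }
})

test_that("adjustment is off by default but available", {
  set.seed(33)
  n <- 10
  ind <- tibble::tibble(report_id = 1:n, a = runif(n), b = runif(n))
  ext <- tibble::tibble(report_id = 1:n, u = runif(n), v = runif(n))
  res <- correlate_indicators(ind, ext)
  expect_false("p_adjusted" %in% names(res))
  resh <- correlate_indicators(ind, ext, adjust = "holm")
  expect_true(all(resh$p_adjusted >= resh$p_value - 1e-12))
  expect_error(correlate_indicators(ind, ext[0, ]), "shared")
})
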