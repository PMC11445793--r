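## Synthetic dream reports with planted, exactly-known emotional structure.
## Tokens are synthetic letter-only words (so tokenization round-trips them)
## drawn from a toy lexicon with assigned valences; correctness of the
## fixtures therefore never depends on any real lexicon's contents.

## Evaluate `expr` under a temporary RNG seed, restoring global RNG state.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

#' Toy lexicon for synthetic dream reports
#'
#' Builds a [dream_lexicon()] of synthetic letter-only tokens with exactly
#' known valences: for each amplitude `a` there are `synonyms` positive
#' tokens with normalized valence `+a` and as many negative tokens with
#' `-a`. Neutral filler words used by the generator are deliberately absent
#' from the lexicon, so they exercise the neutral-default lookup path.
#'
#' @param amplitudes normalized valence magnitudes available to scripts
#'   (default `0.1, 0.2, ..., 1`).
#' @param synonyms number of interchangeable tokens per (sign, amplitude).
#' @param scale_max lexicon scale maximum (default 4).
#' @return a [dream_lexicon()].
#' @export
toy_lexicon <- function(amplitudes = seq(0.1, 1, by = 0.1), synonyms = 3,
                        scale_max = 4) {
  stopifnot(all(amplitudes > 0), all(amplitudes <= 1), synonyms >= 1)
  grid <- expand.grid(a = seq_along(amplitudes), s = seq_len(synonyms))
  pos <- paste0("pos", letters[grid$a], letters[grid$s])
  neg <- paste0("neg", letters[grid$a], letters[grid$s])
  vals <- amplitudes[grid$a] * scale_max
  dream_lexicon(c(pos, neg), c(vals, -vals), scale_max = scale_max)
}

.filler_pool <- paste0("filler", letters[1:12])

#' Define an emotion script
#'
#' An emotion script is the ground-truth plan for one synthetic dream
#' report: an ordered list of token runs, each positive, negative, or
#' neutral, with a length and (for emotional runs) a valence amplitude.
#'
#' @param plan data frame with columns `kind`
#'   (`"positive"`/`"negative"`/`"neutral"`), `length` (tokens, `>= 1`), and
#'   `amplitude` (normalized valence magnitude in `(0, 1]`; ignored for
#'   neutral runs).
#' @param seed RNG seed controlling which synonym/filler tokens realize the
#'   script; identical seeds give byte-identical reports.
#' @return an `emotion_script` object.
#' @examples
#' emotion_script(data.frame(
#'   kind = c("neutral", "positive", "neutral"),
#'   length = c(35, 10, 35),
#'   amplitude = c(0, 0.5, 0)
#' ))
#' @export
emotion_script <- function(plan, seed = 1L) {
  stopifnot(is.data.frame(plan),
            all(c("kind", "length", "amplitude") %in% names(plan)))
  plan <- tibble::as_tibble(plan)
  if (!all(plan$kind %in% c("positive", "negative", "neutral"))) {
    abort("script kinds must be positive, negative, or neutral.")
  }
  if (!all(plan$length >= 1)) abort("run lengths must be >= 1.")
  emo <- plan$kind != "neutral"
  if (any(emo & (plan$amplitude <= 0 | plan$amplitude > 1))) {
    abort("emotional run amplitudes must lie in (0, 1].")
  }
  structure(list(plan = plan, seed = as.integer(seed)), class = "emotion_script")
}

#' Generate one synthetic dream report with ground truth
#'
#' Realizes an [emotion_script()] as a token sequence drawn from the toy
#' lexicon pools and returns, alongside the report text, the exact pre-window
#' valence series and the expected chart and peak/trough counts. The
#' expected values are derived by an independent brute-force oracle (naive
#' double-loop windowing and a run-length sign scanner), not by the
#' package's own pipeline, so pipeline results can be checked against them.
#'
#' @param script an [emotion_script()].
#' @param lexicon a [toy_lexicon()] (or compatible [dream_lexicon()])
#'   containing tokens at the scripted amplitudes.
#' @param report_id id for the generated report.
#' @param window_length,overlap,normalizer windowing settings used for the
#'   ground-truth chart (defaults match [dream_charts()]).
#' @return list with elements `report` (tibble `id`, `text`), `series`
#'   (tibble `report_id`, `position`, `token`, `valence` — the exact planted
#'   series), and `truth` (list: `chart` tibble `x`,`y`; `n_peaks`;
#'   `n_troughs`).
#' @examples
#' sc <- emotion_script(data.frame(
#'   kind = c("neutral", "positive", "neutral"),
#'   length = c(35, 10, 35), amplitude = c(0, 0.5, 0)))
#' gen <- generate_report(sc)
#' gen$truth$n_peaks
#' @export
generate_report <- function(script, lexicon = toy_lexicon(),
                            report_id = "synthetic_01",
                            window_length = 30, overlap = 29,
                            normalizer = "n_windows") {
  stopifnot(inherits(script, "emotion_script"), inherits(lexicon, "dream_lexicon"))
  plan <- script$plan
  norm_vals <- unclass(lexicon) / attr(lexicon, "scale_max")
  tokens <- .with_seed(script$seed, {
    unlist(purrr::pmap(plan, function(kind, length, amplitude) {
      if (kind == "neutral") {
        return(sample(.filler_pool, length, replace = TRUE))
      }
      target <- if (kind == "positive") amplitude else -amplitude
      pool <- names(norm_vals)[abs(norm_vals - target) < 1e-9]
      if (length(pool) == 0L) {
        abort(sprintf("no lexicon token with valence %+.3f for a %s run.",
                      target, kind))
      }
      sample(pool, length, replace = TRUE)
    }))
  })
  values <- rep(
    ifelse(plan$kind == "neutral", 0,
           ifelse(plan$kind == "positive", plan$amplitude, -plan$amplitude)),
    plan$length
  )
  chart <- .bf_chart(values, window_length, overlap, normalizer)
  counts <- .bf_sign_runs(chart$y, eps = 1e-12)
  list(
    report = tibble::tibble(id = report_id, text = paste(tokens, collapse = " ")),
    series = tibble::tibble(report_id = report_id,
                            position = seq_along(tokens),
                            token = tokens, valence = values),
    truth = list(chart = chart, n_peaks = counts$peaks, n_troughs = counts$troughs)
  )
}

## Brute-force oracle chart: naive double loop over windows. Kept loop-based
## and separate from dream_charts() on purpose.
.bf_chart <- function(values, window_length, overlap, normalizer) {
  L <- length(values)
  stride <- window_length - overlap
  if (L < window_length) {
    starts <- 1L
    window_length <- L
  } else {
    starts <- seq.int(1L, L - window_length + 1L, by = stride)
  }
  W <- length(starts)
  y <- numeric(W)
  for (k in seq_len(W)) {
    s <- 0
    for (j in starts[k]:(starts[k] + window_length - 1L)) s <- s + values[j]
    y[k] <- s
  }
  div <- switch(normalizer, n_windows = W, window_length = window_length, none = 1)
  tibble::new_tibble(list(x = as.numeric(seq_len(W)), y = y / div), nrow = W)
}

## Brute-force oracle counts: scan maximal sign runs.
.bf_sign_runs <- function(y, eps) {
  peaks <- 0L; troughs <- 0L; prev <- 0L
  for (v in y) {
    s <- if (v > eps) 1L else if (v < -eps) -1L else 0L
    if (s == 1L && prev != 1L) peaks <- peaks + 1L
    if (s == -1L && prev != -1L) troughs <- troughs + 1L
    prev <- s
  }
  list(peaks = peaks, troughs = troughs)
}

#' Default linear models linking external variables to true indicators
#'
#' Each entry defines one external variable as
#' `intercept + slope * z(indicator) + Normal(0, sigma)` noise, where `z()`
#' is the cohort z-score of the named true indicator (so `slope` and
#' `sigma` directly set the effect size). The default set emulates the
#' classes of variables a sleep-lab validation would bring — PSG-derived
#' sleep architecture, overnight affect change, and trait questionnaires —
#' with link signs chosen to mirror the relationships such studies report
#' (e.g. a steeper positive emotion gradient with more REM and fewer
#' awakenings, more troughs with thinner psychological boundaries).
#' Awakening counts are rounded to integers, which realistically produces
#' ties and so exercises the Pearson fallback of the correlation protocol.
#'
#' @return list of model entries (name, indicator, intercept, slope, sigma,
#'   integer).
#' @export
default_externals_model <- function() {
  e <- function(name, indicator, intercept, slope, sigma, integer = FALSE) {
    list(name = name, indicator = indicator, intercept = intercept,
         slope = slope, sigma = sigma, integer = integer)
  }
  list(
    e("rem_pct",           "emotion_gradient", 20,   5,   2),
    e("n2_pct",            "total_peaks",      50,  -4,   2),
    e("awakenings",        "emotion_gradient",  8,  -2.5, 1, integer = TRUE),
    e("n2_awakenings",     "emotion_gradient",  4,  -1.5, 0.8, integer = TRUE),
    e("drf",               "total_peaks",       3.5, 1.2, 0.6),
    e("pos_affect_change", "nei",              10,  -8,   4),
    e("boundary_q",        "total_troughs",   130,   6,   3),
    e("openness",          "oei",               4.5, 1.1, 0.5)
  )
}

#' Null external-variables model
#'
#' All slopes zero: external variables are pure noise, independent of every
#' indicator. Used for type-I-error simulations of the correlation
#' protocol.
#'
#' @param names variable names to generate.
#' @param sigma noise standard deviation.
#' @return list of model entries.
#' @export
null_externals_model <- function(names = "null_var", sigma = 1) {
  purrr::map(names, function(nm) {
    list(name = nm, indicator = "oei", intercept = 0, slope = 0,
         sigma = sigma, integer = FALSE)
  })
}

## Default per-report script plan: neutral stretches alternating with
## emotional runs until the target word count is reached.
.default_script_plan <- function(n_words, amplitudes = seq(0.1, 1, by = 0.1)) {
  kind <- "neutral"
  len <- sample(8:20, 1)
  amp <- 0
  total <- len
  while (total < n_words) {
    el <- sample(4:12, 1)
    kind <- c(kind, sample(c("positive", "negative"), 1), "neutral")
    nl <- sample(8:25, 1)
    len <- c(len, el, nl)
    amp <- c(amp, sample(amplitudes, 1), 0)
    total <- total + el + nl
  }
  plan <- data.frame(kind = kind, length = len, amplitude = amp)
  # trim to exactly n_words
  cum <- cumsum(plan$length)
  keep <- which(cum - plan$length < n_words)
  plan <- plan[keep, , drop = FALSE]
  excess <- sum(plan$length) - n_words
  if (excess > 0) {
    last <- nrow(plan)
    plan$length[last] <- plan$length[last] - excess
    plan <- plan[plan$length >= 1, , drop = FALSE]
  }
  plan
}

#' Generate a synthetic dream cohort with external variables
#'
#' Samples per-report emotion scripts, realizes them as reports, and
#' constructs an external-variables table as specified linear functions of
#' the true indicators plus Gaussian noise, so the expected correlation
#' signs are known. Defaults emulate the scale of a small sleep-lab pilot:
#' 14 reports with word counts drawn uniformly from 46 to 202.
#'
#' @param n_reports number of reports (default 14; must be `>= 3`).
#' @param seed master RNG seed; identical seeds give byte-identical output.
#' @param lexicon toy lexicon the scripts draw from.
#' @param externals_model list of model entries as produced by
#'   [default_externals_model()] or [null_externals_model()].
#' @param word_range inclusive range of report word counts (default
#'   `c(46, 202)`).
#' @param script_sampler function(n_words) returning a script plan data
#'   frame; defaults to neutral stretches alternating with short emotional
#'   runs.
#' @param window_length,overlap,normalizer windowing settings for the
#'   ground-truth indicators.
#' @return list: `reports` (tibble `id`, `text`), `externals` (tibble,
#'   `report_id` + one column per model entry), `truth` (list: `series`
#'   long tibble of exact planted valences; `indicators` true indicator
#'   table; `scripts` the sampled plans).
#' @export
generate_cohort <- function(n_reports = 14, seed = 1L,
                            lexicon = toy_lexicon(),
                            externals_model = default_externals_model(),
                            word_range = c(46, 202),
                            script_sampler = NULL,
                            window_length = 30, overlap = 29,
                            normalizer = "n_windows") {
  if (n_reports < 3) abort("`n_reports` must be >= 3.")
  if (length(externals_model) > 0) {
    degen <- vapply(externals_model,
                    function(m) m$slope == 0 && m$sigma == 0, logical(1))
    if (any(degen)) abort("degenerate externals model: zero slope and zero noise.")
  }
  if (is.null(script_sampler)) script_sampler <- .default_script_plan
  ids <- sprintf("dream_%02d", seq_len(n_reports))
  gen <- .with_seed(seed, {
    n_words <- sample(word_range[1]:word_range[2], n_reports, replace = TRUE)
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n_reports + 1L)
    plans <- purrr::map(n_words, script_sampler)
    list(n_words = n_words, sub_seeds = sub_seeds, plans = plans)
  })
  reports <- purrr::map(seq_len(n_reports), function(i) {
    generate_report(
      emotion_script(gen$plans[[i]], seed = gen$sub_seeds[i]),
      lexicon = lexicon, report_id = ids[i],
      window_length = window_length, overlap = overlap,
      normalizer = normalizer
    )
  })
  series <- dplyr::bind_rows(purrr::map(reports, "series"))
  charts <- dream_charts(series, window_length = window_length,
                         overlap = overlap, normalizer = normalizer)
  indicators <- dream_indicators(charts)
  externals <- tibble::tibble(report_id = ids)
  if (length(externals_model) > 0) {
    externals <- .with_seed(gen$sub_seeds[n_reports + 1L], {
      for (m in externals_model) {
        v <- indicators[[m$indicator]]
        if (is.null(v)) abort(paste0("unknown indicator in externals model: ",
                                     m$indicator))
        z <- if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else rep(0, length(v))
        val <- m$intercept + m$slope * z + rnorm(length(v), 0, m$sigma)
        if (isTRUE(m$integer)) val <- round(val)
        externals[[m$name]] <- val
      }
      externals
    })
  }
  list(
    reports = dplyr::bind_rows(purrr::map(reports, "report")),
    externals = externals,
    truth = list(series = series, indicators = indicators, scripts = gen$plans)
  )
}
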