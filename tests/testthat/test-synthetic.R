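test_that("default generation matches the study shape and is deterministic", {
  gen <- generate_corpus(generator_config(), seed = 17)
  expect_identical(nrow(gen$corpus), 121L)
  expect_identical(label_counts(gen$corpus),
                   c(migraine = 81L, cluster_headache = 40L))
  expect_true(all(gen$corpus$age >= 18))
  expect_true(all(gen$corpus$sex %in% c("female", "male")))

  gen2 <- generate_corpus(generator_config(), seed = 17)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_corpus(gen$corpus, f1); write_corpus(gen2$corpus, f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical
  expect_false(identical(
    generate_corpus(generator_config(), seed = 18)$corpus$text[1],
    gen$corpus$text[1]))
})

test_that("ground-truth audits are clean and detect tampering", {
  for (s in c(1, 2)) {
    gen <- generate_corpus(small_signal_config(), seed = s)
    aud <- verify_ground_truth(gen)
    expect_true(aud$ok)
  }
  gen <- generate_corpus(small_signal_config(), seed = 3)
  # record 5 is a migraine narrative; sneaking one extra own-class keyword
  # into its last sentence must be caught by the keyword recount
  gen$corpus$text[5] <- sub("\\.$", " hoofdpijn.", gen$corpus$text[5])
  aud <- verify_ground_truth(gen)
  expect_false(aud$ok)
  expect_true(gen$corpus$record_id[5] %in% aud$issues$record_id)
})

test_that("audits stay clean across varied configurations", {
  set.seed(123)
  for (i in 1:6) {
    cfg <- generator_config(
      n_per_class = c(migraine = sample(6:14, 1),
                      cluster_headache = sample(4:8, 1)),
      keyword_rate = runif(1, 0, 0.12),
      sentiment_token_rate = runif(1, 0.02, 0.1),
      p_doc_negative = runif(1, 0.5, 1),
      length_model = list(
        migraine = c(meanlog = log(60), sdlog = 0.5),
        cluster_headache = c(meanlog = log(60), sdlog = 0.5)),
      mean_sentence_tokens = sample(8:18, 1),
      n_no_attack = c(migraine = 1L, cluster_headache = 0L))
    gen <- generate_corpus(cfg, seed = 100 + i)
    expect_true(verify_ground_truth(gen)$ok)
  }
})

test_that("realized distributions hit the configured targets", {
  cfg <- generator_config(n_per_class = c(migraine = 200L,
                                          cluster_headache = 200L))
  gen <- generate_corpus(cfg, seed = 42)
  docs <- tokenize_corpus(gen$corpus)
  stats_tbl <- corpus_token_stats(docs)
  lab <- stats::setNames(gen$corpus$diagnosis, gen$corpus$record_id)
  med_m <- stats::median(stats_tbl$tokens[lab[stats_tbl$record_id] == "migraine"])
  med_c <- stats::median(stats_tbl$tokens[lab[stats_tbl$record_id] == "cluster_headache"])
  expect_lt(abs(med_m - 474) / 474, 0.15)
  expect_lt(abs(med_c - 508) / 508, 0.15)

  # female fraction inside the 99% binomial interval of its target
  p_f <- mean(gen$corpus$sex[gen$corpus$diagnosis == "migraine"] == "female")
  half <- stats::qnorm(0.995) * sqrt(0.8 * 0.2 / 200)
  expect_true(abs(p_f - 0.8) <= half)
})

test_that("lexicon fixtures exercise cascade semantics by construction", {
  lexes <- generate_lexicon_fixtures(generator_config())
  expect_length(lexes, 4L)
  # at least one word in lexicons 1 and 3 with opposite signs
  overlap <- intersect(names(lexes[[1]]$entries), names(lexes[[3]]$entries))
  expect_true(length(overlap) >= 1)
  signs <- sign(lexes[[1]]$entries[overlap]) * sign(lexes[[3]]$entries[overlap])
  expect_true(any(signs < 0))
  # valences cover both signs in every lexicon
  for (lex in lexes) {
    expect_true(any(lex$entries < 0) && any(lex$entries > 0))
  }
  # cascade lookup equals the ordered scan (first-match) oracle
  cas <- lexicon_cascade(lexes)
  words <- unique(unlist(lapply(lexes, function(l) names(l$entries))))
  got <- cascade_lookup(words, cas)
  norm <- lapply(lexes, function(l) l$entries / max(abs(l$entries)))
  want <- vapply(words, function(w) {
    for (l in norm) if (w %in% names(l)) return(l[[w]])
    NA_real_
  }, numeric(1))
  expect_equal(got, unname(want))
})

test_that("keyword recovery grows with the emission rate", {
  recovery <- function(rate, seed) {
    cfg <- small_signal_config(keyword_rate = rate)
    gen <- generate_corpus(cfg, seed = seed)
    docs <- preprocess_corpus(gen$corpus, blocklist = default_blocklist(),
                              stopwords = default_stopwords())
    keys <- keyness_analysis(docs, gen$corpus, min_count = 1)
    injected <- unlist(cfg$class_keywords)
    top <- keys$word[seq_len(min(20L, nrow(keys)))]
    ok <- vapply(seq_along(injected), function(i) {
      w <- injected[i]
      dir <- if (grepl("^cluster", names(injected)[i])) "target" else "reference"
      w %in% top && identical(keys$direction[keys$word == w], dir)
    }, logical(1))
    mean(ok)
  }
  rates <- c(0, 0.03, 0.1)
  rec <- vapply(rates, recovery, numeric(1), seed = 77)
  expect_true(all(diff(rec) >= 0))
  expect_equal(rec[3], 1)
})

test_that("infeasible configurations are rejected", {
  expect_error(generator_config(keyword_rate = 1.2), "probabilities")
  expect_error(generator_config(keyword_rate = 0.5, sentiment_token_rate = 0.6),
               "sum to at most 1")
  expect_error(generator_config(n_per_class = c(migraine = 0L,
                                                cluster_headache = 5L)),
               ">= 1")
  expect_error(generator_config(n_no_attack = c(migraine = 99L,
                                                cluster_headache = 0L)),
               "n_no_attack")
  expect_error(generator_config(theme_mix = c(weather = 1)), "unknown theme")
})

test_that("a two-record zero-signal corpus has exchangeable vocabularies", {
  cfg <- generator_config(
    n_per_class = c(migraine = 1L, cluster_headache = 1L),
    keyword_rate = 0, label_token_rate = 0,
    length_model = list(migraine = c(meanlog = log(60), sdlog = 0.3),
                        cluster_headache = c(meanlog = log(60), sdlog = 0.3)),
    n_no_attack = c(migraine = 0L, cluster_headache = 0L))
  gen <- generate_corpus(cfg, seed = 9)
  docs <- tokenize_corpus(gen$corpus)
  vocab_pool <- c(default_stopwords()$words,
                  headachetext:::background_vocab(700, character(0)),
                  headachetext:::sentiment_word_pools()$negative,
                  headachetext:::sentiment_word_pools()$positive)
  for (d in docs) {
    expect_true(all(doc_tokens(d) %in% vocab_pool))
    expect_false(any(doc_tokens(d) %in%
                       unlist(generator_config()$class_keywords)))
  }
})
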