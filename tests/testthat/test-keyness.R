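test_that("frequency tables aggregate counts and conserve totals", {
  ft <- build_frequency_table(
    list(toy_doc(list(c("a", "b", "a")))),
    list(toy_doc(list("b")))
  )
  expect_equal(ft$group_totals, c(target = 3, reference = 1))
  expect_equal(ft$types$a[ft$types$word == "a"], 2)
  expect_equal(ft$types$b[ft$types$word == "a"], 0)
  expect_equal(unlist(ft$types[ft$types$word == "b", c("a", "b")]),
               c(a = 1, b = 1))

  # identical groups give symmetric counts
  same <- list(toy_doc(list(c("x", "y", "x"))))
  ft2 <- build_frequency_table(same, same)
  expect_equal(ft2$types$a, ft2$types$b)

  expect_error(build_frequency_table(list(), same), "empty target")

  # conservation: group totals equal the preprocessing token counts
  gen <- generate_corpus(small_signal_config(), seed = 2)
  docs <- preprocess_corpus(gen$corpus, blocklist = default_blocklist(),
                            stopwords = default_stopwords())
  lab <- stats::setNames(gen$corpus$diagnosis, gen$corpus$record_id)
  tgt <- docs[names(docs)[lab[names(docs)] == "cluster_headache"]]
  ref <- docs[names(docs)[lab[names(docs)] == "migraine"]]
  ft3 <- build_frequency_table(tgt, ref)
  expect_equal(ft3$group_totals[["target"]],
               sum(corpus_token_stats(tgt)$tokens))
  expect_equal(ft3$group_totals[["reference"]],
               sum(corpus_token_stats(ref)$tokens))
  expect_equal(sum(ft3$types$a), ft3$group_totals[["target"]])
})

test_that("the 2x2 chi-square matches its closed form and chisq.test", {
  # closed form, written independently of the implementation
  closed_form <- function(a, b, c, d, correct) {
    n <- a + b + c + d
    dev <- abs(a * d - b * c)
    if (correct) dev <- max(0, dev - n / 2)
    n * dev^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  }
  row <- keyness_chi2(10, 2, 90, 198)
  expect_equal(row$chi2, closed_form(10, 2, 90, 198, TRUE), tolerance = 1e-12)
  expect_equal(row$chi2, 11.8164, tolerance = 1e-4)
  expect_identical(row$direction, "target")
  expect_identical(row$tier, "*")

  # proportionally identical distributions: uncorrected statistic is zero
  expect_equal(keyness_chi2(5, 10, 95, 190, correct = FALSE)$chi2, 0)
  expect_identical(keyness_chi2(5, 10, 95, 190, correct = FALSE)$tier, "ns")

  # swapping groups preserves chi2 and flips direction
  fwd <- keyness_chi2(10, 2, 90, 198)
  rev <- keyness_chi2(2, 10, 198, 90)
  expect_equal(fwd$chi2, rev$chi2)
  expect_identical(rev$direction, "reference")

  set.seed(99)
  for (i in 1:300) {
    a <- rpois(1, 8); b <- rpois(1, 8)
    c <- rpois(1, 300) + 1; d <- rpois(1, 300) + 1
    if (a + b == 0) next
    for (corr in c(TRUE, FALSE)) {
      got <- keyness_chi2(a, b, c, d, correct = corr)$chi2
      want <- closed_form(a, b, c, d, corr)
      expect_equal(got, want, tolerance = 1e-10)
      # independent oracle: stats::chisq.test on the 2x2 table
      suppressWarnings(
        ct <- stats::chisq.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                                correct = corr))
      if (is.finite(ct$statistic)) {
        expect_equal(got, unname(ct$statistic), tolerance = 1e-8)
        expect_equal(keyness_chi2(a, b, c, d, correct = corr)$p_value,
                     unname(ct$p.value), tolerance = 1e-8)
      }
    }
  }
})

test_that("significance tiers step exactly at 1e-2, 1e-5 and 1e-8", {
  eps <- 1e-12
  p <- c(1, 0.5, 1e-2 + eps, 1e-2, 1e-2 - eps, 1e-5, 1e-5 - eps,
         1e-8, 1e-8 - eps, 1e-30)
  expect_identical(keyness_tier(p),
                   c("ns", "ns", "ns", "ns", "*", "*", "**", "**", "***",
                     "***"))
})

test_that("keyword ranking filters, sorts and tie-breaks alphabetically", {
  docs_t <- list(toy_doc(list(c(rep("zeldzaam", 2), rep("kern", 30),
                                rep("vul", 40)))))
  docs_r <- list(toy_doc(list(c(rep("vul", 60), rep("ander", 10)))))
  ft <- build_frequency_table(docs_t, docs_r)
  out <- rank_keywords(ft, min_count = 5)
  expect_false("zeldzaam" %in% out$word)  # below min_count
  expect_identical(out$word[1], "kern")
  expect_identical(out$direction[1], "target")
  expect_true(all(diff(out$chi2) <= 0))

  # equal chi2 rows appear in alphabetical order
  ft_tie <- build_frequency_table(
    list(toy_doc(list(c(rep("bb", 10), rep("aa", 10), rep("x", 30))))),
    list(toy_doc(list(c(rep("x", 50)))))
  )
  tie <- rank_keywords(ft_tie, min_count = 5)
  two <- tie[tie$word %in% c("aa", "bb"), ]
  expect_equal(two$chi2[1], two$chi2[2])
  expect_identical(two$word, c("aa", "bb"))
})

test_that("injected class keywords are recovered at the top ranks", {
  gen <- generate_corpus(small_signal_config(), seed = 8)
  docs <- preprocess_corpus(gen$corpus, blocklist = default_blocklist(),
                            stopwords = default_stopwords())
  keys <- keyness_analysis(docs, gen$corpus)
  cfg <- small_signal_config()
  top <- keys$word[seq_len(15)]
  for (w in cfg$class_keywords$cluster_headache) {
    expect_true(w %in% top)
    expect_identical(keys$direction[keys$word == w], "target")
  }
  for (w in cfg$class_keywords$migraine) {
    expect_true(w %in% top)
    expect_identical(keys$direction[keys$word == w], "reference")
  }
})
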