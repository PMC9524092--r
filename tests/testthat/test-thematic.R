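test_that("theme proportions are themed-token shares of total tokens", {
  doc <- toy_doc(list(rep("a", 4), rep("b", 3), rep("c", 3)))
  ann <- theme_annotation("doc", list(`1` = "attack_description"))
  pr <- theme_proportions(doc, ann)
  expect_equal(pr$proportion[pr$theme == "attack_description"], 0.4)
  expect_equal(sum(pr$proportion), 0.4)

  # full coverage
  ann_all <- theme_annotation("doc", list(`1` = "treatment", `2` = "treatment",
                                          `3` = "treatment"))
  pr2 <- theme_proportions(doc, ann_all)
  expect_equal(pr2$proportion[pr2$theme == "treatment"], 1)

  # multi-theme sentences count toward each theme independently
  ann_multi <- theme_annotation("doc", list(
    `1` = c("treatment", "burden_of_disease"), `2` = "treatment"))
  pr3 <- theme_proportions(doc, ann_multi)
  expect_equal(pr3$proportion[pr3$theme == "treatment"], 0.7)
  expect_equal(pr3$proportion[pr3$theme == "burden_of_disease"], 0.4)

  expect_error(theme_proportions(toy_doc(list()), ann), "no tokens")
  expect_error(theme_proportions(doc, theme_annotation("doc",
               list(`9` = "triggers"))), "out of range")
  expect_error(theme_annotation("doc", list(`1` = "weather")), "unknown theme")
})

test_that("proportions match a brute-force per-sentence oracle", {
  set.seed(12)
  for (i in 1:60) {
    n_sent <- sample(2:6, 1)
    sents <- replicate(n_sent, rep("w", sample(1:9, 1)), simplify = FALSE)
    doc <- toy_doc(sents, id = "r")
    idx <- sample(seq_len(n_sent), sample(0:n_sent, 1))
    themes <- sample(theme_labels(), length(idx), replace = TRUE)
    asg <- split(themes, as.character(idx))
    ann <- theme_annotation("r", asg)
    pr <- theme_proportions(doc, ann)
    total <- sum(lengths(sents))
    for (th in theme_labels()) {
      # brute force: sum sentence lengths whose assignment set contains th
      manual <- sum(vapply(seq_len(n_sent), function(s) {
        ts <- asg[[as.character(s)]]
        if (!is.null(ts) && th %in% ts) lengths(sents)[s] else 0L
      }, numeric(1)))
      expect_equal(pr$proportion[pr$theme == th], manual / total)
    }
  }
})

test_that("group summaries mirror the per-theme quartile structure", {
  props <- dplyr::bind_rows(
    theme_proportions(toy_doc(list(rep("a", 2), rep("b", 8)), id = "r1"),
                      theme_annotation("r1", list(`1` = "treatment"))),
    theme_proportions(toy_doc(list(rep("a", 5), rep("b", 5)), id = "r2"),
                      theme_annotation("r2", list(`1` = "treatment")))
  )
  lab <- c(r1 = "migraine", r2 = "cluster_headache")
  out <- summarize_themes(props, lab)
  # a theme absent from all texts keeps a 0 (0-0) row
  comorb <- out[out$group == "full_cohort" & out$theme == "comorbidities", ]
  expect_equal(unlist(comorb[, c("median", "q1", "q3")]),
               c(median = 0, q1 = 0, q3 = 0))
  # single-record group: median equals that record's proportion
  mig <- out[out$group == "migraine" & out$theme == "treatment", ]
  expect_equal(mig$median, 0.2)
  full <- out[out$group == "full_cohort" & out$theme == "treatment", ]
  expect_equal(full$median, 0.35)
})

test_that("annotations round-trip through 0-based JSON", {
  anns <- list(
    r1 = theme_annotation("r1", list(`1` = "attack_description",
                                     `4` = c("treatment", "burden_of_disease"))),
    r2 = theme_annotation("r2", list())
  )
  f <- withr::local_tempfile(fileext = ".json")
  write_theme_annotations(anns, f)
  txt <- paste(readLines(f), collapse = "")
  expect_match(txt, '"0"')   # first sentence stored 0-based
  back <- read_theme_annotations(f)
  expect_equal(back$r1$assignments, anns$r1$assignments)
  expect_length(back$r2$assignments, 0L)
})

test_that("theme sub-corpus extraction concatenates themed sentences", {
  corp <- as_corpus(tibble::tibble(
    record_id = c("r1", "r2"),
    text = c("zin een. zin twee. zin drie. zin vier. zin vijf.",
             "alles rustig hier."),
    diagnosis = c("migraine", "cluster_headache"),
    age = c(30L, 40L), sex = c("female", "male")))
  anns <- list(
    r1 = theme_annotation("r1", list(`1` = "attack_description",
                                     `3` = "attack_description",
                                     `5` = "attack_description",
                                     `2` = "treatment")),
    r2 = theme_annotation("r2", list(`1` = "treatment")))
  sub <- extract_theme_subcorpus(corp, anns, "attack_description")
  expect_identical(sub$record_id, "r1")
  expect_identical(sub$text, "zin een. zin drie. zin vijf.")
  expect_identical(sub$diagnosis, "migraine")

  expect_warning(
    empty <- extract_theme_subcorpus(corp, anns, "comorbidities"),
    "no record carries")
  expect_identical(nrow(empty), 0L)
})

test_that("single-theme annotations conserve the token denominator", {
  gen <- generate_corpus(small_signal_config(), seed = 4)
  docs <- tokenize_corpus(gen$corpus)
  for (rid in gen$corpus$record_id[1:10]) {
    doc <- docs[[rid]]
    ann <- gen$annotations[[rid]]
    pr <- theme_proportions(doc, ann)
    total <- sum(lengths(doc$sentences))
    themed <- sum(pr$proportion) * total
    unannotated <- sum(lengths(doc$sentences)[
      setdiff(seq_along(doc$sentences),
              as.integer(names(ann$assignments)))])
    expect_equal(themed + unannotated, total)
  }
})
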