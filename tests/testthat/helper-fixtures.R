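# shared fixtures built in code

toy_doc <- function(sentences, id = "doc") {
  headachetext:::new_tokenized_document(id, sentences)
}

# zero-signal study-scale configuration: labels independent of text
# (no keyword injection, identical per-class length and metadata models);
# shorter texts than the study default keep repeated runs cheap
null_config <- function() {
  generator_config(
    n_per_class = c(migraine = 74L, cluster_headache = 38L),
    keyword_rate = 0,
    shared_vocab_size = 250L,
    length_model = list(
      migraine = c(meanlog = log(80), sdlog = 0.5),
      cluster_headache = c(meanlog = log(80), sdlog = 0.5)
    ),
    mean_sentence_tokens = 12,
    n_no_attack = c(migraine = 0L, cluster_headache = 0L),
    metadata_model = list(
      migraine = list(age_mean = 45, age_sd = 13, p_female = 0.6),
      cluster_headache = list(age_mean = 45, age_sd = 13, p_female = 0.6)
    )
  )
}

# small corpus with strong keyword signal, for quick classification tests
small_signal_config <- function(keyword_rate = 0.1,
                                n = c(migraine = 24L, cluster_headache = 12L)) {
  generator_config(
    n_per_class = n,
    keyword_rate = keyword_rate,
    shared_vocab_size = 150L,
    length_model = list(
      migraine = c(meanlog = log(70), sdlog = 0.4),
      cluster_headache = c(meanlog = log(70), sdlog = 0.4)
    ),
    mean_sentence_tokens = 10,
    n_no_attack = c(migraine = 0L, cluster_headache = 0L)
  )
}

# corpus with fully disjoint class vocabularies (perfectly separable)
separable_corpus <- function(n_per_class = 10L) {
  rows <- list()
  for (i in seq_len(n_per_class)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      record_id = sprintf("m%02d", i),
      text = paste(rep(c("bonk", "dalf", "gorm"), 8), collapse = " "),
      diagnosis = "migraine", age = 40L + i, sex = "female")
    rows[[length(rows) + 1L]] <- tibble::tibble(
      record_id = sprintf("c%02d", i),
      text = paste(rep(c("pelt", "nusk", "fiam"), 8), collapse = " "),
      diagnosis = "cluster_headache", age = 50L + i, sex = "male")
  }
  as_corpus(dplyr::bind_rows(rows))
}

toy_cascade <- function() {
  lexicon_cascade(list(
    sentiment_lexicon(c(pijn = -1, rustig = 0.8, dubbel = -0.9), name = "one"),
    sentiment_lexicon(c(moe = -0.5, fijn = 0.5), name = "two"),
    sentiment_lexicon(c(dubbel = 0.5, extra = -0.2), name = "three")
  ))
}
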