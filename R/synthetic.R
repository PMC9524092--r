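#' Default Dutch stop-word list bundled with the package
#'
#' @return A `word_list` with purpose `stopwords`.
#' @export
default_stopwords <- function() {
  read_wordlist(system.file("extdata", "stopwords_nl.txt",
                            package = "headachetext"),
                purpose = "stopwords")
}

#' Default class-label blocklist bundled with the package
#'
#' Diagnosis names and medication references whose presence would leak the
#' class label into features or sentiment scores.
#'
#' @return A `word_list` with purpose `label_blocklist`.
#' @export
default_blocklist <- function() {
  read_wordlist(system.file("extdata", "blocklist_nl.txt",
                            package = "headachetext"),
                purpose = "label_blocklist")
}

# Deterministic pronounceable pseudo-word inventory for background text.
# Consonant-vowel-consonant forms; reserved words (stop words, keywords,
# label mentions) are excluded so injected signal stays class-exclusive.
background_vocab <- function(size, reserved = character(0)) {
  c1 <- c("b", "d", "f", "g", "h", "k", "l", "m", "n", "p")
  v <- c("a", "e", "i", "o", "u", "aa", "ee", "oo", "ui", "ei")
  c2 <- c("k", "l", "m", "n", "p", "s", "t")
  words <- as.vector(outer(as.vector(outer(c1, v, paste0)), c2, paste0))
  words <- setdiff(words, reserved)
  if (size > length(words)) {
    stop("shared_vocab_size larger than the pseudo-word inventory (",
         length(words), ")", call. = FALSE)
  }
  words[seq_len(size)]
}

# Deterministic valence-word pools, morphologically distinct from the
# background inventory (different onset consonants and cluster codas).
sentiment_word_pools <- function() {
  cons <- c("r", "s", "t", "v", "w", "z")
  vow <- c("a", "e", "o", "u")
  base <- as.vector(outer(cons, vow, paste0))
  list(
    negative = as.vector(outer(base, c("rn", "rk"), paste0))[1:40],
    positive = paste0(base, "lm")[1:15]
  )
}

#' Synthetic-corpus generator configuration
#'
#' Defaults emulate the study corpus: 81 migraine and 40 cluster-headache
#' narratives; log-normal per-text token counts targeting medians (Q1–Q3)
#' of 474 (227–745) and 508 (198–794); roughly 20 tokens per sentence; a
#' sentence-theme mixture putting most mass on attack descriptions,
#' treatment, medical history and disease burden (comorbidities and
#' technical investigations are rare enough that their per-text median
#' proportion is 0); per-class age distributions of 43.1 (SD 12) and 48.9
#' (SD 14.2) years with 80% / 20% female; 90% of documents net-negative in
#' sentiment; and class-exclusive keyword vocabulary using the study's
#' reported key words so that keyness output is human-checkable. Nine
#' records (7 migraine, 2 cluster headache) carry no attack-description
#' sentences, reproducing the 121-to-112 reduction when that theme is
#' extracted.
#'
#' @param n_per_class Named counts of records per diagnosis.
#' @param shared_vocab_size Size of the class-shared background vocabulary.
#' @param class_keywords Named list of class-exclusive keyword vectors.
#' @param keyword_rate Per-token probability of emitting a class keyword.
#' @param label_token_rate Per-token probability of emitting a class-label
#'   mention (these are exactly the words the blocklist removes).
#' @param sentiment_token_rate Per-token probability of a valence word.
#' @param p_doc_negative Probability a document's injected valence words are
#'   negative (all valence words within one document share its sign, and at
#'   least one is always present, so the negative-document share is exactly
#'   Binomial(n, p_doc_negative)).
#' @param stopword_frac Share of background draws that are stop words.
#' @param length_model Per-class log-normal `c(meanlog, sdlog)` for tokens
#'   per text.
#' @param mean_sentence_tokens Mean word tokens per sentence.
#' @param theme_mix Sentence-theme probabilities (must include `none`,
#'   the unannotated share; one theme per sentence).
#' @param n_no_attack Per-class number of records generated without any
#'   attack-description sentence.
#' @param metadata_model Per-class list with `age_mean`, `age_sd`,
#'   `p_female`.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(
    n_per_class = c(migraine = 81L, cluster_headache = 40L),
    shared_vocab_size = 300L,
    class_keywords = list(
      migraine = c("hoofdpijn", "stress", "misselijkheid", "geluid", "vaak"),
      cluster_headache = c("oog", "pijn", "terug", "linker", "tanden")
    ),
    keyword_rate = 0.04,
    label_token_rate = 0.01,
    sentiment_token_rate = 0.05,
    p_doc_negative = 0.9,
    stopword_frac = 0.35,
    length_model = list(
      migraine = c(meanlog = log(474), sdlog = 0.88),
      cluster_headache = c(meanlog = log(508), sdlog = 1.03)
    ),
    mean_sentence_tokens = 20,
    theme_mix = c(attack_description = 0.30, treatment = 0.18,
                  medical_history = 0.12, burden_of_disease = 0.12,
                  triggers = 0.03, comorbidities = 0.01,
                  technical_investigations = 0.01, none = 0.23),
    n_no_attack = c(migraine = 7L, cluster_headache = 2L),
    metadata_model = list(
      migraine = list(age_mean = 43.1, age_sd = 12, p_female = 0.80),
      cluster_headache = list(age_mean = 48.9, age_sd = 14.2, p_female = 0.20)
    )) {
  rates <- c(keyword_rate, label_token_rate, sentiment_token_rate,
             p_doc_negative, stopword_frac)
  if (any(rates < 0 | rates > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (keyword_rate + label_token_rate + sentiment_token_rate > 1) {
    stop("keyword, label and sentiment emission rates must sum to at most 1",
         call. = FALSE)
  }
  if (any(n_per_class < 1L)) stop("n_per_class counts must be >= 1", call. = FALSE)
  if (!all(names(n_per_class) %in% diagnosis_labels())) {
    stop("n_per_class names must be diagnosis labels", call. = FALSE)
  }
  if (any(n_no_attack > n_per_class[names(n_no_attack)])) {
    stop("n_no_attack cannot exceed n_per_class", call. = FALSE)
  }
  bad_theme <- setdiff(names(theme_mix), c(theme_labels(), "none"))
  if (length(bad_theme)) {
    stop("unknown theme in theme_mix: ", bad_theme[1], call. = FALSE)
  }
  theme_mix <- theme_mix / sum(theme_mix)
  structure(list(
    n_per_class = n_per_class, shared_vocab_size = as.integer(shared_vocab_size),
    class_keywords = class_keywords, keyword_rate = keyword_rate,
    label_token_rate = label_token_rate,
    sentiment_token_rate = sentiment_token_rate,
    p_doc_negative = p_doc_negative, stopword_frac = stopword_frac,
    length_model = length_model, mean_sentence_tokens = mean_sentence_tokens,
    theme_mix = theme_mix, n_no_attack = n_no_attack,
    metadata_model = metadata_model
  ), class = "generator_config")
}

#' Generate the four-lexicon fixture cascade
#'
#' Four small synthetic valence lexicons on deliberately different native
#' scales (±1, ±2, integer ±5, ±3), with controlled overlaps: a handful of
#' words occur in the first and third lexicon with opposite signs so that
#' first-match-wins semantics are observable, and part of the negative pool
#' occurs in two lexicons with consistent sign. Deterministic — no
#' randomness.
#'
#' @param config A `generator_config` (reserved for future size knobs).
#' @return List of four `sentiment_lexicon`s in cascade order.
#' @export
generate_lexicon_fixtures <- function(config = generator_config()) {
  pools <- sentiment_word_pools()
  neg <- pools$negative
  pos <- pools$positive
  conflict <- c("wisselwoord", "dubbelwoord")
  pattern <- sentiment_lexicon(c(
    stats::setNames(-(0.4 + 0.05 * (0:9)), neg[1:10]),
    stats::setNames(c(0.5, 0.6, 0.7, 0.8), pos[1:4]),
    stats::setNames(c(0.4, 0.6), conflict),
    stats::setNames(rep_len(c(-0.3, 0.35), 12), paste0("patwoord", 1:12))
  ), name = "pattern_synthetic")
  inhouse <- sentiment_lexicon(c(
    stats::setNames(-(0.8 + 0.1 * (0:9)), neg[11:20]),
    stats::setNames(c(1.0, 1.4, 1.8), pos[5:7]),
    stats::setNames(rep_len(c(-0.9, 1.1), 7), paste0("huiswoord", 1:7))
  ), name = "inhouse_synthetic")
  duoman <- sentiment_lexicon(c(
    stats::setNames(-((0:9) %% 5 + 1), neg[21:30]),
    stats::setNames(rep(-3, 5), neg[1:5]),      # consistent-sign overlap
    stats::setNames(c(-4, -5), conflict),       # sign conflict vs. pattern
    stats::setNames(c(2, 3, 4, 5), pos[8:11]),
    stats::setNames(rep_len(c(-2, 2), 9), paste0("duowoord", 1:9))
  ), name = "duoman_synthetic")
  nrc <- sentiment_lexicon(c(
    stats::setNames(-(0.9 + 0.2 * (0:9)), neg[31:40]),
    stats::setNames(c(1, 1.5, 2, 2.5), pos[12:15]),
    stats::setNames(rep_len(c(-1.2, 1.3), 11), paste0("nrcwoord", 1:11))
  ), name = "nrc_synthetic")
  list(pattern, inhouse, duoman, nrc)
}

label_mention_words <- function() {
  list(migraine = c("migraine", "medicatie"),
       cluster_headache = c("clusterhoofdpijn", "medicatie"))
}

#' Generate a labelled synthetic narrative corpus with ground truth
#'
#' Emits a corpus of synthetic token-stream narratives (pronounceable
#' pseudo-words plus the configured class-exclusive keywords, class-label
#' mentions and valence words), one theme per sentence, together with the
#' stand-off theme annotations, the fixture lexicon cascade and a recountable
#' ground-truth table. Texts are token streams, not fluent Dutch — every
#' downstream consumer is token-based, so linguistic realism is out of
#' scope. Deterministic given `seed`.
#'
#' @param config A `generator_config`.
#' @param seed Integer seed for all draws.
#' @return List with `corpus` (a `narrative_corpus`), `annotations` (named
#'   list of `theme_annotation`s), `lexicons` (four `sentiment_lexicon`s),
#'   `cascade` (their `lexicon_cascade`) and `truth` (tibble with per-record
#'   drawn polarity, injected keyword/valence counts, net injected valence
#'   and theme layout).
#' @export
generate_corpus <- function(config = generator_config(), seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  lexicons <- generate_lexicon_fixtures(config)
  cascade <- lexicon_cascade(lexicons)
  pools <- sentiment_word_pools()
  stopwords <- default_stopwords()$words
  labels <- label_mention_words()
  reserved <- c(stopwords, unlist(config$class_keywords), unlist(labels),
                pools$negative, pools$positive, names(cascade$map))
  content <- background_vocab(config$shared_vocab_size, reserved = reserved)
  bg_words <- c(stopwords, content)
  bg_prob <- numeric(length(bg_words))
  bg_prob[seq_along(stopwords)] <-
    config$stopword_frac / sum(1 / seq_along(stopwords)) / seq_along(stopwords)
  bg_prob[seq_along(content) + length(stopwords)] <-
    (1 - config$stopword_frac) / sum(1 / seq_along(content)) / seq_along(content)

  rows <- list(); anns <- list(); truth_rows <- list()
  withr::local_seed(seed)
  for (cls in names(config$n_per_class)) {
    n_cls <- config$n_per_class[[cls]]
    kw <- config$class_keywords[[cls]]
    lw <- labels[[cls]]
    meta <- config$metadata_model[[cls]]
    lm <- config$length_model[[cls]]
    no_attack <- sample.int(n_cls, config$n_no_attack[[cls]] %||% 0L)
    prefix <- if (cls == "migraine") "mig" else "clu"
    for (i in seq_len(n_cls)) {
      rid <- sprintf("%s_%03d", prefix, i)
      age <- max(18L, min(90L, as.integer(round(
        stats::rnorm(1, meta$age_mean, meta$age_sd)))))
      sex <- if (stats::runif(1) < meta$p_female) "female" else "male"
      sign <- if (stats::runif(1) < config$p_doc_negative) -1 else 1
      target_tokens <- max(30, round(stats::rlnorm(1, lm[["meanlog"]],
                                                   lm[["sdlog"]])))
      mix <- config$theme_mix
      if (i %in% no_attack) {
        mix[["none"]] <- mix[["none"]] + mix[["attack_description"]]
        mix[["attack_description"]] <- 0
      }
      sent_tokens <- list(); sent_theme <- character(0)
      kw_counts <- stats::setNames(integer(length(kw)), kw)
      sentiment_words <- character(0)
      n_tok <- 0L
      spool <- if (sign < 0) pools$negative else pools$positive
      while (n_tok < target_tokens) {
        len <- 3L + stats::rpois(1, max(0, config$mean_sentence_tokens - 3))
        u <- stats::runif(len)
        cat_kw <- u < config$keyword_rate
        cat_sent <- !cat_kw & u < config$keyword_rate + config$sentiment_token_rate
        cat_lab <- !cat_kw & !cat_sent &
          u < config$keyword_rate + config$sentiment_token_rate +
            config$label_token_rate
        toks <- sample(bg_words, len, replace = TRUE, prob = bg_prob)
        if (any(cat_kw)) toks[cat_kw] <- sample(kw, sum(cat_kw), replace = TRUE)
        if (any(cat_sent)) {
          sw <- sample(spool, sum(cat_sent), replace = TRUE)
          toks[cat_sent] <- sw
          sentiment_words <- c(sentiment_words, sw)
        }
        if (any(cat_lab)) toks[cat_lab] <- sample(lw, sum(cat_lab), replace = TRUE)
        if (any(cat_kw)) {
          tk <- table(toks[cat_kw])
          kw_counts[names(tk)] <- kw_counts[names(tk)] + as.integer(tk)
        }
        sent_tokens[[length(sent_tokens) + 1L]] <- toks
        sent_theme <- c(sent_theme,
                        sample(names(mix), 1L, prob = mix))
        n_tok <- n_tok + len
      }
      if (!(i %in% no_attack) && !any(sent_theme == "attack_description")) {
        # every record outside the designated attack-free set must carry the
        # theme, so the attack-description extraction is a fixed reduction
        sent_theme[sample.int(length(sent_theme), 1L)] <- "attack_description"
      }
      if (!length(sentiment_words)) {
        # guarantee at least one valence carrier so polarity is well defined
        s_idx <- sample.int(length(sent_tokens), 1L)
        toks <- sent_tokens[[s_idx]]
        bg_pos <- which(!toks %in% c(kw, lw))
        pos_idx <- if (length(bg_pos)) sample(bg_pos, 1L) else 1L
        sw <- sample(spool, 1L)
        toks[pos_idx] <- sw
        sent_tokens[[s_idx]] <- toks
        sentiment_words <- sw
      }
      net_valence <- sum(cascade_lookup(sentiment_words, cascade))
      text <- paste(vapply(sent_tokens, function(s)
        paste0(paste(s, collapse = " "), "."), character(1)), collapse = " ")
      asg <- as.list(sent_theme)
      names(asg) <- as.character(seq_along(sent_theme))
      asg <- asg[sent_theme != "none"]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        record_id = rid, text = text, diagnosis = cls, age = age, sex = sex)
      anns[[rid]] <- theme_annotation(rid, asg)
      truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
        record_id = rid, diagnosis = cls, age = age, sex = sex,
        doc_sign = sign, n_sentences = length(sent_tokens),
        n_annotated = sum(sent_theme != "none"),
        has_attack = any(sent_theme == "attack_description"),
        n_sentiment_tokens = length(sentiment_words),
        net_valence = net_valence,
        keyword_counts = list(kw_counts)
      )
    }
  }
  list(corpus = as_corpus(dplyr::bind_rows(rows)),
       annotations = anns,
       lexicons = lexicons,
       cascade = cascade,
       truth = dplyr::bind_rows(truth_rows))
}

#' Audit a generated corpus against its ground truth
#'
#' Re-derives every stated ground-truth quantity from the emitted text with
#' the package's own pipeline — sentence count via the splitter, keyword
#' occurrences via the tokenizer, net valence via the cascade, annotated
#' sentence count via the annotation set — and confirms equality. Any
#' mismatch is a generator bug (or evidence of tampering with the text).
#'
#' @param gen Result of [generate_corpus()].
#' @return List with `ok` (logical) and `issues` (tibble `record_id`,
#'   `issue`; empty when clean).
#' @export
verify_ground_truth <- function(gen) {
  issues <- list()
  note <- function(rid, what) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(record_id = rid,
                                                     issue = what)
  }
  for (i in seq_len(nrow(gen$corpus))) {
    rid <- gen$corpus$record_id[i]
    tr <- gen$truth[gen$truth$record_id == rid, ]
    doc <- tokenize_document(gen$corpus$text[i], record_id = rid)
    if (length(doc$sentences) != tr$n_sentences) {
      note(rid, "sentence count mismatch")
    }
    kw_truth <- tr$keyword_counts[[1]]
    toks <- doc_tokens(doc)
    kw_seen <- vapply(names(kw_truth), function(w) sum(toks == w), integer(1))
    if (!identical(unname(kw_seen), unname(as.integer(kw_truth)))) {
      note(rid, "keyword count mismatch")
    }
    sc <- suppressWarnings(score_document(doc, gen$cascade))
    if (abs(sc$score - tr$net_valence) > 1e-9) {
      note(rid, "net valence mismatch")
    }
    ann <- gen$annotations[[rid]]
    if (length(ann$assignments) != tr$n_annotated) {
      note(rid, "annotated sentence count mismatch")
    }
  }
  issues <- if (length(issues)) dplyr::bind_rows(issues) else {
    tibble::tibble(record_id = character(0), issue = character(0))
  }
  list(ok = nrow(issues) == 0L, issues = issues)
}
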