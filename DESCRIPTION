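Package: headachetext
Title: Text Mining and Classification of Self-Reported Headache Narratives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing free-text narratives written by patients with
    primary headache disorders (migraine versus cluster headache): corpus
    statistics on tokens, types and sentences; chi-square keyness analysis of
    class-distinctive vocabulary; sentence-level thematic proportions from
    stand-off annotations; sentiment scoring through an ordered cascade of
    valence lexicons; and binary diagnosis classification from word and
    character n-gram features with naive Bayes, linear support vector machine
    and logistic regression under nested stratified cross-validation and
    leave-one-out evaluation. Includes a seeded synthetic-narrative generator
    with recountable ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    e1071,
    glmnet,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
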