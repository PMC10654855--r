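test_that("preprocessing replaces digits, newlines and underscores with spaces", {
  expect_identical(preprocessText("copd_gold2\nok"), "copd gold  ok")
  expect_identical(preprocessText(""), "")
  s <- "geen afwijkingen gezien vandaag"
  expect_identical(preprocessText(s), s)
  expect_identical(preprocessText("a1b2_c\n\nd"), "a b  c  d")
})

test_that("tokenization splits at spaces and punctuation and lowercases", {
  expect_identical(tokenizeText("pijn, op de Borst."), c("pijn", "op", "de", "borst"))
  expect_identical(tokenizeText("!!!"), character(0))
  # reference splitter oracle on random ASCII strings
  withr::with_seed(77, {
    alphabet <- c(letters, LETTERS, 0:9, ",", ".", ";", "!", "-", "(", ")", " ")
    for (i in 1:25) {
      s <- paste(sample(alphabet, 60, replace = TRUE), collapse = "")
      want <- regmatches(tolower(s), gregexpr("[[:alnum:]]+", tolower(s)))[[1]]
      expect_identical(tokenizeText(s), want)
    }
  })
})

test_that("documents aggregate exactly the notes in the 365-day window", {
  ds <- toyDataset()
  ch <- buildCohort(ds, toyTask())
  docs <- buildDocuments(ch, ds)
  # p1 index 2018-04-01: n1 (2018-03-01) in window, n2 (2017-01-15) outside
  expect_identical(docs$n_notes, 1L)
  expect_match(docs$text, "Koorts en hoest")
  expect_no_match(docs$text, "diabetes")
  # with a wider window both notes are concatenated
  docs2 <- buildDocuments(ch, ds, windowDays = 500)
  expect_identical(docs2$n_notes, 2L)
  expect_match(docs2$text, "diabetes")
  expect_match(docs2$text, "Koorts")
})

test_that("documents equal a brute-force per-observation filter", {
  task <- defaultTasks()$asthma
  ds <- simulateEHR(systemProfile("A", n_patients = 50, notes_per_obs_median = 5,
                                  words_per_note_median = 6),
                    defaultSignal("asthma"), task, seed = 20)
  ch <- buildCohort(ds, task)
  docs <- buildDocuments(ch, ds)
  nt <- notes(ds)
  for (o in sample(seq_len(nrow(ch)), 10)) {
    rows <- which(nt$person_id == ch$person_id[o] &
                    nt$note_date >= ch$index_date[o] - 365 &
                    nt$note_date <= ch$index_date[o] - 1)
    rows <- rows[order(nt$note_date[rows], nt$note_id[rows])]
    expect_identical(docs$text[o], paste(nt$text[rows], collapse = "\n"))
  }
})

test_that("vocabulary pruning applies the document-frequency bounds strictly", {
  # N = 10: a term in 9 docs (90% > 80%) is removed, in 8 docs (= 0.8N) kept,
  # in 5 docs kept
  docs <- c(paste("alfa bravo", c("hoog", "hoog", "hoog", "hoog", "hoog",
                                  "hoog", "hoog", "hoog", "hoog", "laag")),
            NULL)
  docs <- sprintf("%s %s", docs, c(rep("negen", 9), "x"))
  docs <- sprintf("%s %s", docs, c(rep("acht", 8), "y", "z"))
  pl <- fitTextPipeline(docs, maxDf = 0.8, minDf = 0.001)
  expect_false("negen" %in% pl@vocabulary) # df 9 > 0.8 * 10
  expect_true("acht" %in% pl@vocabulary)   # df 8 = 0.8 * 10, boundary kept
  expect_false("alfa" %in% pl@vocabulary)  # df 10
  expect_true("laag" %in% pl@vocabulary)   # df 1 >= 0.001 * 10
  # at N < 1/minDf the lower bound removes nothing
  expect_true(all(c("x", "y", "z") %in% pl@vocabulary))
})

test_that("vocabulary fitting equals a brute-force df filter and ignores document order", {
  withr::with_seed(31, {
    lex <- paste0("w", rep(letters[1:8], 5), rep(letters[1:5], each = 8))
    docs <- vapply(1:200, function(i) {
      paste(sample(lex, sample(3:12, 1), replace = TRUE), collapse = " ")
    }, character(1))
  })
  maxDf <- 0.6; minDf <- 0.02
  pl <- fitTextPipeline(docs, maxDf = maxDf, minDf = minDf)
  # independent count-and-filter oracle
  toks <- lapply(strsplit(docs, " "), unique)
  df <- table(unlist(toks))
  want <- sort(names(df)[df >= minDf * 200 & df <= maxDf * 200])
  expect_identical(pl@vocabulary, want)
  expect_identical(as.integer(df[pl@vocabulary]), pl@df)
  pl2 <- fitTextPipeline(rev(docs), maxDf = maxDf, minDf = minDf)
  expect_identical(pl2@vocabulary, pl@vocabulary)
  expect_identical(pl2@df, pl@df)
  expect_error(fitTextPipeline(c("", "")), "fit error")
})

test_that("binary vectorization is the membership indicator over the vocabulary", {
  docs <- c("aap noot mies aap aap", "noot wim", "zus jet", "")
  pl <- fitTextPipeline(docs)
  tb <- vectorizeBinary(docs, pl)
  # term occurring 7 times is still 1; empty document gives an all-zero row
  expect_equal(as.numeric(featureValues(tb)[1, "Tterm:aap"]), 1)
  expect_true(all(featureValues(tb)[4, ] == 0))
  expect_true(all(featureValues(tb)@x %in% c(0, 1)))
  # brute-force membership oracle
  for (d in seq_along(docs)) {
    for (v in pl@vocabulary) {
      expect_equal(as.numeric(featureValues(tb)[d, paste0("Tterm:", v)]),
                   as.numeric(v %in% tokenizeText(preprocessText(docs[d]))))
    }
  }
})

test_that("tf-idf equals tf x ln(N/df) with frozen fitting-corpus statistics", {
  docs <- c("kat kat hond", "hond vis", "vis kat", "vogel vogel vogel vogel")
  pl <- fitTextPipeline(docs, maxDf = 1, minDf = 0)
  tf <- vectorizeTfidf(docs, pl)
  # hand-computed: tf = 2, N = 4, df("kat") = 2 -> 2 * ln(4/2)
  expect_equal(as.numeric(featureValues(tf)[1, "Ttfidf:kat"]), 2 * log(4 / 2))
  # vogel: tf = 4, df = 1 -> 4 * ln 4
  expect_equal(as.numeric(featureValues(tf)[4, "Ttfidf:vogel"]), 4 * log(4))
  # formula oracle over the whole matrix
  N <- 4
  for (d in seq_along(docs)) {
    toks <- tokenizeText(preprocessText(docs[d]))
    for (v in pl@vocabulary) {
      want <- sum(toks == v) * log(N / pl@df[match(v, pl@vocabulary)])
      expect_equal(as.numeric(featureValues(tf)[d, paste0("Ttfidf:", v)]), want)
    }
  }
  # a term present in every fitting document scores 0 everywhere,
  # also on held-out documents
  docs2 <- c("kat hond vis x", "kat hond vis y", "kat hond vis z")
  pl2 <- fitTextPipeline(docs2, maxDf = 1, minDf = 0)
  tf2 <- vectorizeTfidf(c("kat kat kat", "hond kat"), pl2)
  expect_true(all(featureValues(tf2)[, "Ttfidf:kat"] == 0))
  # tfidf support equals the binary support wherever idf > 0
  tb2 <- vectorizeBinary(c("kat kat kat", "hond kat"), pl2)
  nzIdf <- pl2@vocabulary[log(pl2@nDocs / pl2@df) > 0]
  for (v in nzIdf) {
    expect_identical(featureValues(tf2)[, paste0("Ttfidf:", v)] != 0,
                     featureValues(tb2)[, paste0("Tterm:", v)] != 0)
  }
})

test_that("a spec with tf = 2, N = 4, df = 1 scores 2 ln 4", {
  pl <- fitTextPipeline(c("zeldzaam zeldzaam iets", "iets", "iets x", "iets y"),
                        maxDf = 1, minDf = 0)
  tf <- vectorizeTfidf(c("zeldzaam zeldzaam"), pl)
  expect_equal(as.numeric(featureValues(tf)[1, "Ttfidf:zeldzaam"]),
               2 * log(4), tolerance = 1e-12)
  expect_equal(2 * log(4), 2.7726, tolerance = 1e-4)
})

test_that("pipeline config round-trips and reproduces identical matrices", {
  task <- defaultTasks()$asthma
  ds <- simulateEHR(systemProfile("A", n_patients = 40, notes_per_obs_median = 4,
                                  words_per_note_median = 8),
                    defaultSignal("asthma"), task, seed = 25)
  ch <- buildCohort(ds, task)
  docs <- buildDocuments(ch, ds)
  pl <- fitTextPipeline(docs, seed = 25)
  path <- file.path(withr::local_tempdir(), "pipeline.json")
  saveTextPipeline(pl, path)
  pl2 <- loadTextPipeline(path)
  expect_identical(pl2@vocabulary, pl@vocabulary)
  expect_identical(pl2@df, pl@df)
  m1 <- vectorizeTfidf(docs, pl)
  m2 <- vectorizeTfidf(docs, pl2)
  expect_identical(featureValues(m1)@x, featureValues(m2)@x)
  b1 <- vectorizeBinary(docs, pl)
  b2 <- vectorizeBinary(docs, pl2)
  expect_identical(featureValues(b1)@x, featureValues(b2)@x)
})

test_that("a tampered pipeline file raises an integrity warning", {
  pl <- fitTextPipeline(c("aap noot", "noot mies", "aap mies"))
  path <- file.path(withr::local_tempdir(), "pipeline.json")
  saveTextPipeline(pl, path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  j$vocabulary[1] <- "smokkel"
  jsonlite::write_json(j, path, auto_unbox = TRUE)
  expect_warning(loadTextPipeline(path), "integrity warning")
})

test_that("a pipeline fitted on one system transfers only its own vocabulary", {
  task <- defaultTasks()$asthma
  pair <- simulateSystemPair(
    systemProfile("A", n_patients = 60, notes_per_obs_median = 4,
                  words_per_note_median = 8),
    systemProfile("B", n_patients = 60, notes_per_obs_median = 4,
                  words_per_note_median = 8, vocab_shift = 0.4),
    defaultSignal("asthma"), task, seed = 33)
  chA <- buildCohort(pair$A, task)
  chB <- buildCohort(pair$B, task)
  pl <- fitTextPipeline(buildDocuments(chA, pair$A))
  mB <- vectorizeBinary(buildDocuments(chB, pair$B), pl)
  # exactly the training feature space, nothing from B's novel vocabulary
  expect_identical(featureInfo(mB)$feature_id, paste0("Tterm:", pl@vocabulary))
  vocabB <- unique(unlist(tokenizeText(preprocessText(notes(pair$B)$text))))
  novel <- setdiff(vocabB, pl@vocabulary)
  expect_true(length(novel) > 0)
  expect_true(!any(paste0("Tterm:", novel) %in% featureInfo(mB)$feature_id))
})
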