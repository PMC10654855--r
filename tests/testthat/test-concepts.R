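lex <- defaultLexicon()
rules <- defaultContextRules()

test_that("sentence splitting handles terminal punctuation, newlines and degenerate text", {
  expect_length(splitSentences("Koorts. Geen hoest."), 2L)
  expect_length(splitSentences("een zin zonder leesteken"), 1L)
  # GP shorthand lines split at newlines
  expect_identical(splitSentences("rr 140/90\nmedicatie gestart\ncontrole"),
                   c("rr 140/90", "medicatie gestart", "controle"))
  expect_length(splitSentences(""), 0L)
  # digits are preserved on this path
  expect_match(splitSentences("glucose 12.")[1], "12")
})

test_that("concept matching is leftmost-longest, case-insensitive and non-overlapping", {
  m <- matchConcepts("Diabetes Mellitus type onbekend", lex)
  expect_identical(m$concept_id, "CPT0016") # 'diabetes mellitus', not 'diabetes'
  expect_identical(c(m$start, m$end), c(0L, 2L))
  m2 <- matchConcepts("diabetes mellitus type 2 vastgesteld", lex)
  expect_identical(m2$concept_id, "CPT0017") # longest entry wins
  expect_identical(nrow(matchConcepts("geheel onopvallend consult", lex)), 0L)
  # matched spans never overlap
  m3 <- matchConcepts("pijn op de borst en rugpijn en hoofdpijn", lex)
  expect_identical(m3$concept_id, c("CPT0025", "CPT0014", "CPT0015"))
  expect_true(all(m3$start[-1] >= head(m3$end, -1)))
})

test_that("concept matching equals a brute-force scan with the same tie-break", {
  phrases <- strsplit(lex$term, " ")
  bruteMatch <- function(tokens) {
    out <- list(); i <- 1L
    while (i <= length(tokens)) {
      cands <- which(vapply(phrases, function(p) {
        length(p) <= length(tokens) - i + 1L &&
          all(tokens[i:(i + length(p) - 1L)] == p)
      }, logical(1)))
      if (length(cands)) {
        best <- cands[which.max(lengths(phrases)[cands])]
        out[[length(out) + 1L]] <- data.frame(
          concept_id = lex$concept_id[best], start = i - 1L,
          end = i - 1L + length(phrases[[best]]))
        i <- i + length(phrases[[best]])
      } else i <- i + 1L
    }
    do.call(rbind, c(out, list(data.frame(concept_id = character(),
                                          start = integer(), end = integer()))))
  }
  filler <- c("de", "een", "met", "zonder", "controle", "vandaag", "klachten")
  seeds <- c("hoest", "koorts", "diabetes", "mellitus", "type", "2",
             "pijn", "op", "borst", "rugpijn")
  withr::with_seed(55, {
    for (i in 1:40) {
      tokens <- sample(c(filler, seeds), sample(4:12, 1), replace = TRUE)
      got <- matchConcepts(tokens, lex)
      want <- bruteMatch(tokens)
      expect_equal(got[c("concept_id", "start", "end")], want,
                   ignore_attr = TRUE)
    }
  })
})

test_that("context triggers set modifier flags with direction and termination", {
  s <- "geen aanwijzing voor pneumonie"
  m <- applyContext(s, matchConcepts(s, lex), rules)
  expect_true(m$negated)
  # concept before a forward-only trigger keeps its flags
  s2 <- "hoest maar geen koorts"
  m2 <- applyContext(s2, matchConcepts(s2, lex), rules)
  expect_false(m2$negated[m2$concept_id == "CPT0010"])
  expect_true(m2$negated[m2$concept_id == "CPT0011"])
  # backward trigger
  s3 <- "pneumonie uitgesloten"
  m3 <- applyContext(s3, matchConcepts(s3, lex), rules)
  expect_true(m3$negated)
  # terminator truncates the scope
  s4 <- "geen koorts maar wel hoest"
  m4 <- applyContext(s4, matchConcepts(s4, lex), rules)
  expect_true(m4$negated[m4$concept_id == "CPT0011"])
  expect_false(m4$negated[m4$concept_id == "CPT0010"])
  # beyond the 10-token window the flag is not set
  s5 <- paste("geen", paste(rep("x", 10), collapse = " "), "koorts")
  m5 <- applyContext(s5, matchConcepts(s5, lex), rules)
  expect_false(m5$negated)
  # multiple categories may co-occur
  s6 <- "geen eerder doorgemaakte pneumonie"
  m6 <- applyContext(s6, matchConcepts(s6, lex), rules)
  expect_true(m6$negated && m6$historical)
})

test_that("a concept overlapping a trigger phrase wins over the trigger", {
  lx <- structure(data.frame(term = c("niet aangeboren hersenletsel", "hoest"),
                             concept_id = c("X1", "X2"),
                             preferred_name = c("nah", "hoest")),
                  class = c("Lexicon", "data.frame"))
  s <- "niet aangeboren hersenletsel en hoest"
  m <- matchConcepts(s, lx)
  expect_identical(m$concept_id, c("X1", "X2"))
  m <- applyContext(s, m, rules)
  # 'niet' lies inside the matched concept span, so no negation fires
  expect_false(any(m$negated))
})

test_that("the rule engine equals a brute-force scope interpreter on random sentences", {
  concepts <- c("hoest", "koorts", "pneumonie", "rugpijn", "astma")
  triggers <- c("geen", "niet", "uitgesloten", "mogelijk", "eerder", "moeder",
                "geen aanwijzing voor", "status na", "risico op")
  fillers <- c("de", "en", "bij", "controle", "vandaag", "gister", "verder")
  terminators <- c("maar", "echter", "wel")
  withr::with_seed(101, {
    nChecked <- 0L
    for (i in 1:220) {
      tokens <- unlist(strsplit(sample(c(concepts, triggers, fillers, terminators),
                                       sample(3:12, 1), replace = TRUE), " "))
      m0 <- matchConcepts(tokens, lex)
      got <- applyContext(tokens, m0, rules)
      want <- bruteForceContext(tokens, m0, rules)
      expect_identical(got, want)
      nChecked <- nChecked + nrow(m0)
    }
    expect_gt(nChecked, 200)
  })
})

test_that("an empty rule table leaves all flags false and Tcon unfiltered", {
  s <- "geen koorts en geen hoest"
  m <- applyContext(s, matchConcepts(s, lex), rules[0, ])
  expect_false(any(m$negated | m$hypothetical | m$historical | m$experiencer_other))
  ds <- toyDataset()
  ch <- buildCohort(ds, toyTask())
  tcAll <- conceptFeatures(ch, ds, lex, rules[0, ])
  # unfiltered presence: koorts, hoest, pneumonie (negated but kept)
  expect_setequal(featureInfo(tcAll)$feature_id,
                  paste0("Tcon:", c("CPT0010", "CPT0011", "CPT0013")))
})

test_that("negated concepts are excluded from Tcon under the default filter", {
  ds <- toyDataset()
  ch <- buildCohort(ds, toyTask())
  tc <- conceptFeatures(ch, ds)
  ids <- featureInfo(tc)$feature_id
  expect_true(all(c("Tcon:CPT0010", "Tcon:CPT0011") %in% ids))
  expect_false("Tcon:CPT0013" %in% ids) # 'geen aanwijzing voor pneumonie'
  # same concept mentioned several times still yields a binary 1
  expect_true(all(featureValues(tc)@x == 1))
})

test_that("mention extraction is deterministic and lexicon growth is monotone", {
  txt <- "Moeder met diabetes mellitus.\nZelf geen klachten, wel hoest."
  m1 <- extractMentions(txt, lex, rules)
  m2 <- extractMentions(txt, lex, rules)
  expect_identical(m1, m2)
  expect_true(m1$experiencer_other[m1$concept_id == "CPT0016"])
  lx2 <- structure(rbind(lex, data.frame(term = "klachten", concept_id = "NEW1",
                                         preferred_name = "klacht")),
                   class = c("Lexicon", "data.frame"))
  m3 <- extractMentions(txt, lx2, rules)
  # every previous non-overlapped match is still present
  key <- function(m) paste(m$sentence, m$concept_id, m$start, m$end)
  expect_true(all(key(m1) %in% key(m3)))
  expect_true("NEW1" %in% m3$concept_id)
})
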