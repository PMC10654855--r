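#' @include AllClasses.R utils.R text.R
NULL

# ---- resources -------------------------------------------------------------

#' Load a concept lexicon
#'
#' A lexicon maps surface terms (possibly multi-word) to concept ids. Lookup
#' is case-insensitive and multi-word terms are matched as contiguous token
#' sequences.
#'
#' @param path CSV with columns \code{term}, \code{concept_id},
#'   \code{preferred_name}.
#' @return a \code{Lexicon} data.frame (lowercased terms, tokenized
#'   internally on use).
#' @export
readLexicon <- function(path) {
  lx <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("term", "concept_id", "preferred_name")
  miss <- setdiff(need, names(lx))
  if (length(miss)) {
    .stopf("schema error: lexicon lacks column(s): %s", paste(miss, collapse = ", "))
  }
  if (any(!nzchar(trimws(lx$term)))) .stopf("schema error: empty lexicon term")
  lx$term <- tolower(trimws(lx$term))
  structure(lx, class = c("Lexicon", "data.frame"))
}

#' Bundled synthetic Dutch toy lexicon
#'
#' A small stand-in vocabulary of common Dutch GP terms (licensed Dutch
#' SNOMED/UMLS distributions cannot be bundled); intended for testing and
#' synthetic benchmarks and fully user-replaceable via
#' \code{\link{readLexicon}}.
#'
#' @return a \code{Lexicon} data.frame.
#' @export
defaultLexicon <- function() {
  readLexicon(system.file("extdata", "lexicon_nl_synthetic.csv",
                          package = "notepredict", mustWork = TRUE))
}

#' Load a ConText trigger rule table
#'
#' Each rule is a trigger phrase with a modifier category (negated,
#' hypothetical, historical, experiencer_other) and a scope direction
#' (forward, backward, bidirectional), or a scope terminator (a phrase that
#' truncates any open trigger scope; terminators carry no category).
#'
#' @param path CSV with columns \code{trigger}, \code{category},
#'   \code{direction}, \code{terminator}.
#' @return a \code{ContextRules} data.frame.
#' @export
readContextRules <- function(path) {
  rl <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("trigger", "category", "direction", "terminator")
  miss <- setdiff(need, names(rl))
  if (length(miss)) {
    .stopf("schema error: rule table lacks column(s): %s", paste(miss, collapse = ", "))
  }
  if (any(!nzchar(trimws(rl$trigger)))) .stopf("schema error: empty trigger")
  rl$trigger <- tolower(trimws(rl$trigger))
  rl$terminator <- as.logical(rl$terminator)
  bad <- !rl$terminator & !rl$category %in%
    c("negated", "hypothetical", "historical", "experiencer_other")
  if (any(bad)) {
    .stopf("schema error: unknown category '%s'", rl$category[which(bad)[1L]])
  }
  if (any(rl$terminator & nzchar(trimws(replace(rl$category, is.na(rl$category), ""))))) {
    .stopf("schema error: terminators must carry no category")
  }
  structure(rl, class = c("ContextRules", "data.frame"))
}

#' Bundled Dutch ConText-style trigger table
#'
#' About forty Dutch trigger phrases across the four modifier categories
#' plus scope terminators, following the classic ConText defaults
#' (same-sentence directional scope of at most 10 tokens, truncated at
#' terminators). User-replaceable via \code{\link{readContextRules}}.
#'
#' @return a \code{ContextRules} data.frame.
#' @export
defaultContextRules <- function() {
  readContextRules(system.file("extdata", "context_rules_nl.csv",
                               package = "notepredict", mustWork = TRUE))
}

# ---- sentence splitting and matching --------------------------------------

#' Split raw note text into sentences
#'
#' Splits at terminal punctuation (., !, ?) followed by whitespace and
#' additionally at newlines, because GP notes are line-oriented shorthand.
#' Works on the raw text (digits preserved); returns trimmed non-empty
#' sentences in order.
#'
#' @param text a single character string.
#' @return character vector of sentences.
#' @export
splitSentences <- function(text) {
  s <- strsplit(text, "(?<=[.!?])[[:space:]]+|[[:space:]]*\n[[:space:]]*",
                perl = TRUE)[[1L]]
  s <- trimws(s)
  s[nzchar(s)]
}

# tokenization used by the concept path: lowercase, split at any
# non-alphanumeric character, digits preserved
.conceptTokens <- function(sentence) {
  p <- strsplit(tolower(sentence), "[^\\p{L}\\p{N}]+", perl = TRUE)[[1L]]
  p[nzchar(p)]
}

# leftmost-longest non-overlapping phrase matching over a token sequence.
# phrases: list of token vectors; returns data.frame(item, start, end)
# with 0-based half-open spans. blocked: logical per token, positions that
# may not be part of a match.
.matchPhrases <- function(tokens, phrases, blocked = NULL) {
  n <- length(tokens)
  if (is.null(blocked)) blocked <- logical(n)
  lens <- vapply(phrases, length, integer(1))
  firsts <- vapply(phrases, function(p) p[1L], character(1))
  item <- integer(0); start <- integer(0); end <- integer(0)
  i <- 1L
  while (i <= n) {
    if (blocked[i]) { i <- i + 1L; next }
    cand <- which(firsts == tokens[i])
    if (length(cand)) {
      cand <- cand[order(-lens[cand])] # longest first
      hit <- 0L
      for (ci in cand) {
        L <- lens[ci]
        if (i + L - 1L <= n && !any(blocked[i:(i + L - 1L)]) &&
            identical(tokens[i:(i + L - 1L)], phrases[[ci]])) {
          hit <- ci
          break
        }
      }
      if (hit) {
        item <- c(item, hit)
        start <- c(start, i - 1L)
        end <- c(end, i - 1L + lens[hit])
        i <- i + lens[hit]
        next
      }
    }
    i <- i + 1L
  }
  data.frame(item = item, start = start, end = end)
}

#' Match lexicon concepts in one sentence
#'
#' Case-insensitive, leftmost-longest, non-overlapping dictionary matching
#' over the sentence's token sequence; multi-word terms must appear as
#' contiguous tokens. Token spans are 0-based and half-open.
#'
#' @param sentence a character string (tokenized internally) or a character
#'   vector of tokens.
#' @param lexicon a \code{Lexicon} from \code{\link{readLexicon}}.
#' @return data.frame of mentions: \code{concept_id}, \code{term},
#'   \code{start}, \code{end}, and the four modifier flags initialized to
#'   FALSE.
#' @export
matchConcepts <- function(sentence, lexicon) {
  tokens <- if (length(sentence) == 1L) .conceptTokens(sentence) else tolower(sentence)
  phrases <- strsplit(lexicon$term, "[^\\p{L}\\p{N}]+", perl = TRUE)
  m <- .matchPhrases(tokens, phrases)
  flags <- logical(nrow(m))
  data.frame(concept_id = lexicon$concept_id[m$item],
             term = lexicon$term[m$item],
             start = m$start, end = m$end,
             negated = flags, hypothetical = flags, historical = flags,
             experiencer_other = flags, stringsAsFactors = FALSE)
}

#' Apply ConText trigger rules to concept mentions
#'
#' A mention inside a trigger's scope receives that trigger's modifier flag.
#' The scope runs from the trigger towards the sentence boundary in the
#' trigger's direction (both ways for bidirectional triggers), truncated at
#' the first scope terminator and at a window of \code{window} tokens.
#' Trigger phrases whose span overlaps a concept mention are ignored (the
#' concept wins). Multiple categories may accumulate on one mention.
#'
#' @param sentence a character string or token vector (must be the sentence
#'   the mentions came from).
#' @param mentions data.frame from \code{\link{matchConcepts}}.
#' @param rules a \code{ContextRules} table.
#' @param window maximum scope length in tokens (default 10).
#' @return the mentions data.frame with modifier flags set.
#' @export
applyContext <- function(sentence, mentions, rules, window = 10) {
  tokens <- if (length(sentence) == 1L) .conceptTokens(sentence) else tolower(sentence)
  n <- length(tokens)
  if (!nrow(mentions) || !nrow(rules)) return(mentions)
  blocked <- logical(n)
  for (k in seq_len(nrow(mentions))) {
    if (mentions$end[k] > mentions$start[k]) {
      blocked[(mentions$start[k] + 1L):mentions$end[k]] <- TRUE
    }
  }
  phrases <- strsplit(rules$trigger, "[^\\p{L}\\p{N}]+", perl = TRUE)
  occ <- .matchPhrases(tokens, phrases, blocked = blocked)
  if (!nrow(occ)) return(mentions)
  isTerm <- rules$terminator[occ$item]
  termStart <- occ$start[isTerm]
  termEnd <- occ$end[isTerm]
  for (t in which(!isTerm)) {
    cat_ <- rules$category[occ$item[t]]
    dir_ <- rules$direction[occ$item[t]]
    scopes <- list()
    if (dir_ %in% c("forward", "bidirectional")) {
      s0 <- occ$end[t]
      s1 <- min(n, occ$end[t] + window)
      after <- termStart[termStart >= s0]
      if (length(after)) s1 <- min(s1, min(after))
      scopes[[length(scopes) + 1L]] <- c(s0, s1)
    }
    if (dir_ %in% c("backward", "bidirectional")) {
      s1 <- occ$start[t]
      s0 <- max(0L, occ$start[t] - window)
      before <- termEnd[termEnd <= s1]
      if (length(before)) s0 <- max(s0, max(before))
      scopes[[length(scopes) + 1L]] <- c(s0, s1)
    }
    for (sc in scopes) {
      inScope <- mentions$start < sc[2L] & mentions$end > sc[1L]
      if (any(inScope)) mentions[[cat_]][inScope] <- TRUE
    }
  }
  mentions
}

#' Extract context-qualified concept mentions from a note
#'
#' Runs sentence splitting, dictionary matching and ConText modifier
#' detection over one note text.
#'
#' @param text raw note text.
#' @param lexicon a \code{Lexicon}.
#' @param rules a \code{ContextRules} table.
#' @param window scope window in tokens.
#' @return data.frame of mentions with a \code{sentence} index (1-based),
#'   token spans and modifier flags.
#' @export
extractMentions <- function(text, lexicon, rules = defaultContextRules(),
                            window = 10) {
  sentences <- splitSentences(text)
  res <- vector("list", length(sentences))
  for (s in seq_along(sentences)) {
    tokens <- .conceptTokens(sentences[s])
    m <- matchConcepts(tokens, lexicon)
    if (nrow(m)) m <- applyContext(tokens, m, rules, window = window)
    if (nrow(m)) {
      m$sentence <- s
      res[[s]] <- m
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(concept_id = character(), term = character(),
                      start = integer(), end = integer(),
                      negated = logical(), hypothetical = logical(),
                      historical = logical(), experiencer_other = logical(),
                      sentence = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# cheap regex prefilter: a note/sentence can only contain a lexicon match if
# it contains the first token of some lexicon term
.lexiconPrefilter <- function(lexicon) {
  first <- unique(vapply(strsplit(lexicon$term, "[^\\p{L}\\p{N}]+", perl = TRUE),
                         `[`, character(1), 1L))
  paste0("\\b(", paste(first, collapse = "|"), ")\\b")
}

# qualifying concept ids of one note (same computation as extractMentions +
# modifier filter, with prefilters for speed)
.noteQualifyingConcepts <- function(text, lexicon, rules, disqualify, window,
                                    pattern) {
  low <- tolower(text)
  if (!grepl(pattern, low, perl = TRUE)) return(character(0))
  found <- character(0)
  for (s in splitSentences(low)) {
    if (!grepl(pattern, s, perl = TRUE)) next
    tokens <- .conceptTokens(s)
    m <- matchConcepts(tokens, lexicon)
    if (!nrow(m)) next
    if (nrow(rules)) m <- applyContext(tokens, m, rules, window = window)
    bad <- rep(FALSE, nrow(m))
    for (fl in disqualify) bad <- bad | m[[fl]]
    found <- c(found, m$concept_id[!bad])
  }
  unique(found)
}

#' Clinical-concept presence features (Tcon)
#'
#' One binary column per concept: 1 if the observation has at least one
#' qualifying mention of the concept in a note dated inside the look-back
#' window [index - windowDays, index - 1]. By default a mention qualifies
#' unless it is negated, hypothetical or about someone other than the
#' patient (historical mentions are kept); the disqualifying flags are
#' configurable. Concepts never mentioned (with qualification) are dropped.
#'
#' @param cohort cohort data.frame from \code{\link{buildCohort}}.
#' @param dataset an \linkS4class{EHRDataset}.
#' @param lexicon a \code{Lexicon} (default: bundled toy lexicon).
#' @param rules a \code{ContextRules} table (default: bundled Dutch
#'   triggers). Pass a zero-row table to disable context filtering.
#' @param windowDays note look-back window (default 365).
#' @param disqualify modifier flags that disqualify a mention; default
#'   \code{c("negated", "hypothetical", "experiencer_other")}.
#' @param window ConText scope window in tokens.
#' @return a \linkS4class{FeatureMatrix} with source set \code{Tcon}.
#' @export
conceptFeatures <- function(cohort, dataset, lexicon = defaultLexicon(),
                            rules = defaultContextRules(), windowDays = 365,
                            disqualify = c("negated", "hypothetical",
                                           "experiencer_other"),
                            window = 10) {
  nt <- notes(dataset)
  nObs <- nrow(cohort)
  perObs <- vector("list", nObs)
  byPerson <- if (nrow(nt)) split(seq_len(nrow(nt)), nt$person_id) else list()
  # each note is annotated once; observations then aggregate by window
  needed <- sort(unique(unlist(byPerson[unique(cohort$person_id)])))
  noteConcepts <- vector("list", nrow(nt))
  if (length(needed)) {
    pattern <- .lexiconPrefilter(lexicon)
    noteConcepts[needed] <- lapply(nt$text[needed], .noteQualifyingConcepts,
                                   lexicon = lexicon, rules = rules,
                                   disqualify = disqualify, window = window,
                                   pattern = pattern)
  }
  for (o in seq_len(nObs)) {
    rows <- byPerson[[cohort$person_id[o]]]
    if (is.null(rows)) next
    idx <- as.integer(cohort$index_date[o])
    d <- as.integer(nt$note_date[rows])
    hit <- rows[d >= idx - windowDays & d <= idx - 1L]
    perObs[[o]] <- unique(unlist(noteConcepts[hit]))
  }
  colKey <- sort(unique(unlist(perObs)))
  ii <- integer(0); jj <- integer(0)
  for (o in seq_len(nObs)) {
    k <- perObs[[o]]
    if (length(k)) {
      ii <- c(ii, rep(o, length(k)))
      jj <- c(jj, match(k, colKey))
    }
  }
  vals <- Matrix::sparseMatrix(i = ii, j = jj, x = rep(1, length(ii)),
                               dims = c(nObs, length(colKey)))
  if (length(colKey)) {
    nm <- lexicon$preferred_name[match(colKey, lexicon$concept_id)]
    fi <- data.frame(feature_id = paste0("Tcon:", colKey),
                     source_set = "Tcon",
                     window_tag = paste0(windowDays, "d"),
                     name = sprintf("concept %s (%s)", colKey, nm),
                     stringsAsFactors = FALSE)
  } else {
    fi <- .emptyFeatureInfo()
  }
  FeatureMatrix(vals, fi, cohort)
}
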