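#' @include AllClasses.R utils.R
NULL

#' Bag-of-words text preprocessing
#'
#' Replaces every digit, newline (and carriage return) and underscore with a
#' single space; all other characters are left untouched. Applied before
#' tokenization for the bag-of-words representations. Note that the concept
#' extraction path works on the raw text instead (digits are preserved
#' there).
#'
#' @param text character vector.
#' @return character vector of the same length.
#' @export
preprocessText <- function(text) {
  gsub("[0-9_\r\n]", " ", text)
}

#' Simple tokenizer
#'
#' Splits text at spaces and punctuation (every non-alphanumeric character
#' is a separator), lowercases, and drops empty tokens. Unicode letters are
#' kept intact.
#'
#' @param text character vector (one document per element).
#' @return for a single input string, a character vector of tokens; for a
#'   vector, a list of token vectors.
#' @export
tokenizeText <- function(text) {
  parts <- strsplit(tolower(text), "[^\\p{L}\\p{N}]+", perl = TRUE)
  parts <- lapply(parts, function(p) p[nzchar(p)])
  if (length(text) == 1L) parts[[1L]] else parts
}

#' Aggregate notes into one document per observation
#'
#' Concatenates the text of all notes dated inside the look-back window
#' [index - windowDays, index - 1] into a single document per cohort
#' observation. Observations with no notes in the window yield an empty
#' document (they are kept, not dropped).
#'
#' @param cohort cohort data.frame from \code{\link{buildCohort}}.
#' @param dataset an \linkS4class{EHRDataset} (its \code{notes} table is
#'   used), or a notes data.frame.
#' @param windowDays look-back window in days (default 365).
#' @return data.frame with columns \code{person_id}, \code{index_date},
#'   \code{text}, \code{n_notes}, aligned with the cohort rows.
#' @export
buildDocuments <- function(cohort, dataset, windowDays = 365) {
  nt <- if (is(dataset, "EHRDataset")) notes(dataset) else dataset
  nObs <- nrow(cohort)
  text <- character(nObs)
  nNotes <- integer(nObs)
  if (nrow(nt)) {
    byPerson <- split(seq_len(nrow(nt)), nt$person_id)
    for (o in seq_len(nObs)) {
      rows <- byPerson[[cohort$person_id[o]]]
      if (is.null(rows)) next
      idx <- as.integer(cohort$index_date[o])
      d <- as.integer(nt$note_date[rows])
      hit <- rows[d >= idx - windowDays & d <= idx - 1L]
      hit <- hit[order(nt$note_date[hit], nt$note_id[hit])]
      nNotes[o] <- length(hit)
      if (length(hit)) text[o] <- paste(nt$text[hit], collapse = "\n")
    }
  }
  data.frame(person_id = cohort$person_id, index_date = cohort$index_date,
             text = text, n_notes = nNotes, stringsAsFactors = FALSE)
}

.documentTokens <- function(documents) {
  txt <- if (is.data.frame(documents)) documents$text else documents
  toks <- strsplit(tolower(preprocessText(txt)), "[^\\p{L}\\p{N}]+", perl = TRUE)
  lapply(toks, function(p) p[nzchar(p)])
}

#' Fit the bag-of-words vocabulary and idf table
#'
#' Computes document frequencies over the corpus and keeps every term whose
#' document frequency df satisfies \code{minDf * N <= df <= maxDf * N}
#' (terms appearing in more than \code{maxDf} or in less than \code{minDf}
#' of the documents are removed; the bounds themselves are kept). The fitted
#' vocabulary, document frequencies and corpus size are frozen in the
#' returned \linkS4class{TextPipeline} and reused unchanged when vectorizing
#' held-out or external corpora. Note that for corpora smaller than
#' \code{1/minDf} documents the lower bound removes nothing.
#'
#' @param documents data.frame from \code{\link{buildDocuments}} or a
#'   character vector of documents.
#' @param maxDf,minDf document-frequency bounds as fractions of the corpus
#'   size (defaults 0.8 and 0.001).
#' @param representation \code{"binary"} or \code{"tfidf"} (recorded in the
#'   pipeline; both can be produced from the same fitted pipeline).
#' @param textWindowDays the note look-back window the documents were built
#'   with (metadata).
#' @param seed optional seed recorded in the fit fingerprint.
#' @return a fitted \linkS4class{TextPipeline}.
#' @export
fitTextPipeline <- function(documents, maxDf = 0.8, minDf = 0.001,
                            representation = "binary", textWindowDays = 365,
                            seed = NA_integer_) {
  toks <- .documentTokens(documents)
  n <- length(toks)
  if (n == 0L || all(vapply(toks, length, integer(1)) == 0L)) {
    .stopf("fit error: empty corpus (no documents or all documents empty)")
  }
  dfTab <- table(unlist(lapply(toks, unique)))
  df <- as.integer(dfTab)
  term <- names(dfTab)
  keep <- df >= minDf * n & df <= maxDf * n
  ord <- order(term[keep], method = "radix")
  vocab <- term[keep][ord]
  dfKeep <- df[keep][ord]
  txt <- if (is.data.frame(documents)) documents$text else documents
  new("TextPipeline",
      preprocessing = list(lowercase = TRUE,
                           strip_digits_newlines_underscores = TRUE),
      tokenizer = "split-space-punct",
      maxDf = maxDf, minDf = minDf,
      representation = representation,
      vocabulary = vocab, df = dfKeep, nDocs = as.integer(n),
      textWindowDays = as.integer(textWindowDays),
      fingerprint = list(seed = seed,
                         corpus_hash = .fnv1a32(txt),
                         vocab_hash = .fnv1a32(vocab)))
}

#' Inverse document frequencies of a fitted pipeline
#'
#' \eqn{idf(t) = \ln(N_{fit} / df_{fit}(t))}: the natural-log idf with no
#' smoothing, computed from the fitting corpus.
#'
#' @param pipeline a fitted \linkS4class{TextPipeline}.
#' @return named numeric vector over the vocabulary.
#' @export
idfTable <- function(pipeline) {
  stats::setNames(log(pipeline@nDocs / pipeline@df), pipeline@vocabulary)
}

.countMatrix <- function(documents, pipeline) {
  toks <- .documentTokens(documents)
  vocab <- pipeline@vocabulary
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (d in seq_along(toks)) {
    j <- match(toks[[d]], vocab)
    j <- j[!is.na(j)]
    if (length(j)) {
      tf <- table(j)
      ii <- c(ii, rep(d, length(tf)))
      jj <- c(jj, as.integer(names(tf)))
      xx <- c(xx, as.numeric(tf))
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(toks), length(vocab)))
}

.textFeatureInfo <- function(pipeline, set) {
  vocab <- pipeline@vocabulary
  if (!length(vocab)) return(.emptyFeatureInfo())
  data.frame(feature_id = paste0(set, ":", vocab),
             source_set = set, window_tag = paste0(pipeline@textWindowDays, "d"),
             name = sprintf("%s '%s'",
                            if (set == "Tterm") "term" else "tfidf term", vocab),
             stringsAsFactors = FALSE)
}

#' Binary bag-of-words vectorization (Tterm)
#'
#' One column per vocabulary term; the value is 1 if the term occurs at
#' least once in the observation's document, 0 otherwise. Tokens outside the
#' fitted vocabulary are ignored, which is also how external-system
#' documents are projected onto the training feature space.
#'
#' @param documents data.frame from \code{\link{buildDocuments}} (its
#'   \code{person_id}/\code{index_date} become the observation keys) or a
#'   character vector.
#' @param pipeline a fitted \linkS4class{TextPipeline}.
#' @return a \linkS4class{FeatureMatrix} with source set \code{Tterm}.
#' @export
vectorizeBinary <- function(documents, pipeline) {
  counts <- .countMatrix(documents, pipeline)
  vals <- counts
  vals@x <- rep(1, length(vals@x))
  FeatureMatrix(vals, .textFeatureInfo(pipeline, "Tterm"),
                .docKeys(documents))
}

#' TF-IDF vectorization (Ttfidf)
#'
#' The value for term t in document d is
#' \eqn{tf(t, d) \times \ln(N_{fit} / df_{fit}(t))}, with raw term counts
#' and the idf table frozen from the fitting corpus (no smoothing, no
#' normalization). A term present in every fitting document has idf 0 and
#' therefore scores 0 everywhere.
#'
#' @inheritParams vectorizeBinary
#' @return a \linkS4class{FeatureMatrix} with source set \code{Ttfidf}.
#' @export
vectorizeTfidf <- function(documents, pipeline) {
  counts <- .countMatrix(documents, pipeline)
  idf <- log(pipeline@nDocs / pipeline@df)
  vals <- counts %*% Matrix::Diagonal(x = idf)
  vals <- methods::as(methods::as(methods::as(vals, "dMatrix"),
                                  "generalMatrix"), "CsparseMatrix")
  vals <- Matrix::drop0(vals)
  FeatureMatrix(vals, .textFeatureInfo(pipeline, "Ttfidf"),
                .docKeys(documents))
}

.docKeys <- function(documents) {
  if (is.data.frame(documents) &&
      all(c("person_id", "index_date") %in% names(documents))) {
    documents[c("person_id", "index_date")]
  } else {
    n <- if (is.data.frame(documents)) nrow(documents) else length(documents)
    data.frame(person_id = sprintf("doc%04d", seq_len(n)),
               index_date = as.Date("2000-01-01") + seq_len(n))
  }
}

#' Save / load a fitted TextPipeline as JSON
#'
#' The JSON file captures the full fitted state (flags, bounds, vocabulary,
#' document frequencies, corpus size, fingerprint); loading it reproduces
#' matrices identical to the original pipeline on any corpus. On load the
#' stored vocabulary hash is recomputed; a mismatch (tampered or corrupted
#' file) raises an integrity warning.
#'
#' @param pipeline a \linkS4class{TextPipeline}.
#' @param path JSON file path.
#' @return \code{loadTextPipeline}: the restored pipeline.
#' @export
saveTextPipeline <- function(pipeline, path) {
  stopifnot(is(pipeline, "TextPipeline"))
  jsonlite::write_json(
    list(preprocessing = pipeline@preprocessing,
         tokenizer = pipeline@tokenizer,
         max_df = pipeline@maxDf, min_df = pipeline@minDf,
         representation = pipeline@representation,
         vocabulary = pipeline@vocabulary,
         df = pipeline@df, n_docs = pipeline@nDocs,
         text_window_days = pipeline@textWindowDays,
         fingerprint = pipeline@fingerprint),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname saveTextPipeline
#' @export
loadTextPipeline <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  vocab <- as.character(j$vocabulary)
  fp <- as.list(j$fingerprint)
  if (!is.null(fp$vocab_hash) && !identical(fp$vocab_hash, .fnv1a32(vocab))) {
    warning("integrity warning: vocabulary hash mismatch in '", path,
            "' (file edited or corrupted?)", call. = FALSE)
  }
  new("TextPipeline",
      preprocessing = as.list(j$preprocessing),
      tokenizer = j$tokenizer,
      maxDf = j$max_df, minDf = j$min_df,
      representation = j$representation,
      vocabulary = vocab, df = as.integer(j$df), nDocs = as.integer(j$n_docs),
      textWindowDays = as.integer(j$text_window_days),
      fingerprint = fp)
}
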