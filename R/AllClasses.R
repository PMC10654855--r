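#' @import methods
#' @importClassesFrom Matrix dgCMatrix
NULL

setOldClass("data.frame")

#' EHRDataset: a simplified OMOP-CDM-style GP dataset
#'
#' Container for the four flat tables of one EHR-system population:
#' persons, clinical events (conditions, drugs, measurements, procedures),
#' free-text notes, and observation periods. Referential integrity and the
#' rule that every event and note date falls inside an observation period of
#' the same person are enforced by the validity method.
#'
#' @slot persons data.frame with columns \code{person_id},
#'   \code{year_of_birth}, \code{sex} (0/1, 1 = male).
#' @slot events data.frame with columns \code{person_id}, \code{domain}
#'   (one of condition, drug, measurement, procedure), \code{concept_code},
#'   \code{event_date} (Date).
#' @slot notes data.frame with columns \code{note_id}, \code{person_id},
#'   \code{note_date} (Date), \code{note_class} (gp or communication),
#'   \code{text}.
#' @slot observationPeriods data.frame with columns \code{person_id},
#'   \code{start_date}, \code{end_date} (Date).
#' @slot systemId single character label of the EHR system.
#'
#' @aliases EHRDataset-class
#' @exportClass EHRDataset
setClass("EHRDataset",
  representation(
    persons = "data.frame",
    events = "data.frame",
    notes = "data.frame",
    observationPeriods = "data.frame",
    systemId = "character"
  )
)

.validEHRDataset <- function(object) {
  msgs <- character()
  need <- list(
    persons = c("person_id", "year_of_birth", "sex"),
    events = c("person_id", "domain", "concept_code", "event_date"),
    notes = c("note_id", "person_id", "note_date", "note_class", "text"),
    observationPeriods = c("person_id", "start_date", "end_date")
  )
  for (tab in names(need)) {
    df <- slot(object, if (tab == "observationPeriods") "observationPeriods" else tab)
    miss <- setdiff(need[[tab]], names(df))
    if (length(miss)) {
      msgs <- c(msgs, sprintf("table '%s' lacks column(s): %s",
                              tab, paste(miss, collapse = ", ")))
    }
  }
  if (length(msgs)) return(msgs)
  if (length(object@systemId) != 1L) {
    msgs <- c(msgs, "systemId must be a single string")
  }
  pid <- object@persons$person_id
  if (anyDuplicated(pid)) msgs <- c(msgs, "duplicated person_id in persons")
  for (tab in c("events", "notes", "observationPeriods")) {
    df <- slot(object, tab)
    orphan <- which(!(df$person_id %in% pid))
    if (length(orphan)) {
      msgs <- c(msgs, sprintf(
        "table '%s': person_id not in persons at row(s) %s (e.g. '%s')",
        tab, paste(utils::head(orphan, 3L), collapse = ", "),
        df$person_id[orphan[1L]]))
    }
  }
  op <- object@observationPeriods
  inPeriod <- function(person, date) {
    # TRUE if date falls inside some observation period of that person
    idx <- split(seq_len(nrow(op)), op$person_id)
    ok <- logical(length(date))
    for (i in seq_along(date)) {
      rows <- idx[[as.character(person[i])]]
      ok[i] <- length(rows) > 0L &&
        any(op$start_date[rows] <= date[i] & date[i] <= op$end_date[rows])
    }
    ok
  }
  if (nrow(object@events)) {
    bad <- which(!inPeriod(object@events$person_id, object@events$event_date))
    if (length(bad)) {
      msgs <- c(msgs, sprintf("events: %d event_date(s) outside any observation period (first at row %d)",
                              length(bad), bad[1L]))
    }
  }
  if (nrow(object@notes)) {
    bad <- which(!inPeriod(object@notes$person_id, object@notes$note_date))
    if (length(bad)) {
      msgs <- c(msgs, sprintf("notes: %d note_date(s) outside any observation period (first at row %d)",
                              length(bad), bad[1L]))
    }
  }
  if (length(msgs)) msgs else TRUE
}

setValidity("EHRDataset", .validEHRDataset)

#' Construct an EHRDataset
#'
#' @param persons,events,notes,observationPeriods the four tables; see
#'   \linkS4class{EHRDataset} for required columns. Date columns may be given
#'   as character in ISO-8601 form and are converted.
#' @param systemId label of the EHR system the tables come from.
#' @return a validated \linkS4class{EHRDataset}.
#' @export
EHRDataset <- function(persons, events, notes, observationPeriods,
                       systemId = "A") {
  asDate <- function(df, cols) {
    for (cc in intersect(cols, names(df))) df[[cc]] <- as.Date(df[[cc]])
    df
  }
  events <- asDate(as.data.frame(events), "event_date")
  notes <- asDate(as.data.frame(notes), "note_date")
  observationPeriods <- asDate(as.data.frame(observationPeriods),
                               c("start_date", "end_date"))
  new("EHRDataset",
      persons = as.data.frame(persons), events = events, notes = notes,
      observationPeriods = observationPeriods,
      systemId = as.character(systemId))
}

#' FeatureMatrix: sparse observations-by-features matrix with provenance
#'
#' Rows are cohort observations (one per person and index date), columns are
#' features. Every column carries provenance metadata: which feature set it
#' belongs to (D demographics, E clinical events, Tterm binary bag-of-words,
#' Ttfidf TF-IDF, Tcon clinical concepts) and, for event features, the
#' look-back window it was computed over.
#'
#' @slot values a \code{dgCMatrix}, observations x features.
#' @slot featureInfo data.frame with one row per column of \code{values}:
#'   \code{feature_id} (unique), \code{source_set}, \code{window_tag}
#'   (365d, 30d or NA), \code{name}.
#' @slot observations data.frame of cohort keys aligned with the rows,
#'   containing at least \code{person_id} and \code{index_date}.
#'
#' @aliases FeatureMatrix-class
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  representation(
    values = "dgCMatrix",
    featureInfo = "data.frame",
    observations = "data.frame"
  )
)

.validFeatureMatrix <- function(object) {
  msgs <- character()
  fi <- object@featureInfo
  need <- c("feature_id", "source_set", "window_tag", "name")
  miss <- setdiff(need, names(fi))
  if (length(miss)) {
    return(sprintf("featureInfo lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  if (ncol(object@values) != nrow(fi)) {
    msgs <- c(msgs, sprintf("matrix has %d columns but featureInfo has %d rows",
                            ncol(object@values), nrow(fi)))
  }
  if (nrow(object@values) != nrow(object@observations)) {
    msgs <- c(msgs, sprintf("matrix has %d rows but observations has %d rows",
                            nrow(object@values), nrow(object@observations)))
  }
  if (anyDuplicated(fi$feature_id)) {
    msgs <- c(msgs, "feature_id values are not unique")
  }
  badSet <- setdiff(unique(fi$source_set), c("D", "E", "Tterm", "Ttfidf", "Tcon"))
  if (length(badSet)) {
    msgs <- c(msgs, sprintf("unknown source_set: %s", paste(badSet, collapse = ", ")))
  }
  if (!all(c("person_id", "index_date") %in% names(object@observations))) {
    msgs <- c(msgs, "observations must carry person_id and index_date")
  }
  if (length(msgs)) msgs else TRUE
}

setValidity("FeatureMatrix", .validFeatureMatrix)

#' Construct a FeatureMatrix
#'
#' @param values numeric matrix or sparse Matrix (observations x features).
#' @param featureInfo data.frame with columns \code{feature_id},
#'   \code{source_set}, \code{window_tag}, \code{name}.
#' @param observations data.frame of cohort keys (one row per matrix row).
#' @return a validated \linkS4class{FeatureMatrix}.
#' @export
FeatureMatrix <- function(values, featureInfo, observations) {
  values <- methods::as(methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
                                                "dMatrix"), "generalMatrix"), "CsparseMatrix")
  colnames(values) <- featureInfo$feature_id
  new("FeatureMatrix", values = values,
      featureInfo = as.data.frame(featureInfo),
      observations = as.data.frame(observations))
}

#' TextPipeline: a fitted, serializable text featurization configuration
#'
#' Captures everything needed to reproduce a bag-of-words featurization:
#' preprocessing flags, tokenizer id, the document-frequency pruning bounds,
#' the fitted vocabulary with document frequencies and idf weights from the
#' fitting corpus, and a fit fingerprint. A pipeline fitted on a training
#' corpus is applied unchanged to held-out or external corpora: unseen terms
#' are dropped and idf weights are never refitted.
#'
#' @slot preprocessing named list of flags (\code{lowercase},
#'   \code{strip_digits_newlines_underscores}).
#' @slot tokenizer tokenizer identifier.
#' @slot maxDf,minDf document-frequency pruning bounds as fractions of the
#'   corpus size; terms with df/N above \code{maxDf} or below \code{minDf}
#'   are removed (bounds themselves are kept).
#' @slot representation one of \code{binary}, \code{tfidf}, \code{concept}.
#' @slot vocabulary character vector of kept terms.
#' @slot df integer document frequencies of the kept terms (fitting corpus).
#' @slot nDocs number of documents in the fitting corpus.
#' @slot textWindowDays look-back window for note selection.
#' @slot fingerprint list with \code{seed}, \code{corpus_hash} and
#'   \code{vocab_hash} used for integrity checks on load.
#'
#' @aliases TextPipeline-class
#' @exportClass TextPipeline
setClass("TextPipeline",
  representation(
    preprocessing = "list",
    tokenizer = "character",
    maxDf = "numeric",
    minDf = "numeric",
    representation = "character",
    vocabulary = "character",
    df = "integer",
    nDocs = "integer",
    textWindowDays = "integer",
    fingerprint = "list"
  )
)

.validTextPipeline <- function(object) {
  msgs <- character()
  if (length(object@vocabulary) != length(object@df)) {
    msgs <- c(msgs, "vocabulary and df lengths differ")
  }
  if (length(object@df) && (any(object@df < 1L) || any(object@df > object@nDocs))) {
    msgs <- c(msgs, "document frequencies must lie in [1, nDocs]")
  }
  if (!object@representation %in% c("binary", "tfidf", "concept")) {
    msgs <- c(msgs, "representation must be binary, tfidf or concept")
  }
  if (object@maxDf < object@minDf) msgs <- c(msgs, "maxDf < minDf")
  if (length(msgs)) msgs else TRUE
}

setValidity("TextPipeline", .validTextPipeline)
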