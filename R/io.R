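#' @include AllClasses.R utils.R
NULL

.TABLE_FILES <- c(persons = "persons.csv", events = "events.csv",
                  notes = "notes.csv",
                  observation_periods = "observation_periods.csv")

#' Read a simplified OMOP-CDM-style dataset from CSV tables
#'
#' Reads the four flat tables (persons, events, notes, observation periods)
#' and returns a validated \linkS4class{EHRDataset}. Referential integrity
#' (no orphan person ids, all event/note dates inside an observation period)
#' is enforced; violations raise a schema error naming the table and row.
#'
#' @param path either a directory containing \code{persons.csv},
#'   \code{events.csv}, \code{notes.csv} and \code{observation_periods.csv},
#'   or a named character vector/list mapping those table names to file paths.
#' @param systemId system label; defaults to the directory name.
#' @return an \linkS4class{EHRDataset}.
#' @export
readEHRDataset <- function(path, systemId = NULL) {
  if (length(path) == 1L && is.character(path) && dir.exists(path)) {
    files <- file.path(path, .TABLE_FILES)
    names(files) <- names(.TABLE_FILES)
    if (is.null(systemId)) systemId <- basename(normalizePath(path))
  } else {
    files <- unlist(path)
    miss <- setdiff(names(.TABLE_FILES), names(files))
    if (length(miss)) {
      .stopf("schema error: path map lacks table(s): %s", paste(miss, collapse = ", "))
    }
    if (is.null(systemId)) systemId <- "A"
  }
  absent <- !file.exists(files)
  if (any(absent)) {
    .stopf("schema error: missing table file(s): %s",
           paste(files[absent], collapse = ", "))
  }
  rd <- function(f) utils::read.csv(f, stringsAsFactors = FALSE,
                                    colClasses = "character", encoding = "UTF-8")
  persons <- rd(files[["persons"]])
  events <- rd(files[["events"]])
  notesTab <- rd(files[["notes"]])
  op <- rd(files[["observation_periods"]])
  need <- list(persons = c("person_id", "year_of_birth", "sex"),
               events = c("person_id", "domain", "concept_code", "event_date"),
               notes = c("note_id", "person_id", "note_date", "note_class", "text"),
               observation_periods = c("person_id", "start_date", "end_date"))
  tabs <- list(persons = persons, events = events, notes = notesTab,
               observation_periods = op)
  for (tab in names(need)) {
    miss <- setdiff(need[[tab]], names(tabs[[tab]]))
    if (length(miss)) {
      .stopf("schema error: table '%s' lacks column(s): %s", tab,
             paste(miss, collapse = ", "))
    }
  }
  if (nrow(persons)) {
    persons$year_of_birth <- as.integer(persons$year_of_birth)
    persons$sex <- as.integer(persons$sex)
  }
  ds <- EHRDataset(persons = persons, events = events, notes = notesTab,
                   observationPeriods = op, systemId = systemId)
  ds
}

#' Write an EHRDataset as CSV tables
#'
#' @param dataset an \linkS4class{EHRDataset}.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeEHRDataset <- function(dataset, dir) {
  stopifnot(is(dataset, "EHRDataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- list(persons = persons(dataset), events = events(dataset),
               notes = notes(dataset),
               observation_periods = observationPeriods(dataset))
  paths <- file.path(dir, .TABLE_FILES)
  for (i in seq_along(tabs)) {
    utils::write.csv(tabs[[i]], paths[i], row.names = FALSE,
                     fileEncoding = "UTF-8")
  }
  invisible(paths)
}

#' Build the prediction cohort for a task
#'
#' Scans the event table for target events, applies the age criterion and
#' the two exclusion rules — at least \code{observation_days} of observation
#' before the index date, and follow-up through the end of the time-at-risk
#' window (both measured within the observation period covering the index
#' date) — and labels each remaining observation by whether an outcome event
#' occurs in the closed time-at-risk window
#' [index + tar_start_days, index + tar_end_days]. Unless the task allows
#' multiple observations per patient, only the earliest qualifying index
#' date per person is kept.
#'
#' @param dataset an \linkS4class{EHRDataset}.
#' @param task a \code{\link{taskSpec}}.
#' @return data.frame with columns \code{person_id}, \code{index_date},
#'   \code{label}, \code{system_id}, ordered by person and date. Emits a
#'   warning (not an error) if no observation qualifies.
#' @export
buildCohort <- function(dataset, task) {
  stopifnot(is(dataset, "EHRDataset"), inherits(task, "TaskSpec"))
  ev <- events(dataset)
  pers <- persons(dataset)
  op <- observationPeriods(dataset)
  tgt <- ev[ev$domain == task$target_domain &
              ev$concept_code == task$target_code, , drop = FALSE]
  tgt <- unique(tgt[c("person_id", "event_date")])
  out <- ev[ev$domain == task$outcome_domain &
              ev$concept_code == task$outcome_code, , drop = FALSE]

  keep <- logical(nrow(tgt))
  label <- integer(nrow(tgt))
  if (nrow(tgt)) {
    yob <- pers$year_of_birth[match(tgt$person_id, pers$person_id)]
    age <- as.integer(format(tgt$event_date, "%Y")) - yob
    opByPerson <- split(seq_len(nrow(op)), op$person_id)
    outByPerson <- split(as.integer(out$event_date), out$person_id)
    for (i in seq_len(nrow(tgt))) {
      if (is.na(age[i]) || age[i] < task$min_age) next
      idx <- as.integer(tgt$event_date[i])
      rows <- opByPerson[[tgt$person_id[i]]]
      if (is.null(rows)) next
      covering <- rows[as.integer(op$start_date[rows]) <= idx &
                         idx <= as.integer(op$end_date[rows])]
      ok <- any(idx - as.integer(op$start_date[covering]) >= task$observation_days &
                  as.integer(op$end_date[covering]) >= idx + task$tar_end_days)
      if (!ok) next
      keep[i] <- TRUE
      od <- outByPerson[[tgt$person_id[i]]]
      label[i] <- as.integer(!is.null(od) &&
                               any(od >= idx + task$tar_start_days &
                                     od <= idx + task$tar_end_days))
    }
  }
  cohort <- data.frame(person_id = tgt$person_id[keep],
                       index_date = tgt$event_date[keep],
                       label = label[keep],
                       system_id = rep(systemId(dataset), sum(keep)),
                       stringsAsFactors = FALSE)
  cohort <- cohort[order(cohort$person_id, cohort$index_date), , drop = FALSE]
  if (!task$multiple_obs_per_patient && nrow(cohort)) {
    cohort <- cohort[!duplicated(cohort$person_id), , drop = FALSE]
  }
  rownames(cohort) <- NULL
  if (!nrow(cohort)) {
    warning(sprintf("empty cohort for task '%s' on system '%s'",
                    task$task_id, systemId(dataset)), call. = FALSE)
  }
  cohort
}

#' Persist and reload a FeatureMatrix
#'
#' Writes the sparse values as a MatrixMarket file and all descriptor
#' metadata (feature provenance and observation keys) as a JSON sidecar next
#' to it; \code{readFeatureMatrix} restores a bit-identical object. A missing
#' sidecar or a dimension mismatch between the two files raises an integrity
#' error.
#'
#' @param matrix a \linkS4class{FeatureMatrix}.
#' @param path path of the \code{.mtx} file; the sidecar uses the same path
#'   with extension \code{.json}.
#' @return \code{writeFeatureMatrix}: invisibly the two paths;
#'   \code{readFeatureMatrix}: the restored \linkS4class{FeatureMatrix}.
#' @export
writeFeatureMatrix <- function(matrix, path) {
  stopifnot(is(matrix, "FeatureMatrix"))
  Matrix::writeMM(featureValues(matrix), path)
  side <- sub("\\.mtx$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  obs <- observationKeys(matrix)
  obs$index_date <- as.character(obs$index_date)
  jsonlite::write_json(
    list(dims = dim(matrix), featureInfo = featureInfo(matrix),
         observations = obs),
    side, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(path, side))
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
  side <- sub("\\.mtx$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  if (!file.exists(path)) .stopf("integrity error: missing matrix file '%s'", path)
  if (!file.exists(side)) {
    .stopf("integrity error: missing metadata sidecar '%s'", side)
  }
  vals <- methods::as(methods::as(methods::as(Matrix::readMM(path), "dMatrix"),
                                  "generalMatrix"), "CsparseMatrix")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  fi <- as.data.frame(meta$featureInfo)
  if (!nrow(fi)) fi <- .emptyFeatureInfo()
  obs <- as.data.frame(meta$observations)
  if (!nrow(obs)) {
    obs <- data.frame(person_id = character(), index_date = as.Date(character()))
  } else {
    obs$index_date <- as.Date(obs$index_date)
    if (!is.null(obs$label)) obs$label <- as.integer(obs$label)
  }
  if (nrow(fi) != ncol(vals) || nrow(obs) != nrow(vals)) {
    .stopf("integrity error: sidecar describes %d x %d but matrix is %d x %d",
           nrow(obs), nrow(fi), nrow(vals), ncol(vals))
  }
  fi$window_tag <- as.character(fi$window_tag)
  FeatureMatrix(vals, fi, obs)
}

#' Write/read a cohort table as CSV
#'
#' @param cohort a cohort data.frame from \code{\link{buildCohort}}.
#' @param path CSV file path.
#' @return \code{readCohort}: the cohort data.frame.
#' @export
writeCohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                       colClasses = c(person_id = "character"))
  x$index_date <- as.Date(x$index_date)
  x
}
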