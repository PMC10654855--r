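#' @include AllClasses.R utils.R
NULL

#' Demographic features (set D)
#'
#' Builds the two demographic covariates for each cohort observation: age in
#' years at the index date (calendar-year difference) and sex (0/1).
#'
#' @param cohort cohort data.frame from \code{\link{buildCohort}}.
#' @param dataset the \linkS4class{EHRDataset} the cohort came from (or any
#'   dataset containing all cohort persons).
#' @return a \linkS4class{FeatureMatrix} with source set \code{D}.
#' @export
demographicFeatures <- function(cohort, dataset) {
  pers <- persons(dataset)
  m <- match(cohort$person_id, pers$person_id)
  if (anyNA(m)) {
    .stopf("schema error: cohort person(s) missing from persons table: %s",
           paste(utils::head(cohort$person_id[is.na(m)], 3L), collapse = ", "))
  }
  age <- as.integer(format(cohort$index_date, "%Y")) - pers$year_of_birth[m]
  vals <- cbind(age = age, sex = pers$sex[m])
  fi <- data.frame(feature_id = c("D:age", "D:sex"),
                   source_set = "D", window_tag = NA_character_,
                   name = c("age at index (years)", "sex (1 = male)"),
                   stringsAsFactors = FALSE)
  FeatureMatrix(vals, fi, cohort)
}

#' Clinical-event occurrence features (set E)
#'
#' One binary column per (domain, concept code, look-back window): 1 if the
#' person has at least one event with that code dated inside the closed
#' window [index - w, index - 1], 0 otherwise. The index date itself never
#' contributes (the target event is not a covariate). Columns that are zero
#' for every observation are dropped, so the feature space is the set of
#' (code, window) pairs actually observed in this cohort.
#'
#' @param cohort cohort data.frame from \code{\link{buildCohort}}.
#' @param dataset the \linkS4class{EHRDataset}.
#' @param windows look-back windows in days, descending; default
#'   \code{c(365, 30)}.
#' @return a \linkS4class{FeatureMatrix} with source set \code{E}.
#' @export
eventFeatures <- function(cohort, dataset, windows = c(365, 30)) {
  if (!length(windows) || is.unsorted(rev(windows))) {
    .stopf("configuration error: windows must be non-empty and descending")
  }
  ev <- events(dataset)
  ev <- ev[ev$person_id %in% cohort$person_id, , drop = FALSE]
  nObs <- nrow(cohort)
  ii <- integer(0); jj <- integer(0)
  colKey <- character(0)
  if (nrow(ev)) {
    evByPerson <- split(seq_len(nrow(ev)), ev$person_id)
    keyList <- vector("list", nObs)
    for (o in seq_len(nObs)) {
      rows <- evByPerson[[cohort$person_id[o]]]
      if (is.null(rows)) next
      idx <- as.integer(cohort$index_date[o])
      d <- as.integer(ev$event_date[rows])
      keys <- character(0)
      for (w in windows) {
        hit <- rows[d >= idx - w & d <= idx - 1L]
        if (length(hit)) {
          keys <- c(keys, unique(sprintf("E:%s:%s:%dd", ev$domain[hit],
                                         ev$concept_code[hit], w)))
        }
      }
      keyList[[o]] <- keys
    }
    colKey <- sort(unique(unlist(keyList)))
    if (length(colKey)) {
      for (o in seq_len(nObs)) {
        k <- keyList[[o]]
        if (length(k)) {
          ii <- c(ii, rep(o, length(k)))
          jj <- c(jj, match(k, colKey))
        }
      }
    }
  }
  vals <- Matrix::sparseMatrix(i = ii, j = jj, x = rep(1, length(ii)),
                               dims = c(nObs, length(colKey)))
  parts <- strsplit(colKey, ":", fixed = TRUE)
  fi <- data.frame(
    feature_id = colKey,
    source_set = "E",
    window_tag = vapply(parts, function(p) p[4L], character(1)),
    name = vapply(parts, function(p) {
      sprintf("%s %s in prior %s", p[2L], p[3L], p[4L])
    }, character(1)),
    stringsAsFactors = FALSE)
  if (!length(colKey)) fi <- .emptyFeatureInfo()
  FeatureMatrix(vals, fi, cohort)
}

#' Project a FeatureMatrix onto a reference feature space
#'
#' Used when applying a model or featurization fitted on training data to
#' held-out or external-system observations: columns are reordered to the
#' reference \code{feature_id}s, features absent from \code{x} are
#' zero-filled, and features of \code{x} unknown to the reference space are
#' dropped.
#'
#' @param x a \linkS4class{FeatureMatrix}.
#' @param reference a \code{featureInfo} data.frame (or a
#'   \linkS4class{FeatureMatrix} whose feature space is to be matched).
#' @return a \linkS4class{FeatureMatrix} with exactly the reference columns.
#' @export
alignFeatures <- function(x, reference) {
  fi <- if (is(reference, "FeatureMatrix")) featureInfo(reference) else reference
  vals <- featureValues(x)
  m <- match(fi$feature_id, featureInfo(x)$feature_id)
  out <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(nrow(vals), nrow(fi)))
  present <- which(!is.na(m))
  if (length(present)) out[, present] <- vals[, m[present], drop = FALSE]
  FeatureMatrix(out, fi, observationKeys(x))
}
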