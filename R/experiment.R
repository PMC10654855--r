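#' @include AllClasses.R utils.R structured.R text.R concepts.R evaluation.R
NULL

# ---- feature-set combinations ---------------------------------------------

#' The seven feature-set combinations
#'
#' Structured (S = D+E), three text combinations (demographics plus one text
#' representation) and three combined ones (structured plus one text
#' representation). Demographics are part of every combination because they
#' are always available.
#'
#' @return named list mapping combo id to its member sets.
#' @export
featureCombos <- function() {
  list(
    S = c("D", "E"),
    T_term = c("D", "Tterm"),
    T_tfidf = c("D", "Ttfidf"),
    T_con = c("D", "Tcon"),
    ST_term = c("D", "E", "Tterm"),
    ST_tfidf = c("D", "E", "Ttfidf"),
    ST_con = c("D", "E", "Tcon")
  )
}

.comboRepresentation <- function(combo) {
  c(S = "none", T_term = "term", T_tfidf = "tfidf", T_con = "con",
    ST_term = "term", ST_tfidf = "tfidf", ST_con = "con")[combo]
}

#' Column-bind FeatureMatrix objects
#'
#' All arguments must share the observation (row) index; feature provenance
#' metadata is concatenated along with the values.
#'
#' @param ... \linkS4class{FeatureMatrix} objects.
#' @return a single \linkS4class{FeatureMatrix}.
#' @export
combineFeatures <- function(...) {
  ms <- list(...)
  if (length(ms) == 1L && is.list(ms[[1L]]) && !is(ms[[1L]], "FeatureMatrix")) {
    ms <- ms[[1L]]
  }
  keys <- lapply(ms, function(m) {
    paste(observationKeys(m)$person_id, observationKeys(m)$index_date)
  })
  for (i in seq_along(keys)[-1L]) {
    if (!identical(keys[[1L]], keys[[i]])) {
      .stopf("integrity error: feature matrices do not share the observation index")
    }
  }
  vals <- do.call(cbind, lapply(ms, featureValues))
  fi <- do.call(rbind, lapply(ms, featureInfo))
  FeatureMatrix(vals, fi, observationKeys(ms[[1L]]))
}

#' Assemble the seven combination matrices from the five member sets
#'
#' @param sets named list with elements \code{D}, \code{E}, \code{Tterm},
#'   \code{Ttfidf}, \code{Tcon}, each a \linkS4class{FeatureMatrix} over the
#'   same observations.
#' @param combos combo definition from \code{\link{featureCombos}}.
#' @return named list of seven \linkS4class{FeatureMatrix} objects.
#' @export
assembleCombos <- function(sets, combos = featureCombos()) {
  miss <- setdiff(unique(unlist(combos)), names(sets))
  if (length(miss)) {
    .stopf("missing feature set(s): %s", paste(miss, collapse = ", "))
  }
  lapply(combos, function(members) combineFeatures(sets[members]))
}

# ---- splitting -------------------------------------------------------------

#' Subject-level train/test split
#'
#' Splits a cohort so that all observations of one person land in the same
#' partition; the test partition contains round(testFraction * persons)
#' persons, drawn at random under the given seed.
#'
#' @param cohort cohort data.frame from \code{\link{buildCohort}}.
#' @param testFraction fraction of persons assigned to the test set.
#' @param seed integer seed.
#' @return list with integer row indices \code{train} and \code{test}.
#' @export
splitSubjectLevel <- function(cohort, testFraction = 0.25, seed = 1) {
  if (testFraction <= 0 || testFraction >= 1) {
    .stopf("configuration error: testFraction must lie in (0, 1)")
  }
  ppl <- unique(cohort$person_id)
  if (length(ppl) < 2L) {
    .stopf("split error: need at least 2 persons for a subject-level split")
  }
  k <- max(1L, round(testFraction * length(ppl)))
  if (k >= length(ppl)) k <- length(ppl) - 1L
  testPpl <- .withSeed(seed, sample(ppl, k))
  inTest <- cohort$person_id %in% testPpl
  list(train = which(!inTest), test = which(inTest))
}

# subject-level cross-validation fold ids (1..k) per row
.cvFolds <- function(personIds, k, seed) {
  ppl <- unique(personIds)
  fold <- .withSeed(seed, sample(rep(seq_len(k), length.out = length(ppl))))
  fold[match(personIds, ppl)]
}

# ---- model specifications and tuning --------------------------------------

#' Default hyperparameter grids
#'
#' Small conventional grids: inverse regularization strength C on a log
#' scale for the lasso, depth x rounds x learning-rate for gradient
#' boosting, and mtry variants for a 200-tree random forest. Grids are
#' ordered so that the first entry is the most regularized / smallest model;
#' cross-validation ties resolve toward it.
#'
#' @return named list of data.frames, one per algorithm.
#' @export
defaultGrids <- function() {
  xgb <- expand.grid(eta = c(0.05, 0.2), max_depth = c(2, 4, 6),
                     nrounds = c(50, 200))
  xgb <- xgb[order(xgb$nrounds, xgb$max_depth, xgb$eta), , drop = FALSE]
  rownames(xgb) <- NULL
  list(
    LR = data.frame(C = c(0.001, 0.01, 0.1, 1, 10)),
    XGB = xgb,
    RF = data.frame(num_trees = 200, mtry = c("sqrt", "p03"),
                    stringsAsFactors = FALSE)
  )
}

#' Model specification
#'
#' @param algorithm one of \code{"LR"} (L1 logistic regression),
#'   \code{"XGB"} (gradient boosted trees), \code{"RF"} (random forest).
#' @param grid hyperparameter grid data.frame; default from
#'   \code{\link{defaultGrids}}.
#' @param cv_folds number of cross-validation folds (3).
#' @param seed integer seed governing folds and learner randomness.
#' @return a \code{ModelSpec} list.
#' @export
modelSpec <- function(algorithm = c("LR", "XGB", "RF"), grid = NULL,
                      cv_folds = 3, seed = 1) {
  algorithm <- match.arg(algorithm)
  if (is.null(grid)) grid <- defaultGrids()[[algorithm]]
  if (!nrow(grid)) .stopf("configuration error: empty hyperparameter grid")
  structure(list(algorithm = algorithm, grid = grid,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "ModelSpec")
}

.aurocFast <- function(labels, probs) {
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(probs)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.fitOne <- function(algorithm, params, x, y, seed) {
  set.seed(seed)
  switch(algorithm,
    LR = {
      # decreasing lambda path down to the target value: warm starts keep
      # the coordinate descent stable at weak regularization
      lam <- 1 / (params$C * nrow(x))
      path <- exp(seq(log(max(1, lam * 1e4)), log(lam), length.out = 30))
      glmnet::glmnet(x, y, family = "binomial", alpha = 1, lambda = path)
    },
    XGB = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = params$max_depth,
                      eta = params$eta, nthread = 1),
        data = dtrain, nrounds = params$nrounds, verbose = 0)
    },
    RF = {
      p <- ncol(x)
      mtry <- if (params$mtry == "sqrt") max(1L, floor(sqrt(p)))
              else max(1L, floor(0.3 * p))
      ranger::ranger(x = as.matrix(x), y = factor(y, levels = c(0, 1)),
                     num.trees = params$num_trees, mtry = min(mtry, p),
                     probability = TRUE, importance = "impurity",
                     seed = seed, num.threads = 1)
    })
}

.predictOne <- function(algorithm, fit, params, x) {
  switch(algorithm,
    LR = as.numeric(stats::predict(fit, newx = x,
                                   s = 1 / (params$C * fit$nobs),
                                   type = "response", exact = FALSE)),
    XGB = as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(x))),
    RF = {
      pr <- stats::predict(fit, data = as.matrix(x), num.threads = 1)$predictions
      as.numeric(pr[, "1"])
    })
}

#' Tune hyperparameters by cross-validated AUROC and train the final model
#'
#' Performs a grid search with subject-level k-fold cross-validation on the
#' training data (mean AUROC over folds as the selection criterion; ties
#' resolve toward the earlier, more regularized grid entry), then refits the
#' selected configuration on the full training data.
#'
#' @param x a \linkS4class{FeatureMatrix} or \code{dgCMatrix} of training
#'   observations.
#' @param labels 0/1 outcome vector (must contain both classes).
#' @param spec a \code{\link{modelSpec}}.
#' @return a \code{TrainedModel} list: the fitted learner, selected
#'   hyperparameters, cross-validation table, and the feature descriptor
#'   list used for alignment at prediction time.
#' @export
tuneAndTrain <- function(x, labels, spec) {
  stopifnot(inherits(spec, "ModelSpec"))
  fm <- NULL
  if (is(x, "FeatureMatrix")) {
    fm <- x
    personIds <- observationKeys(x)$person_id
    x <- featureValues(x)
  } else {
    personIds <- as.character(seq_len(nrow(x)))
  }
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    .stopf("training error: labels contain a single class")
  }
  if (ncol(x) == 0L) .stopf("training error: no features")
  folds <- .cvFolds(personIds, spec$cv_folds, .childSeed(spec$seed, "cv"))
  grid <- spec$grid
  cvAuc <- matrix(NA_real_, nrow(grid), spec$cv_folds)
  for (f in seq_len(spec$cv_folds)) {
    tr <- folds != f
    if (length(unique(labels[tr])) < 2L || !any(!tr)) next
    for (g in seq_len(nrow(grid))) {
      params <- grid[g, , drop = FALSE]
      fit <- .fitOne(spec$algorithm, params, x[tr, , drop = FALSE], labels[tr],
                     .childSeed(spec$seed, sprintf("fold%d-g%d", f, g)))
      pr <- .predictOne(spec$algorithm, fit, params, x[!tr, , drop = FALSE])
      cvAuc[g, f] <- .aurocFast(labels[!tr], pr)
    }
  }
  meanAuc <- rowMeans(cvAuc, na.rm = TRUE)
  best <- which.max(round(meanAuc, 10)) # first (most regularized) on ties
  params <- grid[best, , drop = FALSE]
  fit <- .fitOne(spec$algorithm, params, x, labels,
                 .childSeed(spec$seed, "final"))
  betas <- NULL
  featureIds <- colnames(x)
  if (spec$algorithm == "LR") {
    cf <- as.numeric(stats::coef(fit, s = 1 / (params$C * nrow(x))))
    betas <- cf[-1L]
    names(betas) <- featureIds
  }
  structure(list(
    algorithm = spec$algorithm, spec = spec,
    params = params, fit = fit, betas = betas,
    featureIds = featureIds,
    featureInfo = if (!is.null(fm)) featureInfo(fm) else
      data.frame(feature_id = featureIds, source_set = NA, window_tag = NA,
                 name = featureIds, stringsAsFactors = FALSE),
    cv = data.frame(grid, mean_cv_auroc = meanAuc),
    seed = spec$seed), class = "TrainedModel")
}

#' Predict outcome probabilities with a trained model
#'
#' Features are aligned to the model's training feature space by feature id
#' (absent features zero-filled, novel ones dropped) before prediction, so
#' external-system matrices can be passed directly.
#'
#' @param model a \code{TrainedModel}.
#' @param x a \linkS4class{FeatureMatrix} or \code{dgCMatrix}.
#' @return numeric vector of probabilities in [0, 1].
#' @export
predictRisk <- function(model, x) {
  stopifnot(inherits(model, "TrainedModel"))
  if (is(x, "FeatureMatrix")) {
    x <- featureValues(alignFeatures(x, model$featureInfo))
  } else if (!identical(colnames(x), model$featureIds)) {
    .stopf("integrity error: feature columns do not match the model")
  }
  .predictOne(model$algorithm, model$fit, model$params, x)
}

# ---- the full grid ---------------------------------------------------------

.buildTaskFeatureSets <- function(task, dsTrainSys, dsExtSys, cohortTrain,
                                  cohortTest, cohortExt, lexicon, rules,
                                  maxDf, minDf, eventWindows, textWindowDays,
                                  seed) {
  D <- list(train = demographicFeatures(cohortTrain, dsTrainSys),
            test = demographicFeatures(cohortTest, dsTrainSys),
            ext = demographicFeatures(cohortExt, dsExtSys))
  Etrain <- eventFeatures(cohortTrain, dsTrainSys, windows = eventWindows)
  E <- list(train = Etrain,
            test = alignFeatures(eventFeatures(cohortTest, dsTrainSys,
                                               windows = eventWindows), Etrain),
            ext = alignFeatures(eventFeatures(cohortExt, dsExtSys,
                                              windows = eventWindows), Etrain))
  docsTrain <- buildDocuments(cohortTrain, dsTrainSys, windowDays = textWindowDays)
  docsTest <- buildDocuments(cohortTest, dsTrainSys, windowDays = textWindowDays)
  docsExt <- buildDocuments(cohortExt, dsExtSys, windowDays = textWindowDays)
  pipeline <- fitTextPipeline(docsTrain, maxDf = maxDf, minDf = minDf,
                              textWindowDays = textWindowDays, seed = seed)
  Tterm <- list(train = vectorizeBinary(docsTrain, pipeline),
                test = vectorizeBinary(docsTest, pipeline),
                ext = vectorizeBinary(docsExt, pipeline))
  Ttfidf <- list(train = vectorizeTfidf(docsTrain, pipeline),
                 test = vectorizeTfidf(docsTest, pipeline),
                 ext = vectorizeTfidf(docsExt, pipeline))
  TconTrain <- conceptFeatures(cohortTrain, dsTrainSys, lexicon, rules,
                               windowDays = textWindowDays)
  Tcon <- list(train = TconTrain,
               test = alignFeatures(conceptFeatures(cohortTest, dsTrainSys,
                                                    lexicon, rules,
                                                    windowDays = textWindowDays),
                                    TconTrain),
               ext = alignFeatures(conceptFeatures(cohortExt, dsExtSys,
                                                   lexicon, rules,
                                                   windowDays = textWindowDays),
                                   TconTrain))
  list(pipeline = pipeline,
       sets = list(
         train = list(D = D$train, E = E$train, Tterm = Tterm$train,
                      Ttfidf = Ttfidf$train, Tcon = Tcon$train),
         test = list(D = D$test, E = E$test, Tterm = Tterm$test,
                     Ttfidf = Ttfidf$test, Tcon = Tcon$test),
         ext = list(D = D$ext, E = E$ext, Tterm = Tterm$ext,
                    Ttfidf = Ttfidf$ext, Tcon = Tcon$ext)))
}

#' Run the full internal + external validation grid
#'
#' For each task, ranks the two EHR-system datasets by cohort size, uses the
#' larger for a 75/25 subject-level train/internal-test split and the
#' smaller entirely for external validation. All featurization state
#' (event-feature space, bag-of-words vocabulary and idf, concept feature
#' space) is fitted on the training partition only and applied frozen to the
#' internal test set and the external system. Every (task, combo, algorithm)
#' cell is trained once and validated both internally and externally.
#'
#' @param taskData named list; each element is a list with components
#'   \code{task} (a \code{\link{taskSpec}}) and \code{datasets} (a list of
#'   two \linkS4class{EHRDataset}s).
#' @param algorithms subset of \code{c("LR", "XGB", "RF")}.
#' @param grids hyperparameter grids, see \code{\link{defaultGrids}}.
#' @param combos combo definitions, see \code{\link{featureCombos}}.
#' @param seed global seed governing splits, folds and learners.
#' @param testFraction internal test fraction (default 0.25).
#' @param lexicon,rules concept-extraction resources.
#' @param maxDf,minDf vocabulary pruning bounds.
#' @param eventWindows look-back windows for event features.
#' @param textWindowDays note look-back window for text features.
#' @param keepModels whether to keep the fitted model objects (needed for
#'   \code{\link{featureImportance}}).
#' @param verbose print per-stage progress.
#' @return an \code{ExperimentResult} list: \code{records} (one row per
#'   task, combo, algorithm and validation type), \code{predictions} (one
#'   row per scored observation), \code{models}, \code{pipelines},
#'   \code{importance} (top-10 per model) and \code{seed}.
#' @export
runExperiment <- function(taskData, algorithms = c("LR", "XGB", "RF"),
                          grids = defaultGrids(), combos = featureCombos(),
                          seed = 1, testFraction = 0.25,
                          lexicon = defaultLexicon(),
                          rules = defaultContextRules(),
                          maxDf = 0.8, minDf = 0.001,
                          eventWindows = c(365, 30), textWindowDays = 365,
                          keepModels = TRUE, verbose = FALSE) {
  records <- list(); preds <- list(); models <- list()
  pipelines <- list(); importance <- list()
  say <- function(...) if (verbose) message(sprintf(...))
  for (taskName in names(taskData)) {
    td <- taskData[[taskName]]
    task <- td$task
    if (length(td$datasets) < 2L) {
      warning(sprintf("task '%s' skipped: needs two system datasets", taskName),
              call. = FALSE)
      next
    }
    cohorts <- lapply(td$datasets, buildCohort, task = task)
    sizes <- vapply(cohorts, nrow, integer(1))
    if (any(sizes == 0L)) {
      warning(sprintf("task '%s' skipped: empty cohort", taskName), call. = FALSE)
      next
    }
    iTrain <- which.max(sizes)
    iExt <- setdiff(seq_along(cohorts), iTrain)[1L]
    dsTrainSys <- td$datasets[[iTrain]]
    dsExtSys <- td$datasets[[iExt]]
    cohortFull <- cohorts[[iTrain]]
    cohortExt <- cohorts[[iExt]]
    sp <- splitSubjectLevel(cohortFull, testFraction,
                            seed = .childSeed(seed, paste0("split-", taskName)))
    cohortTrain <- cohortFull[sp$train, , drop = FALSE]
    cohortTest <- cohortFull[sp$test, , drop = FALSE]
    say("[%s] cohorts: train %d / test %d / external %d (prevalence %.3f)",
        taskName, nrow(cohortTrain), nrow(cohortTest), nrow(cohortExt),
        mean(cohortTrain$label))
    fs <- .buildTaskFeatureSets(task, dsTrainSys, dsExtSys, cohortTrain,
                                cohortTest, cohortExt, lexicon, rules,
                                maxDf, minDf, eventWindows, textWindowDays,
                                seed)
    pipelines[[taskName]] <- fs$pipeline
    comboTrain <- assembleCombos(fs$sets$train, combos)
    comboTest <- assembleCombos(fs$sets$test, combos)
    comboExt <- assembleCombos(fs$sets$ext, combos)
    for (comboName in names(combos)) {
      for (alg in algorithms) {
        mseed <- .childSeed(seed, paste(taskName, comboName, alg))
        model <- tuneAndTrain(comboTrain[[comboName]], cohortTrain$label,
                              modelSpec(alg, grids[[alg]], seed = mseed))
        key <- paste(taskName, comboName, alg, sep = ".")
        if (keepModels) models[[key]] <- model
        impTab <- featureImportance(model, k = 10)
        if (nrow(impTab)) {
          importance[[key]] <- cbind(task = taskName, combo = comboName,
                                     algorithm = alg, impTab)
        }
        for (vt in c("internal", "external")) {
          cm <- if (vt == "internal") comboTest[[comboName]] else comboExt[[comboName]]
          ch <- if (vt == "internal") cohortTest else cohortExt
          pr <- predictRisk(model, cm)
          met <- tryCatch(computeMetrics(ch$label, pr), error = function(e) {
            warning(sprintf("%s %s: %s", key, vt, conditionMessage(e)),
                    call. = FALSE)
            list(auroc = NA_real_, auprc = NA_real_, brier = NA_real_,
                 precision = NA_real_, recall = NA_real_, f1 = NA_real_,
                 threshold = NA_real_)
          })
          records[[length(records) + 1L]] <- data.frame(
            task = taskName, combo = comboName,
            family = .comboFamily(comboName),
            representation = unname(.comboRepresentation(comboName)),
            algorithm = alg, validation_type = vt,
            auroc = met$auroc, auprc = met$auprc, brier = met$brier,
            precision = met$precision, recall = met$recall, f1 = met$f1,
            threshold = met$threshold, n = nrow(ch), seed = seed,
            stringsAsFactors = FALSE)
          preds[[length(preds) + 1L]] <- data.frame(
            task = taskName, combo = comboName, algorithm = alg,
            validation_type = vt, person_id = ch$person_id,
            index_date = ch$index_date, label = ch$label,
            probability = pr, stringsAsFactors = FALSE)
        }
        say("[%s] %s/%s done", taskName, comboName, alg)
      }
    }
  }
  res <- list(records = do.call(rbind, records),
              predictions = do.call(rbind, preds),
              models = models,
              pipelines = pipelines,
              importance = do.call(rbind, importance),
              seed = seed)
  rownames(res$records) <- rownames(res$predictions) <- NULL
  if (!is.null(res$importance)) rownames(res$importance) <- NULL
  class(res) <- "ExperimentResult"
  res
}

#' @export
print.ExperimentResult <- function(x, ...) {
  cat("ExperimentResult:", length(unique(x$records$task)), "task(s),",
      length(unique(x$records$combo)), "combos,",
      length(unique(x$records$algorithm)), "algorithms ->",
      nrow(x$records[x$records$validation_type == "internal", ]),
      "trained models\n")
  agg <- stats::aggregate(auroc ~ task + family + validation_type,
                          data = x$records, FUN = stats::median)
  print(agg, row.names = FALSE)
  invisible(x)
}
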