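test_that("there are exactly 7 feature-set combinations with the stated members", {
  combos <- featureCombos()
  expect_length(combos, 7L)
  expect_identical(combos$S, c("D", "E"))
  for (nm in names(combos)) {
    expect_true("D" %in% combos[[nm]]) # demographics in every combo
    if (startsWith(nm, "ST_")) expect_true(all(c("D", "E") %in% combos[[nm]]))
  }
  expect_setequal(unique(unlist(combos)), c("D", "E", "Tterm", "Ttfidf", "Tcon"))
})

test_that("combo assembly concatenates columns and preserves provenance", {
  task <- defaultTasks()$asthma
  ds <- simulateEHR(systemProfile("A", n_patients = 60, notes_per_obs_median = 5,
                                  words_per_note_median = 8),
                    defaultSignal("asthma"), task, seed = 17)
  ch <- buildCohort(ds, task)
  docs <- buildDocuments(ch, ds)
  pl <- fitTextPipeline(docs)
  sets <- list(D = demographicFeatures(ch, ds), E = eventFeatures(ch, ds),
               Tterm = vectorizeBinary(docs, pl),
               Ttfidf = vectorizeTfidf(docs, pl),
               Tcon = conceptFeatures(ch, ds))
  combos <- assembleCombos(sets)
  expect_length(combos, 7L)
  expect_identical(ncol(combos$ST_term),
                   ncol(sets$D) + ncol(sets$E) + ncol(sets$Tterm))
  expect_equal(Matrix::rowSums(featureValues(combos$ST_term)),
               Matrix::rowSums(featureValues(sets$D)) +
                 Matrix::rowSums(featureValues(sets$E)) +
                 Matrix::rowSums(featureValues(sets$Tterm)),
               ignore_attr = TRUE)
  expect_identical(unique(featureInfo(combos$T_con)$source_set), c("D", "Tcon"))
  # mismatched observation index is refused
  bad <- sets
  bad$E <- alignFeatures(sets$E, sets$E) # same space
  bad$E@observations <- bad$E@observations[rev(seq_len(nrow(ch))), ]
  expect_error(assembleCombos(bad), "observation index")
})

test_that("subject-level splits keep persons intact and hit the target fraction", {
  cohort <- data.frame(person_id = rep(sprintf("p%04d", 1:1000)),
                       index_date = as.Date("2019-01-01"), label = 0L)
  sp <- splitSubjectLevel(cohort, 0.25, seed = 7)
  expect_length(intersect(cohort$person_id[sp$train],
                          cohort$person_id[sp$test]), 0L)
  expect_true(length(sp$test) >= 230 && length(sp$test) <= 270)
  # multi-observation persons stay together
  cohort2 <- data.frame(person_id = rep(c("a", "b", "c", "d"), times = c(3, 1, 2, 2)),
                        index_date = as.Date("2019-01-01") + 1:8, label = 0L)
  for (s in 1:5) {
    sp2 <- splitSubjectLevel(cohort2, 0.25, seed = s)
    both <- intersect(cohort2$person_id[sp2$train], cohort2$person_id[sp2$test])
    expect_length(both, 0L)
  }
  expect_error(splitSubjectLevel(cohort2[cohort2$person_id == "a", ]), "split error")
  expect_error(splitSubjectLevel(cohort2, 1.5), "testFraction")
})

test_that("perfectly separable data trains to AUROC 1 and tuning is deterministic", {
  withr::with_seed(5, {
    n <- 120
    y <- rep(0:1, each = n / 2)
    x <- cbind(sig1 = y + rnorm(n, 0, 0.01), sig2 = -y + rnorm(n, 0, 0.01),
               noise = rnorm(n))
    fm <- FeatureMatrix(x, data.frame(feature_id = colnames(x), source_set = "E",
                                      window_tag = NA, name = colnames(x)),
                        data.frame(person_id = sprintf("p%03d", 1:n),
                                   index_date = as.Date("2019-01-01")))
    for (alg in c("LR", "XGB", "RF")) {
      m <- tuneAndTrain(fm, y, modelSpec(alg, seed = 11))
      expect_equal(computeMetrics(y, predictRisk(m, fm))$auroc, 1.0,
                   tolerance = 1e-8)
      m2 <- tuneAndTrain(fm, y, modelSpec(alg, seed = 11))
      expect_identical(m$params, m2$params)
      expect_identical(predictRisk(m, fm), predictRisk(m2, fm))
    }
    expect_error(tuneAndTrain(fm, rep(1, n), modelSpec("LR")), "single class")
  })
})

test_that("labels independent of features give chance-level test AUROC", {
  withr::with_seed(13, {
    n <- 2000
    y <- rbinom(n, 1, 0.5)
    x <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
    fm <- FeatureMatrix(x, data.frame(feature_id = colnames(x), source_set = "E",
                                      window_tag = NA, name = colnames(x)),
                        data.frame(person_id = sprintf("p%04d", 1:n),
                                   index_date = as.Date("2019-01-01")))
    sp <- splitSubjectLevel(observationKeys(fm), 0.25, seed = 3)
    m <- tuneAndTrain(FeatureMatrix(x[sp$train, ],
                                    featureInfo(fm),
                                    observationKeys(fm)[sp$train, ]),
                      y[sp$train], modelSpec("LR", seed = 4))
    auc <- computeMetrics(y[sp$test],
                          predictRisk(m, FeatureMatrix(x[sp$test, ],
                                                       featureInfo(fm),
                                                       observationKeys(fm)[sp$test, ])))$auroc
    expect_gt(auc, 0.45)
    expect_lt(auc, 0.55)
  })
})

test_that("a single-task grid yields 7 x algorithms models with two validation records each", {
  task <- defaultTasks()$asthma
  pair <- simulateSystemPair(
    systemProfile("A", n_patients = 220, notes_per_obs_median = 6,
                  words_per_note_median = 8),
    systemProfile("B", n_patients = 120, notes_per_obs_median = 6,
                  words_per_note_median = 8, vocab_shift = 0.3),
    defaultSignal("asthma"), task, seed = 19)
  res <- runExperiment(list(asthma = list(task = task, datasets = pair)),
                       algorithms = "LR", seed = 23)
  expect_identical(nrow(res$records), 14L) # 7 combos x 1 algorithm x 2 validations
  expect_identical(length(res$models), 7L)
  counts <- table(res$records$combo, res$records$validation_type)
  expect_true(all(counts == 1))
  expect_true(all(res$records$auroc >= 0 & res$records$auroc <= 1))
  expect_true(all(res$records$brier >= 0 & res$records$brier <= 1))
  # predictions persisted for every validated observation
  chB <- buildCohort(pair$B, task)
  ext <- res$predictions[res$predictions$validation_type == "external" &
                           res$predictions$combo == "S", ]
  expect_identical(nrow(ext), nrow(chB))

  # vocabulary fitted on the training partition only: refit independently
  chA <- buildCohort(pair$A, task)
  sp <- splitSubjectLevel(chA, 0.25,
                          seed = notepredict:::.childSeed(23, "split-asthma"))
  plWant <- fitTextPipeline(buildDocuments(chA[sp$train, ], pair$A), seed = 23)
  expect_identical(res$pipelines$asthma@vocabulary, plWant@vocabulary)
  expect_identical(res$pipelines$asthma@df, plWant@df)

  # external matrices contain exactly the training feature space
  extT <- vectorizeBinary(buildDocuments(chB, pair$B), res$pipelines$asthma)
  expect_identical(featureInfo(extT)$feature_id,
                   paste0("Tterm:", res$pipelines$asthma@vocabulary))
})

test_that("model training aligns features by id, not column position", {
  withr::with_seed(21, {
    n <- 80
    y <- rbinom(n, 1, 0.5); y[1:2] <- 0:1
    x <- cbind(a = rnorm(n) + 2 * y, b = rnorm(n), c = rnorm(n))
    fi <- data.frame(feature_id = colnames(x), source_set = "E",
                     window_tag = NA, name = colnames(x))
    obs <- data.frame(person_id = sprintf("p%03d", 1:n),
                      index_date = as.Date("2019-01-01"))
    fm <- FeatureMatrix(x, fi, obs)
    m <- tuneAndTrain(fm, y, modelSpec("LR", seed = 2))
    shuffled <- FeatureMatrix(x[, c(3, 1, 2)], fi[c(3, 1, 2), ], obs)
    expect_equal(predictRisk(m, shuffled), predictRisk(m, fm))
  })
})
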