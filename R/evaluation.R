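#' @include utils.R
NULL

#' Discrimination, calibration and F1-threshold metrics
#'
#' Computes the full metric fragment for one validated model:
#' \itemize{
#'   \item AUROC via the rank (Mann-Whitney) formulation with midrank tie
#'     correction;
#'   \item AUPRC as the area under the precision-recall step function
#'     (average precision);
#'   \item Brier score, the mean squared difference between predicted
#'     probability and observed outcome;
#'   \item precision, recall and F1 at the probability threshold that
#'     maximizes F1, found by exhaustive scan over the unique predicted
#'     probabilities (predict positive when probability >= threshold; ties
#'     in F1 are broken toward the higher threshold).
#' }
#'
#' @param labels 0/1 vector with at least one positive and one negative.
#' @param probabilities predicted probabilities in [0, 1].
#' @return named list: \code{auroc}, \code{auprc}, \code{brier},
#'   \code{precision}, \code{recall}, \code{f1}, \code{threshold}.
#' @export
computeMetrics <- function(labels, probabilities) {
  labels <- as.integer(labels)
  if (length(labels) != length(probabilities)) {
    .stopf("labels and probabilities differ in length")
  }
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    .stopf("undefined-metric error: labels contain a single class")
  }
  r <- rank(probabilities) # midranks handle ties
  auroc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # average precision over the PR step function, thresholds descending
  ord <- order(probabilities, decreasing = TRUE)
  p <- probabilities[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1L - y)
  last <- c(p[-1L] != p[-length(p)], TRUE) # block ends of tied probabilities
  tpB <- tp[last]
  fpB <- fp[last]
  prec <- tpB / (tpB + fpB)
  recall <- tpB / n1
  auprc <- sum(diff(c(0, recall)) * prec)

  brier <- mean((probabilities - labels)^2)

  thr <- sort(unique(probabilities), decreasing = TRUE)
  bestF1 <- -1; bestI <- 1L
  f1s <- vapply(thr, function(t) {
    pred <- probabilities >= t
    tp_ <- sum(pred & labels == 1L)
    if (tp_ == 0L) return(0)
    pr <- tp_ / sum(pred)
    rc <- tp_ / n1
    2 * pr * rc / (pr + rc)
  }, numeric(1))
  bestI <- which.max(f1s) # first (= highest threshold) among ties
  t <- thr[bestI]
  pred <- probabilities >= t
  tp_ <- sum(pred & labels == 1L)
  precision <- if (sum(pred)) tp_ / sum(pred) else 0
  rec <- tp_ / n1
  f1 <- if (precision + rec > 0) 2 * precision * rec / (precision + rec) else 0
  list(auroc = auroc, auprc = auprc, brier = brier,
       precision = precision, recall = rec, f1 = f1, threshold = t)
}

#' Median-center evaluation metrics within groups
#'
#' Subtracts the group median of a metric from every value in the group, so
#' that representation and algorithm effects can be compared across tasks
#' and feature-set combinations on a common scale.
#'
#' @param records evaluation-record data.frame (one row per validated model).
#' @param metric column to center (default \code{"auroc"}).
#' @param groupBy grouping columns; default task, validation type and
#'   feature combo.
#' @return \code{records} with an added column \code{<metric>_centered}.
#' @export
medianCenter <- function(records, metric = "auroc",
                         groupBy = c("task", "validation_type", "combo")) {
  g <- interaction(records[groupBy], drop = TRUE)
  med <- stats::ave(records[[metric]], g, FUN = stats::median)
  records[[paste0(metric, "_centered")]] <- records[[metric]] - med
  records
}

.comboFamily <- function(combo) {
  ifelse(combo == "S", "S", ifelse(grepl("^ST_", combo), "S+T", "T"))
}

#' Compare feature-set families with Bonferroni-adjusted Wilcoxon tests
#'
#' Within each (task, validation type) cell, compares the metric values of
#' the structured (S), text (T) and combined (S+T) model families pairwise
#' with two-sided unpaired Wilcoxon rank-sum tests (exact enumeration when
#' both groups have at most 10 untied values, normal approximation with tie
#' correction otherwise). P values are Bonferroni-adjusted over the pairs
#' tested within the same (task, validation type, metric) analysis.
#'
#' @param records evaluation-record data.frame with columns \code{task},
#'   \code{validation_type}, \code{combo} and the metric.
#' @param metric metric column (default \code{"auroc"}).
#' @return data.frame with one row per (task, validation type, family pair):
#'   the rank-sum statistic, raw and adjusted p values and group medians.
#' @export
compareCombos <- function(records, metric = "auroc") {
  records$family <- .comboFamily(records$combo)
  out <- list()
  for (task in unique(records$task)) {
    for (vt in unique(records$validation_type)) {
      sub <- records[records$task == task & records$validation_type == vt, ]
      fams <- intersect(c("S", "T", "S+T"), unique(sub$family))
      pairs <- utils::combn(fams, 2L, simplify = FALSE)
      if (!length(pairs)) next
      rows <- lapply(pairs, function(pr) {
        x <- sub[[metric]][sub$family == pr[1L]]
        y <- sub[[metric]][sub$family == pr[2L]]
        if (length(x) < 2L || length(y) < 2L) return(NULL)
        ties <- anyDuplicated(c(x, y)) > 0L
        wt <- suppressWarnings(stats::wilcox.test(
          x, y, alternative = "two.sided",
          exact = !ties && length(x) <= 10L && length(y) <= 10L,
          correct = TRUE))
        data.frame(task = task, validation_type = vt, metric = metric,
                   family_a = pr[1L], family_b = pr[2L],
                   median_a = stats::median(x), median_b = stats::median(y),
                   statistic = unname(wt$statistic), p_raw = wt$p.value,
                   stringsAsFactors = FALSE)
      })
      rows <- do.call(rbind, rows)
      if (!is.null(rows) && nrow(rows)) {
        rows$p_adjusted <- pmin(1, rows$p_raw * nrow(rows))
        out[[length(out) + 1L]] <- rows
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.multBand <- function(r) {
  ifelse(r > 0.8, "very strong",
         ifelse(r > 0.6, "strong",
                ifelse(r > 0.4, "moderate", "weak")))
}

#' Predictive multiplicity between model families
#'
#' For each task and validation type, computes the Pearson correlation of
#' predicted probabilities between paired models of different feature-set
#' families (S vs T, S vs S+T, T vs S+T), pairing models that share the
#' prediction algorithm (and, for T vs S+T, the text representation), then
#' averages the correlations across representation and algorithm cells.
#' Qualitative bands follow the thresholds r > .8 (very strong),
#' .8 > r > .6 (strong), .6 > r > .4 (moderate).
#'
#' @param predictions data.frame with columns \code{task}, \code{combo},
#'   \code{algorithm}, \code{validation_type}, \code{person_id},
#'   \code{index_date}, \code{probability} (one row per observation scored
#'   by one model).
#' @return data.frame with mean Pearson r and band per (task, validation
#'   type, family pair), plus the number of model pairs averaged.
#' @export
predictionMultiplicity <- function(predictions) {
  predictions$family <- .comboFamily(predictions$combo)
  predictions$rep <- sub("^S?T_", "", predictions$combo)
  predictions$rep[predictions$family == "S"] <- NA
  key <- function(df) paste(df$person_id, df$index_date)
  out <- list()
  for (task in unique(predictions$task)) {
    for (vt in unique(predictions$validation_type)) {
      sub <- predictions[predictions$task == task &
                           predictions$validation_type == vt, ]
      algs <- unique(sub$algorithm)
      reps <- unique(stats::na.omit(sub$rep))
      cellProb <- function(combo, alg) {
        cc <- sub[sub$combo == combo & sub$algorithm == alg, ]
        cc[order(key(cc)), "probability"]
      }
      pairDefs <- list(`S vs T` = c("S", "T"), `S vs S+T` = c("S", "S+T"),
                       `T vs S+T` = c("T", "S+T"))
      for (pn in names(pairDefs)) {
        pd <- pairDefs[[pn]]
        rs <- numeric(0)
        for (alg in algs) {
          for (rp in reps) {
            comboOf <- function(fam) {
              switch(fam, S = "S", T = paste0("T_", rp),
                     `S+T` = paste0("ST_", rp))
            }
            a <- cellProb(comboOf(pd[1L]), alg)
            b <- cellProb(comboOf(pd[2L]), alg)
            if (length(a) && length(a) == length(b) &&
                stats::sd(a) > 0 && stats::sd(b) > 0) {
              # pairs with a constant-prediction model have undefined r
              # and are dropped from the average
              rs <- c(rs, stats::cor(a, b))
            }
          }
        }
        if (length(rs)) {
          out[[length(out) + 1L]] <- data.frame(
            task = task, validation_type = vt, pair = pn,
            pearson_r = mean(rs), n_model_pairs = length(rs),
            band = .multBand(mean(rs)), stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Top-k feature importance of a trained model
#'
#' Importance is the absolute fitted beta for L1 logistic regression (signed
#' values reported), the impurity decrease for random forests, and the gain
#' for gradient boosting. Features with zero importance are dropped; at most
#' \code{k} features are returned (all of them if fewer).
#'
#' @param model a \code{TrainedModel} from \code{\link{tuneAndTrain}}.
#' @param k number of features to return (k = 0 gives an empty table).
#' @return data.frame: \code{rank}, \code{feature_id}, \code{name},
#'   \code{source_set}, \code{importance} (signed for LR),
#'   \code{abs_importance}.
#' @export
featureImportance <- function(model, k = 10) {
  stopifnot(inherits(model, "TrainedModel"))
  fi <- model$featureInfo
  imp <- switch(model$algorithm,
    LR = {
      beta <- as.numeric(model$betas)
      names(beta) <- model$featureIds
      beta
    },
    RF = {
      v <- model$fit$variable.importance
      stats::setNames(as.numeric(v), names(v))
    },
    XGB = {
      it <- xgboost::xgb.importance(model = model$fit)
      stats::setNames(it$Gain, it$Feature)
    },
    .stopf("unknown algorithm '%s'", model$algorithm))
  imp <- imp[!is.na(imp) & imp != 0]
  if (k <= 0L || !length(imp)) {
    return(data.frame(rank = integer(), feature_id = character(),
                      name = character(), source_set = character(),
                      importance = numeric(), abs_importance = numeric(),
                      stringsAsFactors = FALSE))
  }
  ord <- order(abs(imp), decreasing = TRUE)
  top <- ord[seq_len(min(k, length(ord)))]
  ids <- names(imp)[top]
  m <- match(ids, fi$feature_id)
  data.frame(rank = seq_along(top), feature_id = ids,
             name = fi$name[m], source_set = fi$source_set[m],
             importance = as.numeric(imp[top]),
             abs_importance = abs(as.numeric(imp[top])),
             stringsAsFactors = FALSE)
}
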