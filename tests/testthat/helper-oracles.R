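# independent brute-force metric oracles shared across test files
concordanceAUROC <- function(labels, probs) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

sweepAUPRC <- function(labels, probs) {
  thr <- sort(unique(probs), decreasing = TRUE)
  rec <- 0; ap <- 0
  for (t in thr) {
    pred <- probs >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    r <- tp / sum(labels == 1)
    ap <- ap + (r - rec) * prec
    rec <- r
  }
  ap
}

sweepF1 <- function(labels, probs) {
  best <- c(f1 = -1, threshold = NA)
  for (t in sort(unique(probs), decreasing = TRUE)) {
    pred <- probs >= t
    tp <- sum(pred & labels == 1)
    prec <- if (sum(pred)) tp / sum(pred) else 0
    rec <- tp / sum(labels == 1)
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    if (f1 > best["f1"]) best <- c(f1 = f1, threshold = t)
  }
  best
}

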