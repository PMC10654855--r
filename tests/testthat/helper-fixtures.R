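# fixtures built in code; no data files

# a tiny handmade dataset with known cohort structure
toyDataset <- function(systemId = "A") {
  persons <- data.frame(
    person_id = c("p1", "p2", "p3", "p4"),
    year_of_birth = c(1950L, 1980L, 1940L, 2005L),
    sex = c(1L, 0L, 1L, 0L),
    stringsAsFactors = FALSE)
  # p1: qualifies, outcome inside TAR
  # p2: only 200 days of prior observation -> excluded
  # p3: leaves the database mid-TAR -> excluded
  # p4: under-age at index -> excluded
  op <- data.frame(
    person_id = c("p1", "p2", "p3", "p4"),
    start_date = as.Date(c("2015-01-01", "2017-09-14", "2015-06-01", "2015-01-01")),
    end_date = as.Date(c("2019-12-31", "2019-12-31", "2018-04-15", "2019-12-31")),
    stringsAsFactors = FALSE)
  events <- data.frame(
    person_id = c("p1", "p1", "p1", "p2", "p3", "p4",
                  "p1", "p1"),
    domain = c("procedure", "condition", "drug", "procedure", "procedure",
               "procedure", "condition", "condition"),
    concept_code = c("tgt", "c1", "d1", "tgt", "tgt", "tgt", "out", "c2"),
    event_date = as.Date(c("2018-04-01", "2018-03-25", "2017-06-01",
                           "2018-04-01", "2018-04-01", "2018-04-01",
                           "2018-04-20", "2016-01-10")),
    stringsAsFactors = FALSE)
  notes <- data.frame(
    note_id = c("n1", "n2", "n3"),
    person_id = c("p1", "p1", "p2"),
    note_date = as.Date(c("2018-03-01", "2017-01-15", "2018-03-01")),
    note_class = c("gp", "communication", "gp"),
    text = c("Koorts en hoest. Geen aanwijzing voor pneumonie.",
             "Controle diabetes mellitus.",
             "Rugpijn na val."),
    stringsAsFactors = FALSE)
  EHRDataset(persons, events, notes, op, systemId = systemId)
}

toyTask <- function(...) {
  taskSpec("toy", target_domain = "procedure", target_code = "tgt",
           outcome_domain = "condition", outcome_code = "out",
           min_age = 18, tar_start_days = 1, tar_end_days = 30, ...)
}

# random small dataset for property tests (valid by construction)
randomDataset <- function(nPersons, seed, task = toyTask(),
                          pOutcome = 0.3, systemId = "A") {
  withr::with_seed(seed, {
    pid <- sprintf("r%03d", seq_len(nPersons))
    index <- as.Date("2018-01-01") + sample(0:600, nPersons, replace = TRUE)
    prior <- sample(c(100:400, 365:1200), nPersons, replace = TRUE)
    followup <- sample(0:200, nPersons, replace = TRUE)
    persons <- data.frame(person_id = pid,
                          year_of_birth = sample(1930:2003, nPersons, TRUE),
                          sex = sample(0:1, nPersons, TRUE))
    op <- data.frame(person_id = pid, start_date = index - prior,
                     end_date = index + followup)
    evs <- list(data.frame(person_id = pid, domain = task$target_domain,
                           concept_code = task$target_code, event_date = index))
    for (i in seq_len(nPersons)) {
      k <- sample(0:6, 1)
      if (k > 0) {
        span <- as.integer(op$end_date[i]) - as.integer(op$start_date[i])
        d <- as.Date(as.integer(op$start_date[i]) + sample(0:span, k, TRUE),
                     origin = "1970-01-01")
        evs[[length(evs) + 1L]] <- data.frame(
          person_id = pid[i],
          domain = sample(c("condition", "drug", "measurement"), k, TRUE),
          concept_code = sample(c("a", "b", "c", "d", task$outcome_code), k,
                                TRUE, prob = c(rep((1 - pOutcome) / 4, 4), pOutcome)),
          event_date = d)
      }
    }
    events <- do.call(rbind, evs)
    notes <- data.frame(note_id = character(), person_id = character(),
                        note_date = as.Date(character()),
                        note_class = character(), text = character())
    EHRDataset(persons, events, notes, op, systemId = systemId)
  })
}

# independent brute-force cohort construction (exhaustive scan)
bruteForceCohort <- function(dataset, task) {
  ev <- events(dataset)
  pers <- persons(dataset)
  op <- observationPeriods(dataset)
  rows <- list()
  tgt <- ev[ev$domain == task$target_domain &
              ev$concept_code == task$target_code, ]
  tgt <- unique(tgt[c("person_id", "event_date")])
  for (i in seq_len(nrow(tgt))) {
    p <- tgt$person_id[i]
    idx <- tgt$event_date[i]
    age <- as.integer(format(idx, "%Y")) -
      pers$year_of_birth[pers$person_id == p]
    if (age < task$min_age) next
    ok <- FALSE
    for (j in which(op$person_id == p)) {
      covers <- op$start_date[j] <= idx && idx <= op$end_date[j]
      if (covers &&
          as.integer(idx - op$start_date[j]) >= task$observation_days &&
          op$end_date[j] >= idx + task$tar_end_days) ok <- TRUE
    }
    if (!ok) next
    lab <- 0L
    for (j in which(ev$person_id == p &
                      ev$domain == task$outcome_domain &
                      ev$concept_code == task$outcome_code)) {
      if (ev$event_date[j] >= idx + task$tar_start_days &&
          ev$event_date[j] <= idx + task$tar_end_days) lab <- 1L
    }
    rows[[length(rows) + 1L]] <- data.frame(person_id = p, index_date = idx,
                                            label = lab,
                                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(person_id = character(), index_date = as.Date(character()),
                      label = integer()))
  }
  out <- out[order(out$person_id, out$index_date), ]
  if (!task$multiple_obs_per_patient) out <- out[!duplicated(out$person_id), ]
  rownames(out) <- NULL
  out
}

# independent brute-force ConText interpreter over one token sequence:
# scans trigger/terminator occurrences by direct subsequence comparison and
# assigns flags by explicit per-token scope walking
bruteForceContext <- function(tokens, mentions, rules, window = 10) {
  n <- length(tokens)
  covered <- rep(FALSE, n)
  for (k in seq_len(nrow(mentions))) {
    covered[(mentions$start[k] + 1L):mentions$end[k]] <- TRUE
  }
  occAt <- function(phr, i) {
    L <- length(phr)
    i + L - 1L <= n && all(tokens[i:(i + L - 1L)] == phr) &&
      !any(covered[i:(i + L - 1L)])
  }
  # leftmost-longest scan identical in spirit but written independently
  occs <- list()
  i <- 1L
  phrs <- strsplit(rules$trigger, " +")
  while (i <= n) {
    best <- 0L
    for (ri in order(-lengths(phrs))) {
      if (occAt(phrs[[ri]], i)) { best <- ri; break }
    }
    if (best) {
      occs[[length(occs) + 1L]] <- list(rule = best, start = i - 1L,
                                        end = i - 1L + length(phrs[[best]]))
      i <- i + length(phrs[[best]])
    } else i <- i + 1L
  }
  termBounds <- lapply(Filter(function(o) rules$terminator[o$rule], occs),
                       function(o) c(o$start, o$end))
  for (o in occs) {
    if (rules$terminator[o$rule]) next
    cat_ <- rules$category[o$rule]
    dir_ <- rules$direction[o$rule]
    for (k in seq_len(nrow(mentions))) {
      hitF <- hitB <- FALSE
      if (dir_ %in% c("forward", "bidirectional")) {
        lim <- min(n, o$end + window)
        for (tb in termBounds) if (tb[1] >= o$end) lim <- min(lim, tb[1])
        # token positions o$end .. lim-1 (0-based)
        span <- seq(o$end, length.out = max(0, lim - o$end))
        hitF <- any(span >= mentions$start[k] & span < mentions$end[k])
      }
      if (dir_ %in% c("backward", "bidirectional")) {
        lo <- max(0, o$start - window)
        for (tb in termBounds) if (tb[2] <= o$start) lo <- max(lo, tb[2])
        span <- seq(lo, length.out = max(0, o$start - lo))
        hitB <- any(span >= mentions$start[k] & span < mentions$end[k])
      }
      if (hitF || hitB) mentions[[cat_]][k] <- TRUE
    }
  }
  mentions
}
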