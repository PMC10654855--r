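#' @include AllClasses.R utils.R
NULL

# ---- language model for synthetic Dutch-like notes -------------------------

# Deterministic Dutch-like background vocabulary. The token inventory is a
# fixed property of the simulated "language" (independent of the dataset
# seed); vocab_shift renames a fraction of tokens in place, emulating the
# spelling/coding drift between GP EHR systems while keeping the underlying
# frequency distribution identical.
.SYLLABLES <- c(
  "ba", "be", "bo", "da", "de", "do", "ga", "ge", "go", "ka", "ke", "ko",
  "la", "le", "lo", "ma", "me", "mo", "na", "ne", "no", "pa", "pe", "po",
  "ra", "re", "ro", "sa", "se", "so", "ta", "te", "to", "va", "ve", "vo",
  "wa", "we", "wo", "zu", "ij", "ui", "oe", "aa", "ee", "oo", "en", "er",
  "el", "an", "in", "on", "eur", "ing", "lijk", "heid", "acht", "sch")

#' Synthetic background vocabulary
#'
#' Builds the Zipf-distributed Dutch-like token inventory used by
#' \code{\link{simulateEHR}}. The inventory is deterministic (it does not
#' depend on the simulation seed); \code{vocab_shift} renames the given
#' fraction of tokens to unseen variants, which is how a second EHR system's
#' vocabulary drift is emulated. Tokens listed in \code{exclude} (planted
#' signal terms, lexicon phrases) are never generated and never renamed.
#'
#' @param size number of background tokens.
#' @param vocab_shift fraction in [0, 1] of tokens renamed relative to the
#'   unshifted inventory.
#' @param exclude tokens that must not appear in the inventory.
#' @return character vector of length \code{size}; Zipf sampling weight is
#'   proportional to 1/rank^1.05 of the position in the vector.
#' @export
syntheticVocabulary <- function(size = 2000, vocab_shift = 0, exclude = character()) {
  size <- .assertCount(size, "vocabulary size")
  if (vocab_shift < 0 || vocab_shift > 1) {
    .stopf("configuration error: vocab_shift must lie in [0,1]")
  }
  vocab <- .withSeed(424242L, {
    n <- size + 400L
    tok <- character(0)
    while (length(tok) < n) {
      more <- vapply(seq_len(n), function(i) {
        paste(sample(.SYLLABLES, sample(2:4, 1L), replace = TRUE), collapse = "")
      }, character(1))
      tok <- unique(c(tok, more))
      tok <- tok[nchar(tok) >= 4L]
    }
    tok
  })
  vocab <- setdiff(vocab, tolower(exclude))[seq_len(size)]
  if (vocab_shift > 0) {
    k <- floor(vocab_shift * size)
    if (k > 0) {
      idx <- .withSeed(151515L, sample.int(size))[seq_len(k)]
      renamed <- paste0(vocab[idx], "s")
      while (any(renamed %in% c(vocab, tolower(exclude)))) {
        clash <- renamed %in% c(vocab, tolower(exclude))
        renamed[clash] <- paste0(renamed[clash], "x")
      }
      vocab[idx] <- renamed
    }
  }
  vocab
}

.zipfWeights <- function(n, s = 1.05) {
  w <- 1 / seq_len(n)^s
  w / sum(w)
}

.domainCodes <- function(domain, n = 250L) {
  sprintf("%s%03d", substr(domain, 1L, 4L), seq_len(n))
}

.DOMAINS <- c("condition", "drug", "measurement", "procedure")

# Dutch clinical distractor phrases inserted into notes (they match the
# bundled toy lexicon so concept extraction has realistic non-signal hits)
.DISTRACTOR_PHRASES <- c(
  "hoest", "koorts", "hypertensie", "pneumonie", "rugpijn", "hoofdpijn",
  "diabetes mellitus", "eczeem", "duizeligheid", "moeheid", "obstipatie")
.NEGATION_PREFIXES <- c("geen", "geen aanwijzing voor", "niet")

# ---- configuration objects -------------------------------------------------

#' System profile for the synthetic EHR generator
#'
#' Describes one emulated EHR-system population: its size, the per-observation
#' note and event volume (medians of the generated Poisson counts), and the
#' vocabulary drift relative to the reference system.
#'
#' @param system_id label (e.g. "A", "B").
#' @param n_patients number of patients.
#' @param notes_per_obs_median median number of notes per 365-day observation.
#' @param words_per_note_median median number of words per note.
#' @param events_per_obs_median named numeric vector of per-domain median
#'   event counts per observation (names: condition, drug, measurement,
#'   procedure).
#' @param vocab_shift fraction of background vocabulary renamed relative to
#'   the unshifted inventory (planted signal terms are never renamed).
#' @param gp_note_fraction fraction of notes of class "gp" (rest are
#'   "communication").
#' @return a \code{SystemProfile} list.
#' @export
systemProfile <- function(system_id = "A", n_patients = 1000,
                          notes_per_obs_median = 35,
                          words_per_note_median = 12,
                          events_per_obs_median = c(condition = 14, drug = 7,
                                                    measurement = 20, procedure = 1),
                          vocab_shift = 0, gp_note_fraction = 0.9) {
  n_patients <- .assertCount(n_patients, "n_patients")
  notes_per_obs_median <- .assertCount(notes_per_obs_median, "notes_per_obs_median")
  words_per_note_median <- .assertCount(words_per_note_median, "words_per_note_median")
  if (is.null(names(events_per_obs_median)) ||
      !all(.DOMAINS %in% names(events_per_obs_median))) {
    .stopf("configuration error: events_per_obs_median must name all domains: %s",
           paste(.DOMAINS, collapse = ", "))
  }
  if (any(events_per_obs_median < 0)) {
    .stopf("configuration error: events_per_obs_median must be non-negative")
  }
  if (vocab_shift < 0 || vocab_shift > 1) {
    .stopf("configuration error: vocab_shift must lie in [0,1]")
  }
  structure(list(system_id = as.character(system_id), n_patients = n_patients,
                 notes_per_obs_median = notes_per_obs_median,
                 words_per_note_median = words_per_note_median,
                 events_per_obs_median = events_per_obs_median[.DOMAINS],
                 vocab_shift = vocab_shift,
                 gp_note_fraction = gp_note_fraction),
            class = "SystemProfile")
}

#' Planted outcome-signal specification
#'
#' The outcome label of each observation is drawn from a logistic model
#' \eqn{logit(p) = b_0 + \sum_t w_t X_t + \sum_c w_c X_c + \epsilon} where
#' \eqn{X_t} indicates that signal term \eqn{t} was planted in the
#' observation's notes, \eqn{X_c} that signal event code \eqn{c} was planted
#' in its event history, and \eqn{\epsilon \sim N(0, noise\_sd^2)}.
#'
#' @param text_signal_terms data.frame with columns \code{token},
#'   \code{weight} (log-odds per presence); may have zero rows.
#' @param event_signal_codes data.frame with columns \code{code},
#'   \code{domain}, \code{weight}; may have zero rows.
#' @param baseline_log_odds intercept \eqn{b_0}.
#' @param noise_sd standard deviation of the latent noise (>= 0).
#' @param signal_prevalence Bernoulli probability that each signal indicator
#'   is planted in an observation.
#' @return a \code{SignalSpec} list.
#' @export
signalSpec <- function(text_signal_terms = data.frame(token = character(),
                                                      weight = numeric()),
                       event_signal_codes = data.frame(code = character(),
                                                       domain = character(),
                                                       weight = numeric()),
                       baseline_log_odds = 0, noise_sd = 0,
                       signal_prevalence = 0.3) {
  if (noise_sd < 0) .stopf("configuration error: noise_sd must be >= 0")
  if (nrow(event_signal_codes) && is.null(event_signal_codes$domain)) {
    event_signal_codes$domain <- "condition"
  }
  structure(list(text_signal_terms = text_signal_terms,
                 event_signal_codes = event_signal_codes,
                 baseline_log_odds = baseline_log_odds, noise_sd = noise_sd,
                 signal_prevalence = signal_prevalence),
            class = "SignalSpec")
}

#' Prediction task specification
#'
#' Defines a patient-level prediction problem: which event defines the index
#' date (the target event), which event constitutes the outcome, the
#' time-at-risk window after the index date, and the required prior
#' observation time. Observations with less than \code{observation_days} of
#' prior observation, or whose observation period ends before the end of the
#' time-at-risk (loss to follow-up), are excluded by
#' \code{\link{buildCohort}}.
#'
#' @param task_id short task label.
#' @param target_domain,target_code the event defining index dates.
#' @param outcome_domain,outcome_code the outcome event sought in the
#'   time-at-risk window.
#' @param min_age minimum age (years) at index.
#' @param tar_start_days,tar_end_days closed time-at-risk window
#'   [index + tar_start_days, index + tar_end_days].
#' @param observation_days required days of observation before the index
#'   date (covariate window), default 365.
#' @param multiple_obs_per_patient if FALSE (default) only the earliest
#'   qualifying index date per person is kept.
#' @return a \code{TaskSpec} list.
#' @export
taskSpec <- function(task_id, target_domain = "procedure", target_code,
                     outcome_domain = "condition", outcome_code,
                     min_age = 18, tar_start_days = 1, tar_end_days = 365,
                     observation_days = 365,
                     multiple_obs_per_patient = FALSE) {
  tar_start_days <- .assertCount(tar_start_days, "tar_start_days")
  tar_end_days <- .assertCount(tar_end_days, "tar_end_days")
  if (tar_start_days > tar_end_days) {
    .stopf("configuration error: tar_start_days must be <= tar_end_days")
  }
  structure(list(task_id = as.character(task_id),
                 target_domain = target_domain, target_code = target_code,
                 outcome_domain = outcome_domain, outcome_code = outcome_code,
                 min_age = min_age, tar_start_days = tar_start_days,
                 tar_end_days = tar_end_days,
                 observation_days = .assertCount(observation_days, "observation_days"),
                 multiple_obs_per_patient = isTRUE(multiple_obs_per_patient)),
            class = "TaskSpec")
}

#' Default benchmark tasks
#'
#' Four synthetic prediction tasks mirroring common GP prediction problems
#' and their time-at-risk designs: 30-day hospital readmission (2-30 days,
#' multiple observations per patient allowed), first end-of-life conversation
#' within a year (1-365 days, age 60+), asthma exacerbation within two years
#' (1-730 days) and mortality after COPD diagnosis within two years
#' (1-730 days).
#'
#' @return named list of four \code{TaskSpec}s.
#' @export
defaultTasks <- function() {
  list(
    readmission = taskSpec("readmission", "procedure", "discharge",
                           "procedure", "readmit", min_age = 18,
                           tar_start_days = 2, tar_end_days = 30,
                           multiple_obs_per_patient = TRUE),
    endoflife = taskSpec("endoflife", "procedure", "gpvisit",
                         "procedure", "eolconv", min_age = 60,
                         tar_start_days = 1, tar_end_days = 365),
    asthma = taskSpec("asthma", "condition", "asthmadx",
                      "condition", "asthmaexac", min_age = 18,
                      tar_start_days = 1, tar_end_days = 730),
    copd = taskSpec("copd", "condition", "copddx",
                    "condition", "death", min_age = 18,
                    tar_start_days = 1, tar_end_days = 730)
  )
}

#' Default planted signals per task
#'
#' Each task plants two text terms and two coded events with positive
#' log-odds weights; baselines are set so that outcome prevalence falls in
#' the 0.04-0.46 range typical of GP prediction problems.
#'
#' @param task_id one of the \code{\link{defaultTasks}} ids.
#' @return a \code{SignalSpec}.
#' @export
defaultSignal <- function(task_id = c("readmission", "endoflife", "asthma", "copd")) {
  task_id <- match.arg(task_id)
  base <- c(readmission = -3.3, endoflife = -4.3, asthma = -1.8, copd = -3.4)
  terms <- switch(task_id,
    readmission = data.frame(token = c("opname", "tumor"), weight = c(1.5, 1.0)),
    endoflife = data.frame(token = c("kanker", "palliatieve"), weight = c(1.6, 1.2)),
    asthma = data.frame(token = c("benauwd", "prednison"), weight = c(1.4, 1.0)),
    copd = data.frame(token = c("zuurstof", "vermagering"), weight = c(1.5, 1.0)))
  codes <- data.frame(code = paste0("sig", task_id, c("1", "2")),
                      domain = c("condition", "drug"), weight = c(1.2, 0.9))
  signalSpec(terms, codes, baseline_log_odds = unname(base[task_id]),
             noise_sd = 0, signal_prevalence = 0.3)
}

#' Default system profiles
#'
#' Two emulated EHR systems at desk scale: system A (the larger, used for
#' training and internal validation) and system B (smaller, higher note
#' volume, 30% vocabulary drift), mirroring the kind of surface differences
#' seen between GP EHR systems.
#'
#' @param n_a,n_b number of patients per system.
#' @return named list of two \code{SystemProfile}s.
#' @export
defaultProfiles <- function(n_a = 700, n_b = 450) {
  list(
    A = systemProfile("A", n_patients = n_a, notes_per_obs_median = 35,
                      words_per_note_median = 12,
                      events_per_obs_median = c(condition = 14, drug = 7,
                                                measurement = 20, procedure = 1),
                      vocab_shift = 0),
    B = systemProfile("B", n_patients = n_b, notes_per_obs_median = 45,
                      words_per_note_median = 12,
                      events_per_obs_median = c(condition = 9, drug = 10,
                                                measurement = 24, procedure = 3),
                      vocab_shift = 0.3)
  )
}

# ---- the generator ---------------------------------------------------------

.makeNoteText <- function(tokens, sentenceSep) {
  if (!length(tokens)) return("")
  breaks <- cumsum(pmax(2L, stats::rpois(length(tokens), 4L)))
  breaks <- breaks[breaks < length(tokens)]
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(tokens))
  sentences <- vapply(seq_along(starts), function(i) {
    paste(tokens[starts[i]:ends[i]], collapse = " ")
  }, character(1))
  paste(sentences, collapse = sentenceSep)
}

#' Simulate one synthetic GP EHR dataset
#'
#' Generates the four OMOP-CDM-style tables for one EHR-system population
#' under a task design and a planted signal specification. Notes are bags of
#' Zipf-distributed Dutch-like tokens arranged into short sentences (no
#' grammar); outcome labels are drawn from the logistic model of
#' \code{\link{signalSpec}} and realized as outcome events inside the
#' time-at-risk window. Observation periods are generated so that a
#' controlled fraction of observations violates the prior-observation and
#' follow-up rules, exercising cohort exclusion logic downstream.
#' The same seed always produces byte-identical tables.
#'
#' @param profile a \code{\link{systemProfile}}.
#' @param signal a \code{\link{signalSpec}}.
#' @param task a \code{\link{taskSpec}}.
#' @param seed integer seed.
#' @param vocab_size background vocabulary size.
#' @param short_obs_prob fraction of first observations given less than the
#'   required prior observation time.
#' @param dropout_prob fraction of persons leaving the database before the
#'   end of the time-at-risk.
#' @return an \linkS4class{EHRDataset}.
#' @export
simulateEHR <- function(profile, signal, task, seed, vocab_size = 2000,
                        short_obs_prob = 0.08, dropout_prob = 0.08) {
  stopifnot(inherits(profile, "SystemProfile"), inherits(signal, "SignalSpec"),
            inherits(task, "TaskSpec"))
  sigTerms <- signal$text_signal_terms
  reserved <- c(tolower(sigTerms$token),
                unlist(strsplit(tolower(.DISTRACTOR_PHRASES), " ")),
                unlist(strsplit(.NEGATION_PREFIXES, " ")))
  vocab <- syntheticVocabulary(vocab_size, profile$vocab_shift, exclude = reserved)
  vw <- .zipfWeights(length(vocab))
  distractors <- setdiff(.DISTRACTOR_PHRASES, tolower(sigTerms$token))

  codeSpace <- lapply(.DOMAINS, .domainCodes)
  names(codeSpace) <- .DOMAINS
  codeW <- lapply(codeSpace, function(cs) .zipfWeights(length(cs), 1.0))

  studyStart <- as.Date("2016-01-01")
  studyDays <- 1826L

  .withSeed(seed, {
    n <- profile$n_patients
    index1 <- studyStart + sample.int(studyDays, n, replace = TRUE) - 1L
    age <- pmin(95L, pmax(task$min_age,
                          round(stats::rnorm(n, task$min_age + 28, 12))))
    yob <- as.integer(format(index1, "%Y")) - age
    sex <- stats::rbinom(n, 1L, 0.5)
    pid <- sprintf("%s%05d", profile$system_id, seq_len(n))

    short <- stats::runif(n) < short_obs_prob
    priorDays <- ifelse(short,
                        sample(30:(task$observation_days - 1L), n, replace = TRUE),
                        sample(task$observation_days:2190, n, replace = TRUE))
    opStart <- index1 - priorDays
    dropout <- stats::runif(n) < dropout_prob
    opEnd <- as.Date(ifelse(dropout,
                            index1 + sample(0:(task$tar_end_days - 1L), n, replace = TRUE),
                            index1 + task$tar_end_days + sample(0:365, n, replace = TRUE)),
                     origin = "1970-01-01")

    persons <- data.frame(person_id = pid, year_of_birth = yob, sex = sex,
                          stringsAsFactors = FALSE)
    op <- data.frame(person_id = pid, start_date = opStart, end_date = opEnd,
                     stringsAsFactors = FALSE)

    # observation list: (person row, index date)
    obsPerson <- seq_len(n)
    obsIndex <- index1
    if (task$multiple_obs_per_patient) {
      for (i in seq_len(n)) {
        lo <- as.integer(index1[i]) + task$tar_end_days + 2L
        hi <- as.integer(opEnd[i]) - 1L
        extra <- stats::rpois(1L, 0.35)
        if (extra > 0L && hi > lo) {
          d <- as.Date(sample(lo:hi, min(extra, 2L), replace = FALSE),
                       origin = "1970-01-01")
          obsPerson <- c(obsPerson, rep(i, length(d)))
          obsIndex <- c(obsIndex, d)
        }
      }
    }
    nObs <- length(obsPerson)

    nTerms <- nrow(sigTerms)
    nCodes <- nrow(signal$event_signal_codes)
    Xt <- matrix(stats::rbinom(nObs * nTerms, 1L, signal$signal_prevalence),
                 nrow = nObs, ncol = nTerms)
    Xc <- matrix(stats::rbinom(nObs * nCodes, 1L, signal$signal_prevalence),
                 nrow = nObs, ncol = nCodes)
    z <- signal$baseline_log_odds +
      (if (nTerms) drop(Xt %*% sigTerms$weight) else 0) +
      (if (nCodes) drop(Xc %*% signal$event_signal_codes$weight) else 0) +
      (if (signal$noise_sd > 0) stats::rnorm(nObs, 0, signal$noise_sd) else 0)
    y <- stats::rbinom(nObs, 1L, stats::plogis(z))

    evList <- vector("list", nObs)
    noteList <- vector("list", nObs)
    noteCounter <- 0L

    for (o in seq_len(nObs)) {
      i <- obsPerson[o]
      idx <- obsIndex[o]
      winStart <- max(opStart[i], idx - task$observation_days)
      winDays <- as.integer(idx - winStart) # days in [winStart, idx-1]

      # --- events ---
      evDomain <- character(0); evCode <- character(0); evDate <- integer(0)
      for (d in .DOMAINS) {
        k <- stats::rpois(1L, profile$events_per_obs_median[[d]])
        if (k > 0L) {
          evDomain <- c(evDomain, rep(d, k))
          evCode <- c(evCode, sample(codeSpace[[d]], k, replace = TRUE,
                                     prob = codeW[[d]]))
          inWin <- stats::runif(k) < 0.85
          dts <- integer(k)
          dts[inWin] <- as.integer(winStart) + sample.int(winDays, sum(inWin),
                                                          replace = TRUE) - 1L
          if (any(!inWin)) {
            span <- as.integer(opEnd[i]) - as.integer(opStart[i])
            dts[!inWin] <- as.integer(opStart[i]) +
              sample.int(span + 1L, sum(!inWin), replace = TRUE) - 1L
          }
          evDate <- c(evDate, dts)
        }
      }
      # planted event signals
      if (nCodes) {
        for (cix in which(Xc[o, ] == 1L)) {
          evDomain <- c(evDomain, signal$event_signal_codes$domain[cix])
          evCode <- c(evCode, signal$event_signal_codes$code[cix])
          evDate <- c(evDate, as.integer(winStart) + sample.int(winDays, 1L) - 1L)
        }
      }
      # target event at the index date
      evDomain <- c(evDomain, task$target_domain)
      evCode <- c(evCode, task$target_code)
      evDate <- c(evDate, as.integer(idx))
      # outcome event inside TAR (only realizable before end of observation)
      if (y[o] == 1L) {
        od <- as.integer(idx) + sample(task$tar_start_days:task$tar_end_days, 1L)
        if (od <= as.integer(opEnd[i])) {
          evDomain <- c(evDomain, task$outcome_domain)
          evCode <- c(evCode, task$outcome_code)
          evDate <- c(evDate, od)
        }
      }
      evList[[o]] <- data.frame(person_id = pid[i], domain = evDomain,
                                concept_code = evCode,
                                event_date = as.Date(evDate, origin = "1970-01-01"),
                                stringsAsFactors = FALSE)

      # --- notes ---
      nNotes <- max(1L, stats::rpois(1L, profile$notes_per_obs_median))
      nd <- as.integer(winStart) + sample.int(winDays, nNotes, replace = TRUE) - 1L
      cls <- ifelse(stats::runif(nNotes) < profile$gp_note_fraction,
                    "gp", "communication")
      txt <- character(nNotes)
      for (j in seq_len(nNotes)) {
        nw <- max(3L, stats::rpois(1L, profile$words_per_note_median))
        toks <- sample(vocab, nw, replace = TRUE, prob = vw)
        sep <- if (stats::runif(1) < 0.3) "\n" else ". "
        body <- .makeNoteText(toks, sep)
        if (stats::runif(1) < 0.25) {
          phrase <- sample(distractors, 1L)
          if (stats::runif(1) < 0.3) {
            phrase <- paste(sample(.NEGATION_PREFIXES, 1L), phrase)
          }
          body <- paste0(body, sep, phrase)
        }
        if (stats::runif(1) < 0.2) {
          body <- paste0(body, sep, "rr ", sample(90:180, 1L), "/",
                         sample(50:110, 1L))
        }
        txt[j] <- paste0(body, ".")
      }
      # plant text signal terms into randomly chosen in-window notes
      if (nTerms) {
        for (tix in which(Xt[o, ] == 1L)) {
          j <- sample.int(nNotes, 1L)
          reps <- sample(1:2, 1L)
          txt[j] <- paste0(txt[j], " ",
                           paste(rep(sigTerms$token[tix], reps), collapse = ". "),
                           ".")
        }
      }
      noteList[[o]] <- data.frame(
        note_id = sprintf("%sN%07d", profile$system_id, noteCounter + seq_len(nNotes)),
        person_id = pid[i],
        note_date = as.Date(nd, origin = "1970-01-01"),
        note_class = cls, text = txt, stringsAsFactors = FALSE)
      noteCounter <- noteCounter + nNotes
    }

    eventsTab <- do.call(rbind, evList)
    notesTab <- do.call(rbind, noteList)
    rownames(eventsTab) <- rownames(notesTab) <- NULL
    EHRDataset(persons = persons, events = eventsTab, notes = notesTab,
               observationPeriods = op, systemId = profile$system_id)
  })
}

#' Simulate a pair of EHR-system datasets sharing the same outcome signal
#'
#' Draws two datasets from the same task and planted-signal specification but
#' with different surface distributions (population size, note volume,
#' vocabulary drift), emulating training on one EHR system and external
#' validation on another. Planted signal terms are never renamed by the
#' vocabulary shift, so the signal is transferable across systems.
#'
#' @param profile_a,profile_b \code{\link{systemProfile}}s for the two systems.
#' @param signal shared \code{\link{signalSpec}}.
#' @param task shared \code{\link{taskSpec}}.
#' @param seed integer seed; each system uses a seed derived from it.
#' @param ... passed on to \code{\link{simulateEHR}}.
#' @return named list of two \linkS4class{EHRDataset}s.
#' @export
simulateSystemPair <- function(profile_a, profile_b, signal, task, seed, ...) {
  list(
    A = simulateEHR(profile_a, signal, task, .childSeed(seed, "sysA"), ...),
    B = simulateEHR(profile_b, signal, task, .childSeed(seed, "sysB"), ...)
  )
}
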