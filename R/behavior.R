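#' Build a pseudo-randomized stage schedule
#'
#' Constructs the trial schedule for one test stage: a free block of 4
#' familiarisation trials enumerating each distinct bowl configuration
#' (distractor pairing x rewarded side) exactly once in random order,
#' followed by \code{n_closed} scored trials with the rewarded side exactly
#' balanced (left/right) and both pairings equally represented, and with no
#' run of same-side trials longer than \code{max_run}. Deterministic given
#' \code{seed}.
#'
#' @param stage one of \code{"SD"}, \code{"CD"}, \code{"CDR"}, \code{"IDS"}.
#' @param n_closed number of closed trials (even).
#' @param seed integer seed.
#' @param max_run maximum allowed run of consecutive same-side trials,
#'   \code{>= 2}.
#' @param rewarded_exemplar rewarded stimulus exemplar; the default follows
#'   the stage rules of the task (white at SD/CD, reversed to dark-blue at
#'   CDR, novel light-blue at IDS) for a mouse counterbalanced to "white".
#' @return data.frame with columns \code{stage}, \code{type}
#'   (\code{"free"}/\code{"closed"}), \code{trial}, \code{rewarded_exemplar},
#'   \code{pairing} (distractor-texture pairing, \code{"A"}/\code{"B"}) and
#'   \code{rewarded_side} (\code{"left"}/\code{"right"}).
#' @examples
#' sch <- makeSchedule("SD", seed = 1)
#' table(sch$rewarded_side[sch$type == "closed"])
#' @export
makeSchedule <- function(stage = c("SD", "CD", "CDR", "IDS"),
                         n_closed = 30L, seed = 1, max_run = 3L,
                         rewarded_exemplar = NULL) {
  stage <- match.arg(stage)
  n_closed <- as.integer(n_closed)
  if (n_closed < 2L || n_closed %% 2L != 0L)
    stop("n_closed must be even and >= 2")
  if (max_run < 2L) stop("max_run must be >= 2 (infeasible otherwise)")
  if (is.null(rewarded_exemplar))
    rewarded_exemplar <- switch(stage, SD = "white", CD = "white",
                                CDR = "dark-blue", IDS = "light-blue")
  .withSeed(seed, {
    combos <- expand.grid(pairing = c("A", "B"),
                          rewarded_side = c("left", "right"),
                          stringsAsFactors = FALSE)
    free <- combos[sample.int(4L), ]

    base_sides <- rep(c("left", "right"), each = n_closed / 2L)
    ok <- FALSE
    for (i in seq_len(10000L)) {
      sides <- sample(base_sides)
      runs <- rle(sides)$lengths
      if (max(runs) <= max_run) { ok <- TRUE; break }
    }
    if (!ok) stop("could not satisfy the side-run constraint")
    pairings <- sample(rep(c("A", "B"), each = n_closed / 2L))

    out <- rbind(
      data.frame(stage = stage, type = "free", trial = 1:4,
                 rewarded_exemplar = rewarded_exemplar,
                 pairing = free$pairing, rewarded_side = free$rewarded_side),
      data.frame(stage = stage, type = "closed", trial = seq_len(n_closed),
                 rewarded_exemplar = rewarded_exemplar,
                 pairing = pairings, rewarded_side = sides))
    rownames(out) <- NULL
    out
  })
}

#' Locate the learning criterion in a closed-trial outcome sequence
#'
#' The learning criterion is 8 correct choices within 8--10 consecutive
#' closed trials of a single session. This function returns the earliest
#' closed trial \code{t} such that some window of length 8, 9 or 10 ending
#' at \code{t}, lying entirely within one session, contains at least 8
#' correct outcomes. Windows never span sessions (the consecutive-correct
#' count resets at a session boundary) and omissions count as non-correct.
#'
#' With \code{mode = "run"} a stricter reading is applied: the criterion is
#' met at the 8th trial of an uninterrupted run of correct choices (the run
#' counter resets on any error, omission or session boundary).
#'
#' @param outcomes character vector of closed-trial outcomes in order
#'   (\code{"correct"}, \code{"incorrect"}, \code{"omission"}).
#' @param sessions parallel vector of session identifiers (defaults to a
#'   single session).
#' @param mode \code{"window"} (default) or \code{"run"}.
#' @return the 1-based global index of the criterion trial, or
#'   \code{NA_integer_} if the criterion is never met.
#' @examples
#' detectCriterion(rep("correct", 8))                      # 8
#' detectCriterion(c("incorrect", "incorrect", rep("correct", 8)))  # 10
#' @export
detectCriterion <- function(outcomes, sessions = rep(1L, length(outcomes)),
                            mode = c("window", "run")) {
  mode <- match.arg(mode)
  stopifnot(length(outcomes) == length(sessions))
  n <- length(outcomes)
  if (n == 0) return(NA_integer_)
  corr <- outcomes == "correct"
  if (mode == "run") {
    run <- 0L
    for (t in seq_len(n)) {
      if (t > 1L && sessions[t] != sessions[t - 1L]) run <- 0L
      run <- if (corr[t]) run + 1L else 0L
      if (run >= 8L) return(t)
    }
    return(NA_integer_)
  }
  for (t in seq_len(n)) {
    for (w in 8:10) {
      a <- t - w + 1L
      if (a < 1L) next
      if (sessions[a] != sessions[t]) next
      if (sum(corr[a:t]) >= 8L) return(t)
    }
  }
  NA_integer_
}

#' Score one mouse x stage: trials and errors to criterion, median latency
#'
#' Scores the closed trials of one stage for one mouse. Free trials are
#' excluded. Total trials is the number of closed trials up to and
#' including the criterion trial, summed across sessions; total errors
#' counts incorrect choices and omissions among those trials (omissions are
#' error trials). The median choice latency is computed over the same
#' closed trials, excluding missing latencies (omissions). If the
#' criterion is never met the totals cover all closed trials and the
#' criterion is reported as not reached.
#'
#' @param log data.frame of trials of ONE mouse and ONE stage, sorted by
#'   \code{(session, trial_index)}, with columns \code{session},
#'   \code{trial_index}, \code{trial_type}, \code{outcome},
#'   \code{latency_s} (and optionally \code{mouse}, \code{group},
#'   \code{stage}).
#' @param mode criterion reading, passed to [detectCriterion()].
#' @return one-row data.frame: \code{mouse}, \code{group}, \code{stage},
#'   \code{total_trials}, \code{total_errors}, \code{median_latency_s},
#'   \code{criterion_reached}, \code{criterion_session},
#'   \code{criterion_trial} (closed-trial index within its session).
#' @examples
#' sim <- simulateBehavior(p0 = 1, pinf = 1, p_omit = 0, seed = 1)
#' scoreStage(sim$log)
#' @export
scoreStage <- function(log, mode = c("window", "run")) {
  mode <- match.arg(mode)
  need <- c("session", "trial_index", "trial_type", "outcome", "latency_s")
  if (!all(need %in% names(log)))
    stop("log must have columns: ", paste(need, collapse = ", "))
  if ("stage" %in% names(log) && length(unique(log$stage)) > 1L)
    stop("log mixes stages; score one stage at a time")
  if ("mouse" %in% names(log) && length(unique(log$mouse)) > 1L)
    stop("log mixes mice; score one mouse at a time")
  cl <- log[log$trial_type == "closed", , drop = FALSE]
  if (is.unsorted(cl$session) ||
      any(stats::ave(cl$trial_index, cl$session,
                     FUN = function(x) c(0, diff(x))) < 0))
    stop("closed trials must be sorted by (session, trial_index)")
  pick <- function(col, default = NA_character_)
    if (col %in% names(log) && nrow(log)) as.character(log[[col]][1])
    else default
  crit <- detectCriterion(cl$outcome, cl$session, mode = mode)
  scored <- if (is.na(crit)) cl else cl[seq_len(crit), , drop = FALSE]
  lat <- scored$latency_s[!is.na(scored$latency_s)]
  data.frame(
    mouse = pick("mouse"), group = pick("group"), stage = pick("stage"),
    total_trials = nrow(scored),
    total_errors = sum(scored$outcome != "correct"),
    median_latency_s = if (length(lat)) stats::median(lat) else NA_real_,
    criterion_reached = !is.na(crit),
    criterion_session = if (is.na(crit)) NA_integer_
                        else cl$session[crit],
    criterion_trial = if (is.na(crit)) NA_integer_
                      else cl$trial_index[crit])
}

#' Score every mouse x stage cell of a session log
#'
#' Convenience wrapper applying [scoreStage()] to each \code{mouse} x
#' \code{stage} combination of a combined session log.
#'
#' @param log data.frame in the session-log schema (see [scoreStage()]),
#'   with \code{mouse} and \code{stage} columns present.
#' @param mode criterion reading, passed to [detectCriterion()].
#' @return data.frame with one row per mouse x stage.
#' @export
scoreSessions <- function(log, mode = c("window", "run")) {
  mode <- match.arg(mode)
  stopifnot(all(c("mouse", "stage") %in% names(log)))
  cells <- split(log, list(log$mouse, log$stage), drop = TRUE)
  out <- do.call(rbind, lapply(cells, scoreStage, mode = mode))
  out <- out[order(out$mouse, out$stage), , drop = FALSE]
  rownames(out) <- NULL
  out
}
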