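#' Outcome codes for time-to-first-event AE records
#'
#' Each patient contributes one record per AE type, carrying the follow-up
#' time and the first observed state: censoring, the AE of interest, death
#' before the AE, or another competing event (e.g., treatment
#' discontinuation ending AE recording). Integer file codes are
#' 0 = censored, 1 = AE, 2 = death before AE, 3 = other competing event.
#'
#' @format Character vector of the four outcome labels, in file-code order.
#' @export
outcome_levels <- c("censored", "ae", "death_before_ae", "other_ce")

#' Construct an analysis set of per-patient AE records
#'
#' An analysis set holds all time-to-first-event records for one
#' (trial, arm, AE type) unit: for each patient the follow-up time in days
#' and the first observed state.
#'
#' @param time Numeric vector of strictly positive, finite follow-up times
#'   in days.
#' @param outcome Character vector (same length) of outcome labels, see
#'   [outcome_levels], or integer codes 0--3.
#' @param subject_id Optional vector of unique subject identifiers;
#'   defaults to `seq_along(time)`.
#' @param trial_id,arm,ae_type Unit metadata labels.
#' @return An object of class `analysis_set`: a list with elements
#'   `trial_id`, `arm`, `ae_type` and `data` (a data frame with columns
#'   `subject_id`, `time`, `outcome`).
#' @examples
#' analysis_set(c(5, 12, 30), c("ae", "censored", "other_ce"))
#' @export
analysis_set <- function(time, outcome, subject_id = NULL,
                         trial_id = "trial", arm = "E", ae_type = "AE") {
  if (length(time) < 1L)
    stop("an analysis set needs at least one record", call. = FALSE)
  if (!is.numeric(time) || anyNA(time) || any(!is.finite(time)) || any(time <= 0))
    stop("all follow-up times must be strictly positive and finite",
         call. = FALSE)
  outcome <- decode_outcome(outcome)
  if (length(outcome) != length(time))
    stop("time and outcome must have the same length", call. = FALSE)
  if (is.null(subject_id)) subject_id <- seq_along(time)
  if (anyDuplicated(subject_id))
    stop("subject_id must be unique within an analysis set", call. = FALSE)
  structure(
    list(trial_id = as.character(trial_id),
         arm = as.character(arm),
         ae_type = as.character(ae_type),
         data = data.frame(subject_id = subject_id,
                           time = as.numeric(time),
                           outcome = outcome,
                           stringsAsFactors = FALSE)),
    class = "analysis_set")
}

decode_outcome <- function(outcome) {
  if (is.numeric(outcome)) {
    if (any(!outcome %in% 0:3))
      stop("integer outcome codes must be 0, 1, 2 or 3", call. = FALSE)
    return(outcome_levels[outcome + 1L])
  }
  outcome <- as.character(outcome)
  if (any(!outcome %in% outcome_levels))
    stop("unknown outcome label(s): ",
         paste(unique(setdiff(outcome, outcome_levels)), collapse = ", "),
         call. = FALSE)
  outcome
}

#' @export
print.analysis_set <- function(x, ...) {
  cat(sprintf("<analysis_set> trial %s, arm %s, AE type %s: n = %d\n",
              x$trial_id, x$arm, x$ae_type, nrow(x$data)))
  tab <- table(factor(x$data$outcome, levels = outcome_levels))
  print(tab)
  invisible(x)
}

#' Number of patients in an analysis set
#' @param set An [analysis_set()].
#' @return Integer count of records.
#' @export
n_records <- function(set) {
  stopifnot(inherits(set, "analysis_set"))
  nrow(set$data)
}

#' Apply a competing-event scheme
#'
#' Under the all-CE scheme both death before AE and other competing events
#' (disease- or safety-related end of AE recording, e.g., treatment
#' discontinuation) count as competing. Under the death-only scheme only
#' death before AE is competing and other competing events are recoded to
#' censored at the same time.
#'
#' @param set An [analysis_set()].
#' @param scheme `"all_ce"` (default) or `"death_only"`.
#' @return A copy of `set` with outcomes recoded per the scheme. Both
#'   schemes are idempotent.
#' @export
apply_ce_scheme <- function(set, scheme = c("all_ce", "death_only")) {
  stopifnot(inherits(set, "analysis_set"))
  scheme <- match.arg(scheme)
  out <- set
  if (scheme == "death_only") {
    recode <- out$data$outcome == "other_ce"
    out$data$outcome[recode] <- "censored"
  }
  out
}

#' Count observed event states on [0, tau]
#'
#' Classifies each record by its observed state within the evaluation
#' window: records with follow-up beyond `tau` are administratively
#' truncated and count as censored at `tau`; records with `time <= tau`
#' keep their observed outcome (events at exactly `tau` count as observed).
#'
#' @param set An [analysis_set()].
#' @param tau Evaluation time in days, strictly positive.
#' @return An object of class `event_counts`: list with integer counts
#'   `n_ae`, `n_death`, `n_other_ce`, `n_censored`, total `n`, and a named
#'   `proportions` vector summing to one.
#' @export
count_events <- function(set, tau) {
  stopifnot(inherits(set, "analysis_set"))
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0)
    stop("tau must be a single strictly positive evaluation time",
         call. = FALSE)
  state <- ifelse(set$data$time > tau, "censored", set$data$outcome)
  tab <- table(factor(state, levels = outcome_levels))
  n <- nrow(set$data)
  counts <- list(n = n,
                 n_censored = as.integer(tab[["censored"]]),
                 n_ae = as.integer(tab[["ae"]]),
                 n_death = as.integer(tab[["death_before_ae"]]),
                 n_other_ce = as.integer(tab[["other_ce"]]))
  counts$proportions <- c(censored = counts$n_censored,
                          ae = counts$n_ae,
                          death_before_ae = counts$n_death,
                          other_ce = counts$n_other_ce) / n
  structure(counts, class = "event_counts")
}

#' @export
print.event_counts <- function(x, ...) {
  cat(sprintf(
    "<event_counts> n = %d: %d AE, %d death, %d other CE, %d censored\n",
    x$n, x$n_ae, x$n_death, x$n_other_ce, x$n_censored))
  invisible(x)
}
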