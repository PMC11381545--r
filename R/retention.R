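#' Build species-retention survival records from presence profiles
#'
#' For each subject x species pair the clock starts at the first observed
#' presence; the event (loss) is the first subsequent absence, and records
#' still present at the subject's last visit are right-censored. Durations
#' are counted in visit intervals (the cohort's only observed clock, about
#' three months each). By default only the first colonization episode per
#' subject x species is used — a later re-colonization of the same host is
#' not an independent survival record; `episodes = "all"` keeps every
#' episode. Species first seen at a subject's final visit have no interval at
#' risk and yield no record. `require_absence_before = TRUE` additionally
#' drops episodes already in progress at the first visit (left entry).
#'
#' @param presence species x sample 0/1 matrix.
#' @param metadata sample metadata.
#' @param episodes `"first"` (default) or `"all"`.
#' @param require_absence_before only count episodes preceded by an observed
#'   absence.
#' @return data.frame `subject_id`, `species_id`, `duration` (>= 1 visit
#'   intervals), `event` (1 = lost, 0 = censored).
#' @export
build_retention_events <- function(presence, metadata,
                                   episodes = c("first", "all"),
                                   require_absence_before = FALSE) {
  episodes <- match.arg(episodes)
  md <- validate_metadata(metadata, samples = colnames(presence))
  parts <- lapply(split(md, md$subject_id), function(d) {
    x <- presence[, d$sample_id, drop = FALSE] > 0
    nv <- ncol(x)
    if (nv < 2) return(NULL)
    recs <- lapply(seq_len(nrow(x)), function(i) {
      v <- unname(x[i, ])
      out <- list()
      start <- 1L
      repeat {
        on_idx <- which(v & seq_len(nv) >= start)
        if (length(on_idx) == 0) break
        s <- on_idx[1]
        if (require_absence_before && s == 1L) {
          # skip the left-entry episode, move past it
          off <- which(!v & seq_len(nv) > s)
          if (length(off) == 0) break
          start <- off[1] + 1L
          next
        }
        off <- which(!v & seq_len(nv) > s)
        if (length(off) == 0) {
          dur <- nv - s
          if (dur >= 1)
            out[[length(out) + 1]] <- c(duration = dur, event = 0)
          break
        }
        out[[length(out) + 1]] <- c(duration = off[1] - s, event = 1)
        if (episodes == "first") break
        start <- off[1] + 1L
      }
      if (length(out) == 0) return(NULL)
      m <- do.call(rbind, out)
      data.frame(subject_id = d$subject_id[1], species_id = rownames(x)[i],
                 duration = m[, "duration"], event = m[, "event"],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, recs)
  })
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(subject_id = character(), species_id = character(),
                      duration = numeric(), event = integer())
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier species-retention curve
#'
#' Product-limit estimate S(t) = prod over event times t_i <= t of
#' (1 - d_i / n_i), computed with `survival::survfit`. The returned curve
#' starts at S(0) = 1.
#'
#' @param events data.frame from [build_retention_events()] (or any table
#'   with `duration` and `event`), optionally pre-filtered to one species.
#' @return data.frame `time`, `n_risk`, `n_event`, `survival`.
#' @export
km_curve <- function(events) {
  if (is.null(events) || nrow(events) == 0)
    stop("no retention events to estimate a curve from")
  fit <- survival::survfit(survival::Surv(events$duration, events$event) ~ 1)
  data.frame(time = c(0, fit$time),
             n_risk = c(fit$n, fit$n.risk),
             n_event = c(0, fit$n.event),
             survival = c(1, fit$surv))
}

#' Retention probability at a horizon
#'
#' S evaluated at the last curve time not exceeding `horizon` (step-function
#' convention); horizons beyond the curve return the final survival value.
#'
#' @param curve data.frame from [km_curve()].
#' @param horizon non-negative time in visit intervals.
#' @return survival probability in \[0, 1\].
#' @export
retention_probability <- function(curve, horizon) {
  stopifnot(horizon >= 0)
  s <- stats::stepfun(curve$time[-1], curve$survival)
  unname(s(horizon))
}
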