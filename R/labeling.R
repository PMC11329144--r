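#' Labeling policy anchored on PTA interventions
#'
#' Recordings are weakly labeled from percutaneous transluminal angioplasty
#' (PTA) timelines: a recording within `pre_window_days` before an intervention
#' is abnormal (the access was stenosed enough to need reopening); one falling
#' in a window starting `post_start_days` after the intervention and lasting
#' `post_window_days` is normal (the access was just reopened); everything else
#' is unlabeled. Defaults: one weekly visit before PTA (7 days) is abnormal;
#' the normal window opens at day 4 post-PTA and spans 21 days, capturing about
#' three weekly visits per intervention, which reproduces the roughly 3:1
#' normal:abnormal ratio of a weekly-monitored cohort.
#'
#' @param pre_window_days Days before a PTA that count as abnormal (default 7).
#' @param post_start_days Days after a PTA at which the normal window opens
#'   (default 4).
#' @param post_window_days Length of the normal window in days (default 21).
#' @return An object of class `label_policy`.
#' @export
label_policy <- function(pre_window_days = 7, post_start_days = 4,
                         post_window_days = 21) {
  stopifnot(pre_window_days >= 0, post_start_days >= 0, post_window_days >= 0)
  structure(list(pre_window_days = pre_window_days,
                 post_start_days = post_start_days,
                 post_window_days = post_window_days),
            class = "label_policy")
}

#' Assign normal / abnormal / unlabeled states from PTA timelines
#'
#' Labels are derived only from timestamps and PTA event dates (never from
#' simulator ground truth). A recording is `abnormal` iff some event of the
#' same patient satisfies `0 <= event_date - timestamp <= pre_window_days`;
#' `normal` iff some event satisfies `post_start_days <= timestamp - event_date
#' <= post_start_days + post_window_days`; otherwise `unlabeled`. If two close
#' interventions make both windows match, abnormal wins (conservative for a
#' screening tool) and a warning is issued.
#'
#' @param records Data frame with columns `patient_id`, `timestamp` (Date or
#'   coercible), plus any others (carried through).
#' @param events Data frame with columns `patient_id`, `event_date`. Every
#'   event patient must appear in `records`.
#' @param policy A [label_policy()].
#' @return `records` with an added factor column `label` in
#'   levels `c("normal", "abnormal", "unlabeled")`.
#' @export
assign_labels <- function(records, events, policy = label_policy()) {
  stopifnot(inherits(policy, "label_policy"),
            all(c("patient_id", "timestamp") %in% names(records)),
            all(c("patient_id", "event_date") %in% names(events)))
  ts <- as.Date(records$timestamp)
  ev_date <- as.Date(events$event_date)
  unknown <- setdiff(events$patient_id, records$patient_id)
  if (length(unknown))
    stop("assign_labels: PTA event for unknown patient(s): ",
         paste(unknown, collapse = ", "))
  n <- nrow(records)
  abnormal <- logical(n); normal <- logical(n)
  for (j in seq_len(nrow(events))) {
    same <- records$patient_id == events$patient_id[j]
    d_pre <- as.numeric(ev_date[j] - ts)           # days before the event
    d_post <- as.numeric(ts - ev_date[j])          # days after the event
    abnormal <- abnormal | (same & d_pre >= 0 & d_pre <= policy$pre_window_days)
    normal <- normal | (same & d_post >= policy$post_start_days &
                          d_post <= policy$post_start_days + policy$post_window_days)
  }
  both <- abnormal & normal
  if (any(both))
    warning(sum(both), " recording(s) fall in both windows (close PTAs); ",
            "labeled abnormal")
  label <- ifelse(abnormal, "abnormal", ifelse(normal, "normal", "unlabeled"))
  records$label <- factor(label, levels = c("normal", "abnormal", "unlabeled"))
  records
}

#' Count recordings per label
#'
#' @param labeled Data frame as returned by [assign_labels()] (column `label`).
#' @return Named integer vector `c(normal, abnormal, unlabeled)` summing to
#'   `nrow(labeled)`.
#' @export
label_summary <- function(labeled) {
  lv <- c("normal", "abnormal", "unlabeled")
  if (nrow(labeled) == 0) return(stats::setNames(integer(3), lv))
  tab <- table(factor(labeled$label, levels = lv))
  stats::setNames(as.integer(tab), lv)
}
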