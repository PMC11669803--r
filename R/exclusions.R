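#' Exclusion rules for administrative data quality
#'
#' @param min_response_seconds records faster than this are removed as
#'   careless "speeders" (default 300 s, i.e. five minutes).
#' @param drop_duplicates keep only the earliest record per participant and
#'   wave ("the first version").
#' @param drop_psychotic_history remove participants flagged with a history
#'   of psychotic disorder.
#' @param drop_refusals remove participants who refused the verification
#'   interview.
#' @return list of class `exclusion_rules`.
#' @export
exclusion_rules <- function(min_response_seconds = 300,
                            drop_duplicates = TRUE,
                            drop_psychotic_history = TRUE,
                            drop_refusals = TRUE) {
  structure(list(min_response_seconds = min_response_seconds,
                 drop_duplicates = drop_duplicates,
                 drop_psychotic_history = drop_psychotic_history,
                 drop_refusals = drop_refusals),
            class = "exclusion_rules")
}

#' Apply administrative exclusions and report the cohort flow
#'
#' Removes, in order: duplicate records (keeping the earliest timestamp per
#' participant and wave), speeders (response time under the rule's minimum),
#' participants with a history of psychotic disorder, and participants who
#' refused. The flow report counts baseline (wave-1) records removed at each
#' step; `input n - sum(removed) = output n` is asserted on every run, and
#' the operation is idempotent.
#'
#' @param data panel data.frame with columns `id`, `wave`, `timestamp`,
#'   `response_time_seconds`, `psychotic_history`, `refused`, plus items.
#' @param rules an [exclusion_rules()] object.
#' @return list with `data` (the retained records, attribute `flow_report`
#'   attached) and `flow` (data.frame: step, removed, remaining — baseline
#'   record counts).
#' @export
apply_exclusions <- function(data, rules = exclusion_rules()) {
  needed <- c("id", "wave", "timestamp", "response_time_seconds",
              "psychotic_history", "refused")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0)
    fail("apply_exclusions: missing metadata column(s): %s",
         paste(missing_cols, collapse = ", "))

  n_base <- function(d) sum(d$wave == 1)
  steps <- character(0); removed <- integer(0); remaining <- integer(0)
  note <- function(step, before, d) {
    steps <<- c(steps, step)
    removed <<- c(removed, before - n_base(d))
    remaining <<- c(remaining, n_base(d))
    d
  }

  n0 <- n_base(data)
  d <- data

  if (isTRUE(rules$drop_duplicates)) {
    before <- n_base(d)
    ord <- order(d$id, d$wave, d$timestamp)
    d <- d[ord, , drop = FALSE]
    d <- d[!duplicated(d[, c("id", "wave")]), , drop = FALSE]
    d <- note("duplicates", before, d)
  }

  before <- n_base(d)
  d <- d[d$response_time_seconds >= rules$min_response_seconds, , drop = FALSE]
  d <- note("speeders", before, d)

  if (isTRUE(rules$drop_psychotic_history)) {
    before <- n_base(d)
    flagged <- unique(d$id[d$psychotic_history == 1])
    d <- d[!(d$id %in% flagged), , drop = FALSE]
    d <- note("psychotic_history", before, d)
  }

  if (isTRUE(rules$drop_refusals)) {
    before <- n_base(d)
    flagged <- unique(d$id[d$refused == 1])
    d <- d[!(d$id %in% flagged), , drop = FALSE]
    d <- note("refusals", before, d)
  }

  flow <- data.frame(step = steps, removed = removed, remaining = remaining,
                     stringsAsFactors = FALSE)
  stopifnot(n0 - sum(flow$removed) == n_base(d))
  rownames(d) <- NULL
  attr(d, "flow_report") <- flow
  list(data = d, flow = flow)
}

#' Participants present at both waves
#'
#' @param data panel data.frame (post-exclusion).
#' @return the data restricted to participants with both a wave-1 and a
#'   wave-2 record, plus attribute `lost_to_followup` (count).
#' @export
complete_followup <- function(data) {
  ids1 <- unique(data$id[data$wave == 1])
  ids2 <- unique(data$id[data$wave == 2])
  keep <- intersect(ids1, ids2)
  out <- data[data$id %in% keep, , drop = FALSE]
  attr(out, "lost_to_followup") <- length(ids1) - length(keep)
  out
}

#' Persistence and incidence of a screening classification across waves
#'
#' Persistence is the fraction of baseline positives that are positive again
#' at wave 2; incidence is the fraction of baseline negatives that are
#' positive at wave 2. Empty denominators give `NA` with a flag.
#'
#' @param baseline,wave2 classifications per participant (factors from
#'   [classify_ples()], or logicals where `TRUE` = positive), same length and
#'   order.
#' @return list with `persistence`, `incidence` (fractions), the underlying
#'   counts, and `flags` (character vector naming undefined quantities).
#' @export
#' @examples
#' b <- rep(c(TRUE, FALSE), c(455, 2903))
#' w2 <- c(rep(c(TRUE, FALSE), c(104, 351)), rep(c(TRUE, FALSE), c(137, 2766)))
#' r <- transition_rates(b, w2)
#' round(100 * c(r$persistence, r$incidence), 1)  # 22.9, 4.7
transition_rates <- function(baseline, wave2) {
  as_pos <- function(x) {
    if (is.factor(x) || is.character(x)) x == "positive" else as.logical(x)
  }
  b <- as_pos(baseline); w <- as_pos(wave2)
  if (length(b) != length(w))
    fail("transition_rates: classifications differ in length")
  ok <- !is.na(b) & !is.na(w)
  b <- b[ok]; w <- w[ok]
  n_pos <- sum(b); n_neg <- sum(!b)
  persisted <- sum(b & w); incident <- sum(!b & w)
  flags <- character(0)
  persistence <- if (n_pos > 0) persisted / n_pos else {
    flags <- c(flags, "persistence_undefined"); NA_real_
  }
  incidence <- if (n_neg > 0) incident / n_neg else {
    flags <- c(flags, "incidence_undefined"); NA_real_
  }
  list(persistence = persistence, incidence = incidence,
       counts = c(baseline_positive = n_pos, baseline_negative = n_neg,
                  persisted = persisted, incident = incident),
       flags = flags)
}
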