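#' Canonical 24-node network layout
#'
#' The network has 24 nodes in four constructs: the three CAPE-P15 factors
#' (PI = persecutory ideation, BEs = bizarre experiences, PAs = perceptual
#' abnormalities), the nine PHQ-9 items, the seven GAD-7 items, and the five
#' ASLEC adverse life-event factors (A1 punishment, A2 loss, A3 adjustment,
#' A4 interpersonal stress, A5 academic stress).
#'
#' @return a data.frame with columns `node` and `construct` (24 rows, in
#'   canonical order).
#' @export
#' @examples
#' table(clpn_node_info()$construct)
clpn_node_info <- function() {
  data.frame(
    node = c("PI", "BEs", "PAs",
             paste0("PHQ", 1:9),
             paste0("GAD", 1:7),
             paste0("A", 1:5)),
    construct = rep(c("PLEs", "depression", "anxiety", "life_events"),
                    c(3L, 9L, 7L, 5L)),
    stringsAsFactors = FALSE
  )
}

#' Define a screening instrument
#'
#' An instrument specification names the item columns, the response scale,
#' and (optionally) a factor map assigning item subsets to scored factors.
#' Factor scores are means of valid items by default; a `sum` mode exists
#' for sensitivity analysis.
#'
#' @param name instrument name.
#' @param items character vector of item column names, in order.
#' @param scale_min,scale_max integer response bounds (`scale_min < scale_max`).
#' @param factors named list mapping factor name to a character subset of
#'   `items`; `NULL` means each item is scored as its own node.
#' @param scoring `"factor_mean"` (default) or `"sum"`.
#' @param completeness minimum fraction of valid items required for a factor
#'   score; below it the score is `NA`.
#' @return an object of class `instrument_spec`.
#' @export
instrument_spec <- function(name, items, scale_min, scale_max,
                            factors = NULL, scoring = c("factor_mean", "sum"),
                            completeness = 0.8) {
  scoring <- match.arg(scoring)
  stopifnot(scale_min < scale_max, completeness >= 0, completeness <= 1)
  if (!is.null(factors)) {
    unknown <- setdiff(unlist(factors), items)
    if (length(unknown) > 0)
      fail("instrument '%s': factor map names unknown items: %s",
           name, paste(unknown, collapse = ", "))
    if (anyDuplicated(unlist(factors)))
      fail("instrument '%s': factor map assigns an item twice", name)
  }
  structure(list(name = name, items = items,
                 scale_min = scale_min, scale_max = scale_max,
                 factors = factors, scoring = scoring,
                 completeness = completeness),
            class = "instrument_spec")
}

#' Default instrument specifications
#'
#' CAPE-P15 (15 items, 1-4) with the PI/BEs/PAs factor map (5/7/3 items;
#' the exact published item-to-subtype assignment is not fixed by the scale's
#' short form, so the contiguous default here is configurable), PHQ-9
#' (9 items, 1-4, item-level nodes), GAD-7 (7 items, 1-4, item-level nodes),
#' and ASLEC (27 items, 1-5) with five factors used as network nodes
#' (punishment 7, loss 5, adjustment 5, interpersonal 5, academic 5 items).
#'
#' @return named list of [instrument_spec()] objects
#'   (`cape`, `phq`, `gad`, `aslec`).
#' @export
default_instruments <- function() {
  cape_items <- sprintf("cape_%02d", 1:15)
  aslec_items <- sprintf("aslec_%02d", 1:27)
  list(
    cape = instrument_spec(
      "CAPE-P15", cape_items, 1L, 4L,
      factors = list(PI = cape_items[1:5],
                     BEs = cape_items[6:12],
                     PAs = cape_items[13:15])),
    phq = instrument_spec("PHQ-9", sprintf("phq_%02d", 1:9), 1L, 4L),
    gad = instrument_spec("GAD-7", sprintf("gad_%02d", 1:7), 1L, 4L),
    aslec = instrument_spec(
      "ASLEC", aslec_items, 1L, 5L,
      factors = list(A1 = aslec_items[1:7],
                     A2 = aslec_items[8:12],
                     A3 = aslec_items[13:17],
                     A4 = aslec_items[18:22],
                     A5 = aslec_items[23:27]))
  )
}

#' CAPE-P15 weighted score
#'
#' The whole-scale weighted score is the sum of all valid item scores divided
#' by the number of valid items, i.e. the mean over valid items; it lies in
#' the response range. Rows with no valid item get `NA`.
#'
#' @param responses numeric matrix or data.frame of item responses (rows =
#'   participants), or a single numeric vector of one participant's items.
#'   Scoring is pure arithmetic; range validation happens at I/O time in
#'   [read_panel_csv()].
#' @param spec an [instrument_spec()]; defaults to the CAPE-P15 spec.
#' @return numeric vector of weighted scores.
#' @export
#' @examples
#' cape_weighted_score(rep(1, 15))           # 1.0
#' cape_weighted_score(c(rep(2, 14), NA))    # 2.0
cape_weighted_score <- function(responses, spec = default_instruments()$cape) {
  if (is.vector(responses) && is.numeric(responses))
    responses <- matrix(responses, nrow = 1)
  responses <- as.matrix(responses)
  k <- rowSums(!is.na(responses))
  out <- rowSums(responses, na.rm = TRUE) / k
  out[k == 0] <- NA_real_
  out
}

#' Classify a PLEs weighted score against the screening cut-off
#'
#' The screening cut-off for the CAPE-P15 weighted score is 1.57; scores at
#' or above it are classified positive (boundary inclusion is switchable via
#' `inclusive`). Missing scores yield a missing class.
#'
#' @param score numeric vector of weighted scores.
#' @param cutoff cut-off value (default 1.57).
#' @param inclusive logical; if `TRUE` (default) a score equal to the cut-off
#'   is positive.
#' @return factor with levels `negative`, `positive` (NA preserved).
#' @export
#' @examples
#' classify_ples(c(1.0, 1.57, 4.0))
classify_ples <- function(score, cutoff = 1.57, inclusive = TRUE) {
  pos <- if (inclusive) score >= cutoff else score > cutoff
  factor(ifelse(pos, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' Score instrument factors
#'
#' Each factor is scored as the mean of its valid items (or the sum when the
#' spec's scoring mode is `"sum"`). A factor score is missing when fewer than
#' the spec's completeness fraction of its items are valid.
#'
#' @param items data.frame or matrix containing (at least) the instrument's
#'   item columns.
#' @param spec an [instrument_spec()] with a factor map.
#' @return data.frame of per-factor scores, one row per input row.
#' @export
score_factors <- function(items, spec) {
  if (is.null(spec$factors))
    fail("instrument '%s' has no factor map", spec$name)
  items <- as.data.frame(items)
  missing_cols <- setdiff(unlist(spec$factors), names(items))
  if (length(missing_cols) > 0)
    fail("instrument '%s': missing item columns: %s",
         spec$name, paste(missing_cols, collapse = ", "))
  out <- lapply(spec$factors, function(cols) {
    m <- as.matrix(items[, cols, drop = FALSE])
    valid <- rowSums(!is.na(m))
    s <- if (spec$scoring == "sum") rowSums(m, na.rm = TRUE)
         else rowSums(m, na.rm = TRUE) / valid
    s[valid < spec$completeness * length(cols) | valid == 0] <- NA_real_
    s
  })
  as.data.frame(out, optional = TRUE)
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(total))`,
#' with sample variances. Requires at least two items, at least three rows,
#' and a non-degenerate total score.
#'
#' @param items n x k numeric matrix or data.frame, complete cases used.
#' @return alpha (a real number, at most 1).
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  m <- m[complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  if (k < 2) fail("cronbach_alpha: need at least 2 items, got %d", k)
  if (nrow(m) < 3) fail("cronbach_alpha: need at least 3 complete rows")
  vt <- var(rowSums(m))
  if (vt <= 0) fail("cronbach_alpha: total score has zero variance")
  k / (k - 1) * (1 - sum(apply(m, 2, var)) / vt)
}

#' Build the 24-node score matrix for one wave
#'
#' Scores the four instruments into the canonical node layout: CAPE-P15
#' factors PI/BEs/PAs, the nine PHQ items, the seven GAD items, and the five
#' ASLEC factors. Item-level nodes are the raw item responses; factor nodes
#' are valid-item means subject to the spec's completeness rule.
#'
#' @param data a panel data.frame (one row per participant per wave) with the
#'   instrument item columns, an `id` column and a `wave` column.
#' @param wave which wave to score (1 or 2).
#' @param instruments list of instrument specs as from [default_instruments()].
#' @return an object of class `node_scores`: list with elements `scores`
#'   (n x 24 matrix, rownames = participant ids), `wave`, and `nodes` (the
#'   [clpn_node_info()] frame).
#' @export
node_scores <- function(data, wave, instruments = default_instruments()) {
  stopifnot(wave %in% c(1, 2))
  rows <- data[data$wave == wave, , drop = FALSE]
  if (nrow(rows) == 0) fail("node_scores: no records for wave %d", wave)
  if (anyDuplicated(rows$id))
    fail("node_scores: duplicate records for wave %d; run apply_exclusions() first",
         wave)
  rows <- rows[order(rows$id), , drop = FALSE]

  cape <- score_factors(rows, instruments$cape)
  phq <- as.matrix(rows[, instruments$phq$items, drop = FALSE])
  gad <- as.matrix(rows[, instruments$gad$items, drop = FALSE])
  aslec <- score_factors(rows, instruments$aslec)

  info <- clpn_node_info()
  m <- cbind(as.matrix(cape), phq, gad, as.matrix(aslec))
  colnames(m) <- info$node
  rownames(m) <- as.character(rows$id)
  if (any(is.infinite(m))) fail("node_scores: non-finite node score produced")
  structure(list(scores = m, wave = wave, nodes = info),
            class = "node_scores")
}

#' @export
print.node_scores <- function(x, ...) {
  cat(sprintf("<node_scores> wave %d: %d participants x %d nodes\n",
              x$wave, nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

# Coerce a node_scores object or bare matrix to the 24-column matrix.
as_node_matrix <- function(x) {
  if (inherits(x, "node_scores")) x$scores
  else if (is.matrix(x)) x
  else fail("expected a node_scores object or a numeric matrix")
}
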