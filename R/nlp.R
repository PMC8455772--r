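# Regex-based radiology report parsing: ETT presence labeling for cohort
# building and tip-carina distance extraction for reference measurements.

.ett_patterns <- "\\bendo[- ]?tracheal\\s+tube\\b|\\bet\\s+tube\\b|\\bett\\b"
.negation_terms <- c("no", "not", "without", "removed", "removal",
                     "remove", "extubated", "extubation", "discontinued",
                     "absent", "withdrawn")
.distance_pattern <- paste0(
  "\\b([0-9]+(?:\\.[0-9]+)?)\\s*(cm|mm)\\s+",
  "(?:above|from|below|beyond|proximal\\s+to|distal\\s+to)\\s+",
  "(?:the\\s+)?carina")

#' Detect endotracheal-tube mentions in a report
#'
#' Case-insensitive pattern families for "endotracheal tube", "ET tube" and
#' "ETT" (distractor devices such as a nasogastric tube do not trigger). A
#' negation or removal term within `neg_window` tokens before or after a
#' mention votes ABSENT; no mention at all yields ABSENT; conflicting votes
#' yield UNCERTAIN.
#'
#' @param text A single non-empty report string.
#' @param neg_window Token window for negation scope (default 5).
#' @return A list: `ett_status` (`"PRESENT"`, `"ABSENT"` or `"UNCERTAIN"`)
#'   and `matched_span` (`c(start, end)` character offsets of the first
#'   triggering mention, or `NULL` when nothing matched).
#' @export
detect_ett <- function(text, neg_window = 5) {
  stopifnot(is.character(text), length(text) == 1, nzchar(text))
  m <- gregexpr(.ett_patterns, text, ignore.case = TRUE, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(list(ett_status = "ABSENT", matched_span = NULL))
  }
  toks <- gregexpr("\\S+", text)[[1]]
  tok_start <- as.integer(toks)
  tok_end <- tok_start + attr(toks, "match.length") - 1L
  raw <- regmatches(text, list(toks))[[1]]
  words <- gsub("[^a-z]", "", tolower(raw))
  # negation scope never crosses a sentence boundary
  ends <- grepl("[.!?][\"')]*$", raw)
  sent <- cumsum(c(0L, ends[-length(ends)]))
  votes <- vapply(seq_along(m), function(i) {
    start <- m[i]
    ti <- which(tok_start <= start & tok_end >= start)[1]
    if (is.na(ti)) ti <- which.min(abs(tok_start - start))
    lo <- max(1, ti - neg_window)
    hi <- min(length(words), ti + neg_window)
    win <- lo:hi
    win <- win[sent[win] == sent[ti]]
    any(words[win] %in% .negation_terms)
  }, logical(1))
  status <- if (all(votes)) "ABSENT" else if (any(votes)) "UNCERTAIN" else "PRESENT"
  span <- c(m[1], m[1] + attr(m, "match.length")[1] - 1L)
  list(ett_status = status, matched_span = span)
}

#' Extract a tip-carina distance from report text
#'
#' Matches numeric + unit + carina-relation phrases such as
#' "4.2 cm above the carina" or "35 mm from the carina"; millimeters are
#' converted to centimeters. The first plausible match (within
#' `(0, max_cm]`) is returned.
#'
#' @param text A single non-empty report string.
#' @param max_cm Plausibility bound in centimeters (default 15).
#' @return Distance in cm, or `NA_real_` when no plausible match exists.
#' @export
extract_distance_cm <- function(text, max_cm = 15) {
  stopifnot(is.character(text), length(text) == 1, nzchar(text))
  m <- gregexpr(.distance_pattern, text, ignore.case = TRUE, perl = TRUE)[[1]]
  if (m[1] == -1) return(NA_real_)
  for (hit in regmatches(text, list(m))[[1]]) {
    g <- regmatches(hit, regexec(.distance_pattern, hit,
                                 ignore.case = TRUE, perl = TRUE))[[1]]
    val <- as.numeric(g[2])
    if (tolower(g[3]) == "mm") val <- val / 10
    if (is.finite(val) && val > 0 && val <= max_cm) return(val)
  }
  NA_real_
}

#' Parse a full report: presence status plus reference distance
#'
#' The distance is reported only for PRESENT status; an extracted value
#' outside the plausibility bound is dropped and flagged.
#'
#' @inheritParams detect_ett
#' @inheritParams extract_distance_cm
#' @return A list: `ett_status`, `distance_cm` (`NA` unless PRESENT with a
#'   plausible measurement), `matched_span`, `implausible` flag.
#' @export
parse_report <- function(text, neg_window = 5, max_cm = 15) {
  det <- detect_ett(text, neg_window)
  dist <- NA_real_
  implausible <- FALSE
  if (det$ett_status == "PRESENT") {
    raw <- extract_distance_cm(text, max_cm = Inf)
    if (!is.na(raw)) {
      if (raw > 0 && raw <= max_cm) dist <- raw else implausible <- TRUE
    }
  }
  list(ett_status = det$ett_status, distance_cm = dist,
       matched_span = det$matched_span, implausible = implausible)
}

#' Parse a table of reports
#'
#' Vectorized [parse_report()] over a data frame, mirroring the
#' `parse-reports` CLI subcommand.
#'
#' @param df Data frame with columns `exam_id` and `report_text`.
#' @inheritParams parse_report
#' @return Data frame with `exam_id`, `ett_status`, `distance_cm`,
#'   `span_start`, `span_end`.
#' @export
parse_reports <- function(df, neg_window = 5, max_cm = 15) {
  stopifnot(all(c("exam_id", "report_text") %in% names(df)))
  res <- lapply(as.character(df$report_text), parse_report,
                neg_window = neg_window, max_cm = max_cm)
  data.frame(
    exam_id = df$exam_id,
    ett_status = vapply(res, `[[`, character(1), "ett_status"),
    distance_cm = vapply(res, `[[`, numeric(1), "distance_cm"),
    span_start = vapply(res, function(r)
      if (is.null(r$matched_span)) NA_integer_ else r$matched_span[1], integer(1)),
    span_end = vapply(res, function(r)
      if (is.null(r$matched_span)) NA_integer_ else r$matched_span[2], integer(1)),
    stringsAsFactors = FALSE)
}
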