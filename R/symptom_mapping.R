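# Free-text symptom extraction: reason-for-encounter strings -> SymptomEvents.

#' Split a reason-for-encounter string into reason segments
#'
#' A single free-text field routinely contains several reasons (symptoms,
#' diagnoses, administrative queries) separated by punctuation. Exclusion
#' filters are scoped to a segment, so splitting happens before matching.
#' Empty segments are dropped; surrounding whitespace is trimmed.
#'
#' @param reason_text Character scalar (non-NULL; may be empty).
#' @param delimiters Regular expression character class of segment
#'   delimiters (default semicolon, comma, pipe and newline).
#' @return Character vector of non-empty trimmed segments.
#' @export
#' @examples
#' split_reasons("abdo pain; weight loss")
split_reasons <- function(reason_text, delimiters = "[;,|\n]") {
  stopifnot(length(reason_text) == 1, !is.null(reason_text))
  if (is.na(reason_text) || !nzchar(trimws(reason_text))) return(character(0))
  parts <- strsplit(reason_text, delimiters)[[1]]
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

# Vectorised segment matcher used by extract_symptom_events(): returns a
# logical matrix (segment x lexicon entry).
match_segments_matrix <- function(segments, lexicon) {
  n <- length(segments)
  entries <- lexicon$entries
  out <- matrix(FALSE, nrow = n, ncol = length(entries),
                dimnames = list(NULL, vapply(entries, `[[`, "", "code")))
  if (n == 0) return(out)
  for (j in seq_along(entries)) {
    e <- entries[[j]]
    hit <- rep(FALSE, n)
    for (p in e$include) {
      hit <- hit | grepl(p, segments, ignore.case = TRUE, perl = TRUE)
    }
    if (any(hit) && length(e$exclude) > 0) {
      veto <- rep(FALSE, n)
      for (p in e$exclude) {
        veto <- veto | grepl(p, segments, ignore.case = TRUE, perl = TRUE)
      }
      hit <- hit & !veto
    }
    out[, j] <- hit
  }
  out
}

#' Map one reason segment to symptom codes
#'
#' A code is returned iff at least one of its include patterns matches the
#' segment and none of its exclude patterns does. Matching is
#' case-insensitive; the result is deduplicated and sorted in canonical
#' order.
#'
#' @param segment Character scalar, one reason segment.
#' @param lexicon A [symptom_lexicon()].
#' @return Character vector of canonical symptom codes (possibly empty).
#' @export
#' @examples
#' lex <- default_lexicon()
#' match_symptoms("yellow sclera ?jaundice", lex)
#' match_symptoms("family history pancreatic cancer", lex)
match_symptoms <- function(segment, lexicon) {
  stopifnot(inherits(lexicon, "pc_lexicon"), length(segment) == 1)
  m <- match_segments_matrix(segment, lexicon)
  codes <- colnames(m)[m[1, ]]
  codes[order(match(codes, canonical_symptoms()))]
}

#' Extract symptom events from encounter records
#'
#' Splits each encounter's reason text into segments, matches every segment
#' against the lexicon, and emits one event per (encounter, matched code)
#' pair with `source = "text"`. Multiple matches of the same code within one
#' encounter are deduplicated. Output order is stable: sorted by patient,
#' date, then canonical code order, independent of input row order.
#'
#' @param encounters Data frame with columns `patient_id`, `encounter_date`
#'   (Date) and `reason_text`.
#' @param lexicon A [symptom_lexicon()].
#' @param delimiters Passed to [split_reasons()].
#' @return Data frame of symptom events with columns `patient_id`,
#'   `event_date`, `symptom_code`, `source`, `provenance`.
#' @export
extract_symptom_events <- function(encounters, lexicon, delimiters = "[;,|\n]") {
  stopifnot(inherits(lexicon, "pc_lexicon"))
  req <- c("patient_id", "encounter_date", "reason_text")
  stopifnot(all(req %in% names(encounters)))
  if (nrow(encounters) == 0) return(empty_events())

  segs <- strsplit(as.character(encounters$reason_text), delimiters)
  nseg <- lengths(segs)
  seg_vec <- trimws(unlist(segs, use.names = FALSE))
  row_of <- rep(seq_len(nrow(encounters)), nseg)
  keep <- nzchar(seg_vec) & !is.na(seg_vec)
  seg_vec <- seg_vec[keep]
  row_of <- row_of[keep]

  m <- match_segments_matrix(seg_vec, lexicon)
  hits <- which(m, arr.ind = TRUE)
  if (nrow(hits) == 0) return(empty_events())

  ev <- data.frame(
    patient_id = encounters$patient_id[row_of[hits[, 1]]],
    event_date = encounters$encounter_date[row_of[hits[, 1]]],
    symptom_code = colnames(m)[hits[, 2]],
    source = "text",
    provenance = seg_vec[hits[, 1]],
    stringsAsFactors = FALSE
  )
  # one event per (encounter, code): the same code matched in two segments
  # of one encounter collapses to a single event
  ev <- ev[!duplicated(data.frame(row_of[hits[, 1]], ev$symptom_code)), ]
  order_events(ev)
}

empty_events <- function() {
  data.frame(
    patient_id = character(0),
    event_date = as.Date(character(0)),
    symptom_code = character(0),
    source = character(0),
    provenance = character(0),
    stringsAsFactors = FALSE
  )
}

order_events <- function(ev) {
  o <- order(ev$patient_id, ev$event_date,
             match(ev$symptom_code, canonical_symptoms()))
  ev <- ev[o, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}
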