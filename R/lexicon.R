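# Symptom lexicon: configurable regex inclusion/exclusion filters mapping
# free-text "reason for encounter" segments to canonical symptom codes.

#' Construct a symptom lexicon
#'
#' A lexicon is a list of entries, one per canonical symptom code, each with
#' case-insensitive `include` regular expressions and optional `exclude`
#' expressions. A segment maps to a code iff at least one include pattern
#' matches and no exclude pattern matches the same segment. Codes absent
#' from the lexicon can never be emitted by the text mapper (new-onset
#' diabetes, for instance, is derived from pathology and prescriptions, not
#' text, and is deliberately absent from the default lexicon).
#'
#' @param entries List of lists with elements `code` (canonical symptom
#'   code), `include` (character vector of regex patterns, non-empty) and
#'   optionally `exclude` (character vector of regex patterns).
#' @return Object of class `pc_lexicon`.
#' @export
symptom_lexicon <- function(entries) {
  if (!is.list(entries) || length(entries) == 0) {
    stop("lexicon must contain at least one entry", call. = FALSE)
  }
  codes <- vapply(entries, function(e) as.character(e$code %||% NA_character_),
                  character(1))
  if (anyNA(codes)) stop("every lexicon entry needs a 'code'", call. = FALSE)
  assert_canonical_codes(codes, "lexicon code")
  if (anyDuplicated(codes)) {
    stop(sprintf("duplicate lexicon code(s): %s",
                 paste(unique(codes[duplicated(codes)]), collapse = ", ")),
         call. = FALSE)
  }
  entries <- lapply(entries, function(e) {
    inc <- as.character(unlist(e$include))
    exc <- as.character(unlist(e$exclude))
    if (length(inc) == 0 || any(!nzchar(inc))) {
      stop(sprintf("lexicon entry '%s': include patterns must be non-empty",
                   e$code), call. = FALSE)
    }
    for (p in c(inc, exc)) {
      ok <- tryCatch({ grepl(p, "x", perl = TRUE); TRUE },
                     error = function(err) FALSE,
                     warning = function(w) FALSE)
      if (!ok) stop(sprintf("lexicon entry '%s': pattern does not compile: %s",
                            e$code, p), call. = FALSE)
    }
    list(code = as.character(e$code), include = inc, exclude = exc)
  })
  structure(list(entries = entries), class = "pc_lexicon")
}

#' @export
print.pc_lexicon <- function(x, ...) {
  cat(sprintf("<pc_lexicon> %d symptom codes\n", length(x$entries)))
  for (e in x$entries) {
    cat(sprintf("  %-24s %d include / %d exclude pattern(s)\n",
                e$code, length(e$include), length(e$exclude)))
  }
  invisible(x)
}

#' Load a symptom lexicon from YAML
#'
#' The YAML file is a list of `{code, include: [...], exclude: [...]}`
#' entries (see `inst/extdata/lexicon.yaml` for the shipped default).
#'
#' @param path Path to a YAML lexicon file.
#' @return A `pc_lexicon`.
#' @export
load_lexicon <- function(path) {
  symptom_lexicon(yaml::read_yaml(path))
}

#' The default symptom lexicon shipped with the package
#'
#' An illustrative, clinician-plausible regex lexicon over the canonical
#' symptom codes, including exclusion filters for common false-positive
#' phrasings ("family history ...", "no jaundice", intentional weight
#' loss). It is replaceable configuration, not a claim of fidelity to any
#' externally published filter list.
#'
#' @return A `pc_lexicon`.
#' @export
default_lexicon <- function() {
  load_lexicon(system.file("extdata", "lexicon.yaml", package = "panctriage",
                           mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
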