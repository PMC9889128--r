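# Mention recognition: longest-match dictionary lookup, toxin regular
# expressions, and prion/species co-occurrence.
#
# Offsets are 0-based, half-open, per field (title or abstract), so that for
# every mention substr(text, start + 1, end) == surface.

TOKEN_CHARS <- "A-Za-z0-9-"

empty_mentions <- function(with_context = TRUE) {
  base <- data.frame(start = integer(), end = integer(), surface = character(),
                     pathogen_id = character(), method = character(),
                     ambiguous_ids = character(), stringsAsFactors = FALSE)
  if (!with_context) return(base)
  cbind(data.frame(pmid = character(), field = character(),
                   stringsAsFactors = FALSE), base)
}

# token start positions (1-based) and a boundary lookup for a text
token_starts <- function(text) {
  m <- gregexpr(sprintf("[%s]+", TOKEN_CHARS), text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(integer())
  as.integer(m)
}

is_token_char <- function(text, pos) {
  # pos is 1-based; out-of-range counts as a boundary
  if (pos < 1L || pos > nchar(text)) return(FALSE)
  grepl(sprintf("[%s]", TOKEN_CHARS), substr(text, pos, pos), perl = TRUE)
}

#' Compile a dictionary into a matcher
#'
#' Builds a first-token index over the (case-folded) dictionary surfaces so
#' the scan only tests candidate surfaces whose first token matches the token
#' under the cursor. Compilation is deterministic.
#'
#' @param dictionary A non-empty `pm_dictionary`.
#' @return A `pm_matcher`.
#' @export
compile_matcher <- function(dictionary) {
  stopifnot(inherits(dictionary, "pm_dictionary"))
  if (!nrow(dictionary$entries)) stop("dictionary is empty", call. = FALSE)
  entries <- dictionary$entries
  low <- tolower(entries$surface)
  # one matcher node per distinct case-folded surface; all pathogen ids kept
  split_ids <- split(entries$pathogen_id, low)
  surfaces <- names(split_ids)
  ids <- lapply(split_ids, function(v) sort(unique(v)))
  first_tok <- vapply(surfaces, function(s) {
    regmatches(s, regexpr(sprintf("[%s]+", TOKEN_CHARS), s, perl = TRUE))
  }, character(1), USE.NAMES = FALSE)
  index <- split(seq_along(surfaces), first_tok)
  structure(list(surfaces = surfaces, nchars = nchar(surfaces), ids = ids,
                 index = index, case_policy = dictionary$case_policy),
            class = "pm_matcher")
}

#' @export
print.pm_matcher <- function(x, ...) {
  cat(sprintf("<pm_matcher> %d distinct surfaces, %d first-token buckets\n",
              length(x$surfaces), length(x$index)))
  invisible(x)
}

#' Find dictionary mentions in a text
#'
#' Scans left to right over token start positions. A surface matches at a
#' position when the case-folded text slice equals the surface and both slice
#' edges fall on token boundaries. Among candidates starting at the same
#' token the longest wins (so a subspecies term beats its parent species
#' term); matched spans never overlap — the scan resumes after the accepted
#' match. Equal-length candidates for different pathogens are resolved to the
#' lexicographically lowest `pathogen_id`, with all candidates recorded in
#' `ambiguous_ids`.
#'
#' @param matcher A `pm_matcher` from [compile_matcher()].
#' @param text A string (may be empty).
#' @return Mention data frame with 0-based half-open `start`/`end`, `surface`
#'   (the original text slice), `pathogen_id`, `method = "dictionary"`, and
#'   `ambiguous_ids` (comma-separated; `NA` when unambiguous).
#' @export
find_dictionary_mentions <- function(matcher, text) {
  stopifnot(inherits(matcher, "pm_matcher"))
  if (is.null(text) || is.na(text) || !nzchar(text)) return(empty_mentions(FALSE))
  low <- tolower(text)
  n <- nchar(text)
  starts <- token_starts(low)
  out <- list()
  i <- 1L
  min_pos <- 1L  # matched spans never overlap
  while (i <= length(starts)) {
    pos <- starts[i]
    if (pos < min_pos) { i <- i + 1L; next }
    rest <- substr(low, pos, n)
    tok <- regmatches(rest, regexpr(sprintf("[%s]+", TOKEN_CHARS), rest,
                                    perl = TRUE))
    cand <- matcher$index[[tok]]
    best_len <- 0L; best_ids <- NULL
    for (k in cand) {
      len <- matcher$nchars[k]
      if (len < best_len || pos + len - 1L > n) next
      if (substr(low, pos, pos + len - 1L) != matcher$surfaces[k]) next
      if (is_token_char(low, pos + len)) next  # must end at a token boundary
      if (len > best_len) {
        best_len <- len
        best_ids <- matcher$ids[[k]]
      } else {
        best_ids <- sort(unique(c(best_ids, matcher$ids[[k]])))
      }
    }
    if (best_len > 0L) {
      out[[length(out) + 1L]] <- data.frame(
        start = pos - 1L, end = pos - 1L + best_len,
        surface = substr(text, pos, pos + best_len - 1L),
        pathogen_id = best_ids[1],
        method = "dictionary",
        ambiguous_ids = if (length(best_ids) > 1L) paste(best_ids, collapse = ",")
                        else NA_character_,
        stringsAsFactors = FALSE)
      min_pos <- pos + best_len
    }
    i <- i + 1L
  }
  if (!length(out)) return(empty_mentions(FALSE))
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Build a toxin regular-expression bank
#'
#' One case-insensitive pattern per toxin, anchored on the toxin stem but
#' allowing letter prefixes and inflectional endings, so that forms embedded
#' in longer tokens ("onabotulinumtoxinA", "antiaflatoxinB1") are caught.
#' Unlike dictionary matching, the regex path is deliberately not constrained
#' to token boundaries. Every pattern must embed `(?i)` and compile.
#'
#' @param patterns Data frame with columns `pattern` and `pathogen_id`;
#'   defaults to the packaged bank covering aflatoxins, botulinum toxins,
#'   ciguatoxins, conotoxins, enterotoxins, saxitoxins and tetrodotoxin.
#' @return A `pm_regex_bank`.
#' @export
toxin_regex_bank <- function(patterns = default_toxin_patterns()) {
  stopifnot(all(c("pattern", "pathogen_id") %in% names(patterns)))
  for (i in seq_len(nrow(patterns))) {
    p <- patterns$pattern[i]
    if (!grepl("(?i)", p, fixed = TRUE)) {
      stop(sprintf("pattern for %s lacks the (?i) case-insensitivity directive",
                   patterns$pathogen_id[i]), call. = FALSE)
    }
    ok <- tryCatch({ regexpr(p, "", perl = TRUE); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop(sprintf("pattern for %s does not compile: %s",
                          patterns$pathogen_id[i], p), call. = FALSE)
  }
  structure(list(patterns = patterns), class = "pm_regex_bank")
}

toxin_stem_pattern <- function(stem) {
  sprintf("(?i)[a-z]*(?:%s)[a-z0-9-]*", stem)
}

#' @rdname toxin_regex_bank
#' @export
default_toxin_patterns <- function() {
  stems <- c(
    "toxin-aflatoxin"   = "aflatox",
    "toxin-botulinum"   = "botulinum ?(?:neuro)?tox",
    "toxin-ciguatoxin"  = "ciguatox",
    "toxin-conotoxin"   = "conotox",
    "toxin-enterotoxin" = "enterotox",
    "toxin-saxitoxin"   = "saxitox",
    "toxin-tetrodotoxin" = "tetrodotox"
  )
  data.frame(pattern = vapply(stems, toxin_stem_pattern, character(1),
                              USE.NAMES = FALSE),
             pathogen_id = names(stems), stringsAsFactors = FALSE)
}

#' Find toxin mentions in a text
#'
#' @param bank A `pm_regex_bank`.
#' @param text A string.
#' @return Mention data frame (`method = "regex"`). Matches of one pattern
#'   never overlap each other; overlaps across patterns or with dictionary
#'   mentions are resolved by [annotate_citation()].
#' @export
find_toxin_mentions <- function(bank, text) {
  stopifnot(inherits(bank, "pm_regex_bank"))
  if (is.null(text) || is.na(text) || !nzchar(text)) return(empty_mentions(FALSE))
  out <- list()
  for (i in seq_len(nrow(bank$patterns))) {
    m <- gregexpr(bank$patterns$pattern[i], text, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    lens <- attr(m, "match.length")
    out[[length(out) + 1L]] <- data.frame(
      start = as.integer(m) - 1L, end = as.integer(m) - 1L + lens,
      surface = substring(text, m, m + lens - 1L),
      pathogen_id = bank$patterns$pathogen_id[i],
      method = "regex", ambiguous_ids = NA_character_,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_mentions(FALSE))
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res[order(res$start, res$end, res$pathogen_id), , drop = FALSE]
}

#' Build a prion co-occurrence rule
#'
#' PrPSc prion variants are designated by host species, and the literature
#' signals them by a misfolded-protein term ("PrPSc", "prion") co-occurring
#' with the species name. The default species lexicon covers the common host
#' species, each matched by its common name and plural.
#'
#' @param prion_terms Terms denoting the misfolded protein form.
#' @param species Named list: species id fragment -> character vector of
#'   surface terms. Pathogen ids are `prpsc-<species>`.
#' @return A `pm_prion_rule`.
#' @export
prion_rule <- function(prion_terms = c("PrPSc", "prion", "prions"),
                       species = default_prion_species()) {
  stopifnot(length(prion_terms) > 0, length(species) > 0, !is.null(names(species)))
  structure(list(prion_terms = prion_terms, species = species),
            class = "pm_prion_rule")
}

#' @rdname prion_rule
#' @export
default_prion_species <- function() {
  base <- c("sheep", "human", "cattle", "cat", "deer", "goat", "mink",
            "elk", "greater kudu", "moose", "mule", "nyala", "onyx", "ostrich")
  out <- lapply(base, function(s) {
    plural <- switch(s,
      sheep = , cattle = , deer = , moose = , nyala = character(),  # invariant plurals
      paste0(s, "s"))
    unique(c(s, plural))
  })
  names(out) <- gsub(" ", "-", base)
  out
}

boundary_pattern <- function(term) {
  sprintf("(?i)(?<![%s])%s(?![%s])", TOKEN_CHARS,
          gsub("([][{}()*+?.\\^$|])", "\\\\\\1", term), TOKEN_CHARS)
}

find_term_spans <- function(term, text) {
  if (is.null(text) || is.na(text) || !nzchar(text)) {
    return(data.frame(start = integer(), end = integer(), surface = character(),
                      stringsAsFactors = FALSE))
  }
  m <- gregexpr(boundary_pattern(term), text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(), end = integer(), surface = character(),
                      stringsAsFactors = FALSE))
  }
  lens <- attr(m, "match.length")
  data.frame(start = as.integer(m) - 1L, end = as.integer(m) - 1L + lens,
             surface = substring(text, m, m + lens - 1L), stringsAsFactors = FALSE)
}

#' Find prion mentions in a citation
#'
#' Emits one mention per species-term occurrence (in title or abstract) when
#' a prion term occurs anywhere in the same citation; nothing when either
#' side is absent.
#'
#' @param rule A `pm_prion_rule`.
#' @param cit A [citation()].
#' @return Mention data frame with `field` column (`method = "prion"`).
#' @export
find_prion_mentions <- function(rule, cit) {
  stopifnot(inherits(rule, "pm_prion_rule"), inherits(cit, "pm_citation"))
  fields <- list(title = cit$title, abstract = cit$abstract)
  has_prion <- any(vapply(rule$prion_terms, function(tm) {
    any(vapply(fields, function(tx) {
      !is.null(tx) && nrow(find_term_spans(tm, tx)) > 0
    }, logical(1)))
  }, logical(1)))
  if (!has_prion) return(empty_mentions(TRUE))
  out <- list()
  for (field in names(fields)) {
    text <- fields[[field]]
    if (is.null(text)) next
    for (sp in names(rule$species)) {
      for (tm in rule$species[[sp]]) {
        spans <- find_term_spans(tm, text)
        if (!nrow(spans)) next
        out[[length(out) + 1L]] <- cbind(
          data.frame(pmid = cit$pmid, field = field, stringsAsFactors = FALSE),
          spans,
          data.frame(pathogen_id = paste0("prpsc-", sp), method = "prion",
                     ambiguous_ids = NA_character_, stringsAsFactors = FALSE))
      }
    }
  }
  if (!length(out)) return(empty_mentions(TRUE))
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res <- res[!duplicated(res[, c("field", "start", "end", "pathogen_id")]), , drop = FALSE]
  res[order(match(res$field, c("title", "abstract")), res$start, res$pathogen_id),
      c("pmid", "field", "start", "end", "surface", "pathogen_id", "method",
        "ambiguous_ids"), drop = FALSE]
}

method_rank <- c(dictionary = 1L, regex = 2L, prion = 3L)

resolve_overlaps <- function(mentions) {
  if (nrow(mentions) < 2L) return(mentions)
  ord <- order(mentions$start, -(mentions$end - mentions$start),
               method_rank[mentions$method], mentions$pathogen_id)
  # leftmost-longest greedy; on full ties, dictionary beats regex beats prion,
  # then lowest pathogen_id
  cand <- mentions[ord, , drop = FALSE]
  kept <- logical(nrow(cand))
  occupied_end <- -1L
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] >= occupied_end) {
      # no overlap with anything accepted so far at this or an earlier start?
      overlap <- FALSE
      if (any(kept)) {
        ks <- which(kept)
        overlap <- any(cand$start[ks] < cand$end[i] & cand$end[ks] > cand$start[i])
      }
      if (!overlap) {
        kept[i] <- TRUE
        occupied_end <- max(occupied_end, cand$end[i])
      }
    }
  }
  res <- cand[kept, , drop = FALSE]
  res[order(res$start), , drop = FALSE]
}

#' Annotate one citation with all three recognizers
#'
#' Union of dictionary, toxin-regex and prion mentions over title and
#' abstract (title only when the abstract is absent). Overlapping spans
#' within a field are resolved to the longest; on length ties a dictionary
#' mention beats a regex mention beats a prion mention, then the lowest
#' `pathogen_id`. Output is sorted by (field, start).
#'
#' @param cit A [citation()].
#' @param matcher Optional `pm_matcher`.
#' @param bank Optional `pm_regex_bank`.
#' @param rule Optional `pm_prion_rule`.
#' @return Mention data frame with columns `pmid`, `field`, `start`, `end`,
#'   `surface`, `pathogen_id`, `method`, `ambiguous_ids`.
#' @export
annotate_citation <- function(cit, matcher = NULL, bank = NULL, rule = NULL) {
  stopifnot(inherits(cit, "pm_citation"))
  fields <- list(title = cit$title, abstract = cit$abstract)
  prion <- if (!is.null(rule)) find_prion_mentions(rule, cit) else empty_mentions(TRUE)
  parts <- list()
  for (field in names(fields)) {
    text <- fields[[field]]
    if (is.null(text)) next
    span_parts <- list()
    if (!is.null(matcher)) span_parts$dict <- find_dictionary_mentions(matcher, text)
    if (!is.null(bank)) span_parts$regex <- find_toxin_mentions(bank, text)
    spans <- do.call(rbind, c(unname(span_parts), make.row.names = FALSE))
    field_mentions <- if (!is.null(spans) && nrow(spans)) {
      cbind(data.frame(pmid = cit$pmid, field = field, stringsAsFactors = FALSE),
            spans)[, names(empty_mentions(TRUE)), drop = FALSE]
    } else empty_mentions(TRUE)
    field_mentions <- rbind(field_mentions, prion[prion$field == field, , drop = FALSE])
    parts[[field]] <- resolve_overlaps(field_mentions)
  }
  res <- do.call(rbind, c(parts, make.row.names = FALSE))
  if (is.null(res) || !nrow(res)) return(empty_mentions(TRUE))
  res[order(match(res$field, c("title", "abstract")), res$start), , drop = FALSE]
}

#' Annotate every citation in a corpus
#'
#' @param x A `pm_corpus`.
#' @inheritParams annotate_citation
#' @return One mention data frame for the whole corpus, citations in corpus
#'   order.
#' @export
annotate_corpus <- function(x, matcher = NULL, bank = NULL, rule = NULL) {
  stopifnot(inherits(x, "pm_corpus"))
  parts <- lapply(x$citations, annotate_citation,
                  matcher = matcher, bank = bank, rule = rule)
  res <- do.call(rbind, c(parts, make.row.names = FALSE))
  if (is.null(res)) empty_mentions(TRUE) else res
}

#' Write and read mentions as JSON Lines
#'
#' One object per mention with fields pmid, field, start, end, surface,
#' pathogen_id, method.
#'
#' @param mentions Mention data frame.
#' @param path File path.
#' @return `write_mentions` returns `path` invisibly; `read_mentions` the
#'   data frame.
#' @export
write_mentions <- function(mentions, path) {
  lines <- vapply(seq_len(nrow(mentions)), function(i) {
    jsonlite::toJSON(as.list(mentions[i, , drop = FALSE]), auto_unbox = TRUE,
                     na = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_mentions
#' @export
read_mentions <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_mentions(TRUE))
  rows <- lapply(seq_along(lines), function(i) {
    rec <- jsonlite::fromJSON(lines[i], simplifyVector = TRUE)
    data.frame(pmid = rec$pmid, field = rec$field,
               start = as.integer(rec$start), end = as.integer(rec$end),
               surface = rec$surface, pathogen_id = rec$pathogen_id,
               method = rec$method,
               ambiguous_ids = rec$ambiguous_ids %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
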