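# Citation records and corpora: constructors, PubMed XML and JSON Lines I/O.

#' Create a citation record
#'
#' A citation is one MEDLINE/PubMed record: a PMID, a title, an optional
#' abstract, and the MeSH descriptors under which the article was indexed.
#' The title and abstract are the only text fields the recognizers scan.
#'
#' @param pmid Non-empty string, unique within a corpus.
#' @param title Non-empty string.
#' @param abstract Optional string; `NULL` when the record has no abstract
#'   (roughly a fifth of MEDLINE citations carry only a title).
#' @param mesh Data frame with columns `id` and `name`, one row per MeSH
#'   descriptor. Qualifier terms are not represented; labeling works at
#'   descriptor level.
#' @param pubtypes Optional character vector of publication types.
#' @return An object of class `pm_citation`.
#' @export
citation <- function(pmid, title, abstract = NULL, mesh = empty_mesh(),
                     pubtypes = character()) {
  if (!is.character(pmid) || length(pmid) != 1L || !nzchar(pmid)) {
    stop("`pmid` must be a single non-empty string", call. = FALSE)
  }
  if (!is.character(title) || length(title) != 1L || !nzchar(title)) {
    stop(sprintf("citation %s: `title` must be a single non-empty string", pmid),
         call. = FALSE)
  }
  if (!is.null(abstract)) {
    stopifnot(is.character(abstract), length(abstract) == 1L)
  }
  mesh <- as.data.frame(mesh, stringsAsFactors = FALSE)
  if (!all(c("id", "name") %in% names(mesh))) {
    stop("`mesh` must have columns `id` and `name`", call. = FALSE)
  }
  structure(
    list(pmid = pmid, title = title, abstract = abstract,
         mesh = mesh[, c("id", "name"), drop = FALSE],
         pubtypes = as.character(pubtypes)),
    class = "pm_citation"
  )
}

empty_mesh <- function() {
  data.frame(id = character(), name = character(), stringsAsFactors = FALSE)
}

#' Assemble citations into a corpus
#'
#' @param citations List of [citation()] objects.
#' @param source Provenance string (e.g. the file the corpus was read from).
#' @return An object of class `pm_corpus`: an ordered, PMID-keyed collection.
#'   Duplicate PMIDs are an error, never silently dropped.
#' @export
corpus <- function(citations = list(), source = NA_character_) {
  ok <- vapply(citations, inherits, logical(1), what = "pm_citation")
  if (!all(ok)) stop("all elements must be `pm_citation` objects", call. = FALSE)
  pmids <- vapply(citations, `[[`, character(1), "pmid")
  dup <- unique(pmids[duplicated(pmids)])
  if (length(dup)) {
    stop("duplicate PMIDs in corpus: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  names(citations) <- pmids
  structure(list(citations = citations, source = source), class = "pm_corpus")
}

#' @export
length.pm_corpus <- function(x) length(x$citations)

#' @export
print.pm_corpus <- function(x, ...) {
  n_abs <- sum(vapply(x$citations, function(cit) !is.null(cit$abstract), logical(1)))
  cat(sprintf("<pm_corpus> %d citations (%d with abstract)", length(x), n_abs))
  if (!is.na(x$source)) cat(sprintf(" from %s", x$source))
  cat("\n")
  invisible(x)
}

#' Look up one citation by PMID
#'
#' @param x A `pm_corpus`.
#' @param pmid PMID string.
#' @return The `pm_citation`; error if absent.
#' @export
get_citation <- function(x, pmid) {
  cit <- x$citations[[pmid]]
  if (is.null(cit)) stop("unknown PMID: ", pmid, call. = FALSE)
  cit
}

#' Read a PubMed/MEDLINE XML article set
#'
#' Parses the `PubmedArticleSet` dialect. Each `PubmedArticle` yields one
#' citation; structured abstracts (several `AbstractText` sections) are
#' concatenated with single spaces in document order; `MeshHeadingList`
#' descriptors are kept, qualifiers ignored. Articles without a PMID are
#' skipped with a warning.
#'
#' @param path Path to a PubMed XML file.
#' @return A [corpus()].
#' @export
read_pubmed_xml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed PubMed XML in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  articles <- xml2::xml_find_all(doc, ".//PubmedArticle")
  cits <- vector("list", length(articles))
  keep <- logical(length(articles))
  for (i in seq_along(articles)) {
    art <- articles[[i]]
    pmid <- xml2::xml_text(xml2::xml_find_first(art, ".//MedlineCitation/PMID"))
    if (is.na(pmid) || !nzchar(pmid)) {
      warning(sprintf("article %d has no PMID; skipped", i), call. = FALSE)
      next
    }
    title <- xml2::xml_text(xml2::xml_find_first(art, ".//Article/ArticleTitle"))
    abst_nodes <- xml2::xml_find_all(art, ".//Article/Abstract/AbstractText")
    abstract <- if (length(abst_nodes)) {
      paste(xml2::xml_text(abst_nodes), collapse = " ")
    } else NULL
    mh <- xml2::xml_find_all(art, ".//MeshHeadingList/MeshHeading/DescriptorName")
    mesh <- data.frame(
      id = xml2::xml_attr(mh, "UI"),
      name = xml2::xml_text(mh),
      stringsAsFactors = FALSE
    )
    pt <- xml2::xml_text(xml2::xml_find_all(art, ".//PublicationTypeList/PublicationType"))
    cits[[i]] <- citation(pmid, title, abstract, mesh, pt)
    keep[i] <- TRUE
  }
  corpus(cits[keep], source = path)
}

citation_to_list <- function(cit) {
  list(
    pmid = cit$pmid,
    title = cit$title,
    abstract = cit$abstract,
    mesh = if (nrow(cit$mesh)) {
      lapply(seq_len(nrow(cit$mesh)),
             function(i) list(id = cit$mesh$id[i], name = cit$mesh$name[i]))
    } else list(),
    pubtypes = as.list(cit$pubtypes)
  )
}

#' Write and read a corpus as JSON Lines
#'
#' One JSON object per line with fields `pmid`, `title`, `abstract` (omitted
#' when absent), `mesh` (array of `{id, name}`) and `pubtypes`. The round
#' trip `read_jsonl(write_jsonl(x, path))` is field-for-field lossless.
#'
#' @param x A `pm_corpus`.
#' @param path Output (or input) file path.
#' @return `write_jsonl` returns `path` invisibly; `read_jsonl` returns a
#'   [corpus()].
#' @export
write_jsonl <- function(x, path) {
  stopifnot(inherits(x, "pm_corpus"))
  lines <- vapply(x$citations, function(cit) {
    jsonlite::toJSON(citation_to_list(cit), auto_unbox = TRUE, null = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_jsonl
#' @export
read_jsonl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  cits <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) stop(sprintf("malformed JSON on line %d of %s: %s",
                                                     i, path, conditionMessage(e)),
                                             call. = FALSE))
    mesh <- if (length(rec$mesh)) {
      data.frame(
        id = vapply(rec$mesh, function(m) as.character(m$id), character(1)),
        name = vapply(rec$mesh, function(m) as.character(m$name), character(1)),
        stringsAsFactors = FALSE
      )
    } else empty_mesh()
    cits[[i]] <- citation(rec$pmid, rec$title,
                          abstract = if (is.null(rec$abstract)) NULL else rec$abstract,
                          mesh = mesh,
                          pubtypes = unlist(rec$pubtypes) %||% character())
  }
  corpus(cits, source = path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Abstract availability accounting
#'
#' @param x A non-empty `pm_corpus`.
#' @return A list with `n_total`, `n_without_abstract` and `percent_without`
#'   (100 x n_without / n_total, reported to 2 decimals).
#' @export
abstract_stats <- function(x) {
  stopifnot(inherits(x, "pm_corpus"))
  n <- length(x)
  if (n == 0L) stop("corpus is empty", call. = FALSE)
  n_without <- sum(vapply(x$citations, function(cit) is.null(cit$abstract), logical(1)))
  abstract_stats_counts(n, n_without)
}

#' @rdname abstract_stats
#' @param n_total,n_without_abstract Raw counts, for accounting over corpora
#'   that are summarised rather than held in memory.
#' @export
abstract_stats_counts <- function(n_total, n_without_abstract) {
  stopifnot(n_total >= 1, n_without_abstract >= 0, n_without_abstract <= n_total)
  list(n_total = n_total, n_without_abstract = n_without_abstract,
       percent_without = round_half_away(100 * n_without_abstract / n_total, 2L))
}

# round half away from zero (base round() is banker's rounding)
round_half_away <- function(x, digits) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
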