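# Weak supervision: MeSH-derived relevance labels and entity masking.
#
# The labeling assumption: if a pathogen appears among the MeSH index terms
# of a citation, the pathogen is a focus entity of that article and treated
# as experimentally studied; otherwise the mention is background.

MASK_TOKEN <- "@PATHOGEN$"

#' The mask token substituted for pathogen mentions
#'
#' @return The constant string `"@PATHOGEN$"`, chosen so that it can never be
#'   produced by tokenizing natural text.
#' @export
mask_token <- function() MASK_TOKEN

#' Build a pathogen-to-MeSH link table
#'
#' @param records List of [pathogen_record()] objects (the registry).
#' @return A `pm_mesh_link`: named list mapping every registry
#'   `pathogen_id` to its (possibly empty) set of MeSH descriptor ids/names.
#' @export
mesh_link <- function(records) {
  ids <- vapply(records, `[[`, character(1), "pathogen_id")
  stopifnot(!anyDuplicated(ids))
  link <- lapply(records, `[[`, "mesh_descriptors")
  names(link) <- ids
  structure(link, class = "pm_mesh_link")
}

#' Weak relevance label for one (citation, pathogen) pair
#'
#' @param cit A [citation()].
#' @param pathogen_id Pathogen in the link table; unknown ids are an error.
#' @param link A [mesh_link()].
#' @return `"relevant"` iff the citation's MeSH descriptors (ids or names)
#'   intersect the pathogen's descriptor set, else `"irrelevant"`.
#' @export
label_pair <- function(cit, pathogen_id, link) {
  stopifnot(inherits(cit, "pm_citation"), inherits(link, "pm_mesh_link"))
  if (!pathogen_id %in% names(link)) {
    stop("unknown pathogen in MeSH link table: ", pathogen_id, call. = FALSE)
  }
  cite_terms <- c(cit$mesh$id, cit$mesh$name)
  if (length(intersect(cite_terms, link[[pathogen_id]]))) "relevant" else "irrelevant"
}

mask_field <- function(text, starts, ends) {
  if (!length(starts)) return(text)
  if (any(starts < 0 | ends > nchar(text) | starts >= ends)) {
    stop("mention offsets out of range for field text", call. = FALSE)
  }
  ord <- order(starts)
  if (any(ends[ord][-length(ord)] > starts[ord][-1])) {
    stop("overlapping mentions cannot be masked", call. = FALSE)
  }
  # right-to-left so earlier offsets stay valid
  for (i in rev(ord)) {
    text <- paste0(substr(text, 1L, starts[i]), MASK_TOKEN,
                   substring(text, ends[i] + 1L))
  }
  text
}

#' Mask one pathogen's mentions in a citation
#'
#' Replaces every given mention span by the mask token, right-to-left per
#' field, and joins title and abstract with a single newline. Text outside
#' mention spans is unchanged.
#'
#' @param cit A [citation()].
#' @param mentions Mention data frame rows, all for this citation and one
#'   pathogen (other pathogens' mentions are left as surface text).
#' @return The masked text (one string).
#' @export
mask_citation <- function(cit, mentions) {
  stopifnot(inherits(cit, "pm_citation"))
  if (nrow(mentions)) {
    if (!all(mentions$pmid == cit$pmid)) {
      stop("mentions do not all belong to citation ", cit$pmid, call. = FALSE)
    }
    if (length(unique(mentions$pathogen_id)) > 1L) {
      stop("mask_citation masks one pathogen at a time", call. = FALSE)
    }
  }
  title <- with(mentions[mentions$field == "title", , drop = FALSE],
                mask_field(cit$title, start, end))
  parts <- title
  if (!is.null(cit$abstract)) {
    abstract <- with(mentions[mentions$field == "abstract", , drop = FALSE],
                     mask_field(cit$abstract, start, end))
    parts <- c(parts, abstract)
  }
  paste(parts, collapse = "\n")
}

#' Build the weakly labeled training set
#'
#' One example per (citation, pathogen) pair with at least one recognized
#' mention, labeled by [label_pair()] and masked by [mask_citation()].
#' Pathogens absent from the link table's registry are an error; pathogens
#' registered with an empty MeSH mapping yield no examples (their label is
#' undecidable, and emitting them would create systematically wrong
#' negatives) — they are still recognized and filtered at inference.
#'
#' @param x A `pm_corpus`.
#' @param mentions Mentions from [annotate_corpus()] on the same corpus.
#' @param link A [mesh_link()] covering every mentioned pathogen.
#' @return Data frame (`pmid`, `pathogen_id`, `text`, `label`) sorted by
#'   (pmid, pathogen_id).
#' @export
build_training_set <- function(x, mentions, link) {
  stopifnot(inherits(x, "pm_corpus"), inherits(link, "pm_mesh_link"))
  unknown <- setdiff(unique(mentions$pmid), names(x$citations))
  if (length(unknown)) {
    stop("mentions reference unknown PMIDs: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  pairs <- unique(mentions[, c("pmid", "pathogen_id")])
  pairs <- pairs[order(pairs$pmid, pairs$pathogen_id), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    pid <- pairs$pathogen_id[i]
    if (!pid %in% names(link)) {
      stop("mention pathogen not in MeSH link table: ", pid, call. = FALSE)
    }
    if (!length(link[[pid]])) next  # no MeSH mapping: label undecidable
    cit <- get_citation(x, pairs$pmid[i])
    sel <- mentions[mentions$pmid == pairs$pmid[i] & mentions$pathogen_id == pid, ,
                    drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      pmid = cit$pmid, pathogen_id = pid,
      text = mask_citation(cit, sel),
      label = label_pair(cit, pid, link),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(pmid = character(), pathogen_id = character(),
                      text = character(), label = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Write and read labeled examples as JSON Lines
#'
#' One object per example with fields pmid, pathogen_id, text, label.
#'
#' @param examples Data frame from [build_training_set()].
#' @param path File path.
#' @export
write_examples <- function(examples, path) {
  lines <- vapply(seq_len(nrow(examples)), function(i) {
    jsonlite::toJSON(as.list(examples[i, , drop = FALSE]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_examples
#' @export
read_examples <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    data.frame(pmid = rec$pmid, pathogen_id = rec$pathogen_id, text = rec$text,
               label = rec$label, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Write and read a MeSH link table as TSV
#'
#' One line per (pathogen, descriptor): `pathogen_id TAB descriptor`.
#' Pathogens with an empty mapping are written as a single line with an empty
#' descriptor field so the registry stays total on read.
#'
#' @param link A [mesh_link()].
#' @param path File path.
#' @export
write_mesh_link <- function(link, path) {
  stopifnot(inherits(link, "pm_mesh_link"))
  lines <- unlist(lapply(names(link), function(pid) {
    if (length(link[[pid]])) paste(pid, link[[pid]], sep = "\t")
    else paste0(pid, "\t")
  }))
  writeLines(c("pathogen_id\tdescriptor", lines), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_mesh_link
#' @export
read_mesh_link <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  link <- lapply(split(df$descriptor, df$pathogen_id), function(v) v[nzchar(v)])
  structure(link[unique(df$pathogen_id)], class = "pm_mesh_link")
}
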