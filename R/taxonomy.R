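# OBO taxonomy reading and subtree term collection.
#
# The NCBI Taxonomy as distributed by the OBO Foundry is a flat OBO 1.2/1.4
# file of [Term] stanzas. No installed package parses OBO, and the pipeline
# needs only four stanza fields (id, name, synonym, is_a), so the reader is
# implemented here directly.

#' Load a taxonomy from an OBO flat file
#'
#' Reads `[Term]` stanzas and keeps, per term: its identifier, scientific
#' name, synonyms and `is_a` parent. Obsolete terms are excluded. Synonyms
#' with `EXACT` or `RELATED` scope (and scopeless synonyms, whose OBO default
#' is `RELATED`) are harvested; `BROAD` and `NARROW` synonyms are not, to
#' limit false-positive lexicon entries.
#'
#' @param path Path to an OBO file.
#' @return A `pm_taxonomy`: a node table keyed by taxon id plus a child index.
#' @export
load_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  parse_obo_terms(lines)
}

parse_obo_terms <- function(lines) {
  # stanza boundaries: lines of the form [Name]
  stanza_starts <- grep("^\\[[^]]+\\]\\s*$", lines)
  nodes <- list()
  for (k in seq_along(stanza_starts)) {
    from <- stanza_starts[k]
    if (!identical(trimws(lines[from]), "[Term]")) next
    to <- if (k < length(stanza_starts)) stanza_starts[k + 1] - 1L else length(lines)
    body <- lines[(from + 1L):to]
    body <- body[nzchar(trimws(body)) & !startsWith(trimws(body), "!")]
    node <- parse_term_stanza(body, stanza_line = from)
    if (is.null(node)) next  # obsolete
    if (!is.null(nodes[[node$taxon_id]])) {
      stop(sprintf("malformed OBO: duplicate term id %s (stanza at line %d)",
                   node$taxon_id, from), call. = FALSE)
    }
    nodes[[node$taxon_id]] <- node
  }
  new_taxonomy(nodes)
}

parse_term_stanza <- function(body, stanza_line) {
  field <- sub(":.*$", "", body)
  value <- trimws(sub("^[^:]+:", "", body))
  get1 <- function(f) {
    v <- value[field == f]
    if (length(v)) v[[1]] else NA_character_
  }
  if (identical(tolower(get1("is_obsolete")), "true")) return(NULL)
  id <- get1("id")
  name <- get1("name")
  if (is.na(id) || !nzchar(id) || is.na(name) || !nzchar(name)) {
    stop(sprintf("malformed OBO: term stanza at line %d lacks id or name", stanza_line),
         call. = FALSE)
  }
  syn_raw <- value[field == "synonym"]
  syns <- character()
  for (s in syn_raw) {
    m <- regmatches(s, regexec('^"((?:[^"\\\\]|\\\\.)*)"\\s*([A-Z]*)', s))[[1]]
    if (length(m) < 2L) {
      stop(sprintf("malformed OBO: unparseable synonym line in stanza at line %d: %s",
                   stanza_line, s), call. = FALSE)
    }
    scope <- if (nzchar(m[3])) m[3] else "RELATED"
    if (scope %in% c("EXACT", "RELATED")) {
      syns <- c(syns, gsub('\\\\(.)', "\\1", m[2]))
    }
  }
  parent <- get1("is_a")
  if (!is.na(parent)) parent <- trimws(sub("!.*$", "", parent))
  list(taxon_id = id, scientific_name = name,
       other_names = unique(syns),
       parent_id = if (is.na(parent) || !nzchar(parent)) NA_character_ else parent)
}

new_taxonomy <- function(nodes) {
  children <- list()
  for (node in nodes) {
    p <- node$parent_id
    if (!is.na(p)) children[[p]] <- c(children[[p]], node$taxon_id)
  }
  structure(list(nodes = nodes, children = children), class = "pm_taxonomy")
}

#' @export
length.pm_taxonomy <- function(x) length(x$nodes)

#' @export
print.pm_taxonomy <- function(x, ...) {
  n_par <- sum(vapply(x$nodes, function(n) !is.na(n$parent_id), logical(1)))
  cat(sprintf("<pm_taxonomy> %d terms (%d with parent links)\n", length(x), n_par))
  invisible(x)
}

taxon_node <- function(taxonomy, taxon_id) {
  node <- taxonomy$nodes[[taxon_id]]
  if (is.null(node)) stop("unknown taxon id: ", taxon_id, call. = FALSE)
  node
}

#' Collect names and synonyms for a taxon subtree
#'
#' Returns the scientific name and synonyms of the root taxon and of every
#' transitive descendant (subspecies and strains), the raw material for one
#' pathogen's lexicon entries. Subspecies terms are what make longest-match
#' lookup prefer the most specific form (e.g. a strain designation over the
#' bare species name).
#'
#' @param taxonomy A `pm_taxonomy`.
#' @param root_taxon_id Taxon id present in `taxonomy`.
#' @return Data frame with columns `term`, `taxon_id`, `provenance`
#'   (`scientific_name` / `synonym` for the root, `subspecies` for any
#'   descendant's name or synonym).
#' @export
collect_subtree_terms <- function(taxonomy, root_taxon_id) {
  stopifnot(inherits(taxonomy, "pm_taxonomy"))
  root_taxon_id <- unname(root_taxon_id)
  taxon_node(taxonomy, root_taxon_id)  # errors on unknown id
  out_term <- character(); out_id <- character(); out_prov <- character()
  stack <- root_taxon_id
  seen <- character()
  while (length(stack)) {
    id <- stack[[1]]
    stack <- stack[-1]
    if (id %in% seen) stop("cycle detected in taxonomy at ", id, call. = FALSE)
    seen <- c(seen, id)
    node <- taxonomy$nodes[[id]]
    is_root <- identical(id, root_taxon_id)
    out_term <- c(out_term, node$scientific_name, node$other_names)
    out_id <- c(out_id, rep(id, 1L + length(node$other_names)))
    out_prov <- c(out_prov,
                  if (is_root) "scientific_name" else "subspecies",
                  rep(if (is_root) "synonym" else "subspecies",
                      length(node$other_names)))
    kids <- taxonomy$children[[id]]
    if (length(kids)) stack <- c(kids, stack)
  }
  data.frame(term = out_term, taxon_id = out_id, provenance = out_prov,
             stringsAsFactors = FALSE)
}
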