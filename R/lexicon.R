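# Pathogen records and the normalization cascade that yields the matching
# dictionary.

#' Create a pathogen-of-interest record
#'
#' One record per pathogen the pipeline should track. The category decides
#' which recognizer handles it: `organism` terms go through the dictionary,
#' `toxin` mentions are matched by regular expressions, `prion` mentions by
#' prion-term/species co-occurrence.
#'
#' @param pathogen_id Unique identifier (e.g. a taxon id, `toxin-aflatoxin`,
#'   `prpsc-sheep`).
#' @param canonical_name Display name.
#' @param category One of `"organism"`, `"prion"`, `"toxin"`.
#' @param taxon_ids Taxon ids covered (root plus subspecies); required
#'   non-empty for organisms, must be empty otherwise.
#' @param mesh_descriptors MeSH descriptor ids/names used for weak labeling
#'   and PubMed retrieval.
#' @param raw_terms Character vector of surface terms before normalization, or
#'   a data frame with columns `term` and `provenance` as produced by
#'   [collect_subtree_terms()].
#' @return A `pm_pathogen` record.
#' @export
pathogen_record <- function(pathogen_id, canonical_name,
                            category = c("organism", "prion", "toxin"),
                            taxon_ids = character(),
                            mesh_descriptors = character(),
                            raw_terms = character()) {
  category <- match.arg(category)
  pathogen_id <- unname(pathogen_id)
  stopifnot(is.character(pathogen_id), length(pathogen_id) == 1L, nzchar(pathogen_id))
  if (category == "organism" && !length(taxon_ids)) {
    stop(sprintf("organism record %s needs at least one taxon id", pathogen_id),
         call. = FALSE)
  }
  if (category != "organism" && length(taxon_ids)) {
    stop(sprintf("%s record %s must not carry taxon ids", category, pathogen_id),
         call. = FALSE)
  }
  if (is.character(raw_terms)) {
    raw_terms <- data.frame(term = raw_terms,
                            provenance = rep("synonym", length(raw_terms)),
                            stringsAsFactors = FALSE)
  }
  stopifnot(all(c("term", "provenance") %in% names(raw_terms)))
  raw_terms <- raw_terms[!duplicated(raw_terms$term), , drop = FALSE]
  structure(
    list(pathogen_id = pathogen_id, canonical_name = canonical_name,
         category = category, taxon_ids = unique(taxon_ids),
         mesh_descriptors = unique(mesh_descriptors), raw_terms = raw_terms),
    class = "pm_pathogen"
  )
}

#' Build an organism record from a taxonomy subtree
#'
#' Convenience wrapper: collects the root's and all descendants' names and
#' synonyms via [collect_subtree_terms()] and wraps them in a record.
#'
#' @inheritParams collect_subtree_terms
#' @param pathogen_id Identifier for the record; defaults to the root taxon id.
#' @param mesh_descriptors MeSH descriptors for the pathogen.
#' @return A `pm_pathogen` of category `organism`.
#' @export
organism_record <- function(taxonomy, root_taxon_id, pathogen_id = root_taxon_id,
                            mesh_descriptors = character()) {
  terms <- collect_subtree_terms(taxonomy, root_taxon_id)
  pathogen_record(pathogen_id,
                  canonical_name = taxon_node(taxonomy, root_taxon_id)$scientific_name,
                  category = "organism",
                  taxon_ids = unique(terms$taxon_id),
                  mesh_descriptors = mesh_descriptors,
                  raw_terms = terms)
}

is_virus_term <- function(term) {
  toks <- strsplit(trimws(term), "\\s+")[[1]]
  length(toks) > 0L && tolower(toks[length(toks)]) == "virus"
}

strip_trailing_virus <- function(term) {
  trimws(sub("\\s+\\S+$", "", trimws(term)))
}

#' Normalize organism terms for the matching dictionary
#'
#' Applies, in order: (1) delete the token "subtype" ("H1N1 subtype" becomes
#' "H1N1"); (2) discard terms whose lower-cased form starts with
#' `"influenza a virus ("` or `"influenza b virus ("` — these strain-level
#' entries exist in the thousands and contribute nothing to recall; (3) for
#' virus terms (last whitespace token is "virus"), additionally emit the
#' variant with the trailing "virus" removed, keeping both, since prose often
#' leaves the virus implied ("influenza A" vs "influenza A virus"); (4)
#' discard single-letter virus names such as "B virus", which would otherwise
#' fire inside unrelated virus names; (5) discard any term of 3 characters or
#' fewer. Output is deduplicated case-insensitively, first-seen casing and
#' order preserved. The cascade is idempotent.
#'
#' @param raw_terms Character vector.
#' @return Character vector of surviving normalized terms.
#' @export
normalize_organism_terms <- function(raw_terms) {
  if (!length(raw_terms)) return(character())
  out <- character()
  for (term in raw_terms) {
    term <- trimws(gsub("\\s+", " ", term))
    # (1) drop the token "subtype"
    term <- trimws(gsub("\\s+", " ",
                        gsub("(?i)(^|\\s)subtype(\\s|$)", " ", term, perl = TRUE)))
    if (!nzchar(term)) next
    # (2) bulk influenza strain entries
    low <- tolower(term)
    if (startsWith(low, "influenza a virus (") || startsWith(low, "influenza b virus (")) next
    variants <- term
    if (is_virus_term(term)) {
      # (4) single-letter virus names are discarded outright
      toks <- strsplit(term, " ", fixed = TRUE)[[1]]
      if (length(toks) == 2L && nchar(toks[1]) == 1L) next
      # (3) keep both the full form and the "virus"-less variant
      stripped <- strip_trailing_virus(term)
      if (nzchar(stripped)) variants <- c(variants, stripped)
    }
    # (5) more-than-three-characters rule
    variants <- variants[nchar(variants) > 3L]
    out <- c(out, variants)
  }
  out[!duplicated(tolower(out))]
}

#' Build the matching dictionary from pathogen records
#'
#' Runs the normalization cascade on every record's raw terms and assembles
#' the surviving surfaces into one dictionary. A surface shared by several
#' pathogens is kept for each of them: the ambiguity is retained here and
#' resolved (deterministically) at match time. Records whose terms all fall
#' to the cascade contribute nothing, with a warning.
#'
#' Only `organism` records contribute dictionary surfaces; toxins and prions
#' are recognized by their own methods ([toxin_regex_bank()], [prion_rule()]).
#'
#' @param records List of [pathogen_record()] objects with unique ids.
#' @return A `pm_dictionary`: entry table (`surface`, `pathogen_id`,
#'   `provenance`) plus the case policy (case-insensitive) and per-pathogen
#'   term counts.
#' @export
build_dictionary <- function(records) {
  stopifnot(length(records) > 0)
  ids <- vapply(records, `[[`, character(1), "pathogen_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate pathogen_id across records: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  pieces <- list()
  for (rec in records) {
    if (rec$category != "organism") next
    kept_surface <- character(); kept_prov <- character()
    for (i in seq_len(nrow(rec$raw_terms))) {
      norm <- normalize_organism_terms(rec$raw_terms$term[i])
      kept_surface <- c(kept_surface, norm)
      kept_prov <- c(kept_prov, rep(rec$raw_terms$provenance[i], length(norm)))
    }
    keep <- !duplicated(tolower(kept_surface))
    if (!any(keep)) {
      warning(sprintf("pathogen %s: no terms survive normalization", rec$pathogen_id),
              call. = FALSE)
      next
    }
    pieces[[rec$pathogen_id]] <- data.frame(
      surface = unname(kept_surface[keep]), pathogen_id = rec$pathogen_id,
      provenance = unname(kept_prov[keep]), stringsAsFactors = FALSE)
  }
  entries <- if (length(pieces)) do.call(rbind, c(pieces, make.row.names = FALSE))
             else data.frame(surface = character(), pathogen_id = character(),
                             provenance = character(), stringsAsFactors = FALSE)
  new_dictionary(entries)
}

new_dictionary <- function(entries) {
  stopifnot(all(c("surface", "pathogen_id", "provenance") %in% names(entries)))
  key <- paste(tolower(entries$surface), entries$pathogen_id)
  if (anyDuplicated(key)) {
    stop("duplicate (surface, pathogen_id) pairs in dictionary", call. = FALSE)
  }
  if (any(nchar(entries$surface) <= 3L)) {
    stop("dictionary entries of 3 characters or fewer are not allowed", call. = FALSE)
  }
  structure(list(entries = entries, case_policy = "insensitive"),
            class = "pm_dictionary")
}

#' @export
print.pm_dictionary <- function(x, ...) {
  cat(sprintf("<pm_dictionary> %d entries, %d pathogens, case-%s matching\n",
              nrow(x$entries), length(unique(x$entries$pathogen_id)), x$case_policy))
  invisible(x)
}

#' Per-pathogen dictionary term counts
#'
#' @param dictionary A `pm_dictionary`.
#' @return Data frame with columns `pathogen_id` and `n_terms`.
#' @export
dictionary_stats <- function(dictionary) {
  stopifnot(inherits(dictionary, "pm_dictionary"))
  tab <- table(dictionary$entries$pathogen_id)
  data.frame(pathogen_id = names(tab), n_terms = as.integer(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write and read a dictionary as TSV
#'
#' One line per entry, `surface TAB pathogen_id TAB provenance`, with a
#' header row. `write_dictionary` also drops a JSON sidecar
#' (`<path>.stats.json`) with entry and per-pathogen counts.
#'
#' @param dictionary A `pm_dictionary`.
#' @param path TSV file path.
#' @return `write_dictionary` returns `path` invisibly; `read_dictionary`
#'   returns a `pm_dictionary`.
#' @export
write_dictionary <- function(dictionary, path) {
  stopifnot(inherits(dictionary, "pm_dictionary"))
  utils::write.table(dictionary$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  stats <- list(n_entries = nrow(dictionary$entries),
                n_pathogens = length(unique(dictionary$entries$pathogen_id)),
                per_pathogen = dictionary_stats(dictionary))
  jsonlite::write_json(stats, paste0(path, ".stats.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  entries <- utils::read.delim(path, stringsAsFactors = FALSE,
                               colClasses = "character", fileEncoding = "UTF-8")
  new_dictionary(entries)
}
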