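# Record-service contract and the deterministic mock backend.
#
# The acquisition methodology needs four capabilities from a record service:
# taxonomy name search (scientific names only, or all name fields), taxonomy
# child listing, literature search by MeSH query string, and gene-record
# links from a taxon to PMIDs. The mock backend implements the contract from
# a directory of TSV tables, fully deterministically, so dataset builds are
# reproducible and testable offline. The contract keeps a live NCBI
# E-utilities backend pluggable.

#' Open a mock record service
#'
#' Reads a directory of TSV tables:
#' \describe{
#'   \item{nodes.tsv}{`taxon_id`, `scientific_name`, `parent_id` (empty for
#'     roots)}
#'   \item{names.tsv}{`taxon_id`, `name`, `name_class`
#'     (`scientific_name`/`synonym`)}
#'   \item{mesh_map.tsv}{`taxon_id`, `descriptor` — taxon-to-MeSH identifier
#'     mapping (absent taxa have no MeSH descriptor)}
#'   \item{mesh_index.tsv}{`descriptor`, `pmid` — the literature index}
#'   \item{gene_links.tsv}{`taxon_id`, `pmid` — gene-record links}
#' }
#' @param dir Directory containing the tables.
#' @return A `pm_mock_service`.
#' @export
mock_record_service <- function(dir) {
  if (!dir.exists(dir)) stop("mock backend directory not found: ", dir, call. = FALSE)
  read_tab <- function(f) {
    utils::read.delim(file.path(dir, f), stringsAsFactors = FALSE,
                      colClasses = "character")
  }
  svc <- structure(list(nodes = read_tab("nodes.tsv"),
                        names = read_tab("names.tsv"),
                        mesh_map = read_tab("mesh_map.tsv"),
                        mesh_index = read_tab("mesh_index.tsv"),
                        gene_links = read_tab("gene_links.tsv"),
                        dir = dir),
                   class = c("pm_mock_service", "pm_record_service"))
  svc
}

#' Record service capabilities
#'
#' Generic interface implemented by backends. `svc_search_taxon` searches
#' taxon names (`scope = "scientific"` restricts to scientific names);
#' `svc_children` lists direct children; `svc_search_literature` evaluates a
#' MeSH query string of `[MH]`-tagged clauses joined by `AND`;
#' `svc_gene_link_pmids` returns PMIDs of gene records linked to a taxon;
#' `svc_mesh_descriptors` returns the MeSH descriptors mapped to a taxon.
#'
#' @param service A record service.
#' @param name,taxon_id,query Capability arguments.
#' @return Character vectors (taxon ids or PMIDs), sorted, deduplicated.
#' @export
svc_search_taxon <- function(service, name, scope = c("scientific", "all")) {
  UseMethod("svc_search_taxon")
}

#' @rdname svc_search_taxon
#' @param scope `"scientific"` or `"all"` name fields.
#' @export
svc_search_taxon.pm_mock_service <- function(service, name, scope = c("scientific", "all")) {
  scope <- match.arg(scope)
  tab <- service$names
  if (scope == "scientific") {
    tab <- tab[tab$name_class == "scientific_name", , drop = FALSE]
  }
  sort(unique(tab$taxon_id[tolower(tab$name) == tolower(name)]))
}

#' @rdname svc_search_taxon
#' @export
svc_children <- function(service, taxon_id) UseMethod("svc_children")

#' @rdname svc_search_taxon
#' @export
svc_children.pm_mock_service <- function(service, taxon_id) {
  sort(unique(service$nodes$taxon_id[service$nodes$parent_id == taxon_id]))
}

#' @rdname svc_search_taxon
#' @export
svc_search_literature <- function(service, query) UseMethod("svc_search_literature")

#' @rdname svc_search_taxon
#' @export
svc_search_literature.pm_mock_service <- function(service, query) {
  clauses <- strsplit(query, "\\s+AND\\s+")[[1]]
  terms <- vapply(clauses, function(cl) {
    m <- regmatches(cl, regexec('^\\s*"?([^"]*?)"?\\s*\\[MH\\]\\s*$', cl))[[1]]
    if (length(m) < 2L || !nzchar(m[2])) {
      stop("unsupported query clause: ", cl, call. = FALSE)
    }
    m[2]
  }, character(1))
  postings <- lapply(terms, function(tm) {
    service$mesh_index$pmid[tolower(service$mesh_index$descriptor) == tolower(tm)]
  })
  sort(unique(Reduce(intersect, postings)))
}

#' @rdname svc_search_taxon
#' @export
svc_gene_link_pmids <- function(service, taxon_id) UseMethod("svc_gene_link_pmids")

#' @rdname svc_search_taxon
#' @export
svc_gene_link_pmids.pm_mock_service <- function(service, taxon_id) {
  sort(unique(service$gene_links$pmid[service$gene_links$taxon_id == taxon_id]))
}

#' @rdname svc_search_taxon
#' @export
svc_mesh_descriptors <- function(service, taxon_id) UseMethod("svc_mesh_descriptors")

#' @rdname svc_search_taxon
#' @export
svc_mesh_descriptors.pm_mock_service <- function(service, taxon_id) {
  sort(unique(service$mesh_map$descriptor[service$mesh_map$taxon_id == taxon_id]))
}

#' Resolve a pathogen name to a taxon
#'
#' Searches scientific names first; on zero hits, widens to all name fields.
#' Exactly one hit resolves; zero hits is `not_found`; several hits is
#' `ambiguous` and the pathogen is skipped — only unambiguous single-record
#' resolutions are trusted.
#'
#' @param name Pathogen name (non-empty).
#' @param service A record service.
#' @return List with `status` (`found`/`not_found`/`ambiguous`), `taxon_id`
#'   (`NA` unless found), and `candidates`.
#' @export
resolve_taxon <- function(name, service) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  hits <- svc_search_taxon(service, name, scope = "scientific")
  if (!length(hits)) hits <- svc_search_taxon(service, name, scope = "all")
  status <- if (length(hits) == 1L) "found"
            else if (!length(hits)) "not_found"
            else "ambiguous"
  list(status = status,
       taxon_id = if (status == "found") hits else NA_character_,
       candidates = hits)
}

#' Expand a taxon to itself plus all subspecies
#'
#' Transitive closure of child links, root included, via breadth-first
#' traversal over recursive child queries.
#'
#' @param taxon_id Root taxon id.
#' @param service A record service.
#' @return Sorted character vector of taxon ids.
#' @export
expand_subspecies <- function(taxon_id, service) {
  seen <- character()
  queue <- taxon_id
  while (length(queue)) {
    id <- queue[[1]]
    queue <- queue[-1]
    if (id %in% seen) stop("cycle detected in taxonomy at ", id, call. = FALSE)
    seen <- c(seen, id)
    queue <- c(queue, svc_children(service, id))
  }
  sort(unique(seen))
}

#' PMIDs indexed under a pathogen's MeSH descriptors
#'
#' Union over the pathogen's descriptors of the MeSH-indexed literature
#' search. A pathogen with no MeSH descriptor returns the empty set and is
#' flagged for the acquisition report.
#'
#' @param pathogen A [pathogen_record()].
#' @param service A record service.
#' @return List with `pmids` (sorted) and `flagged_no_mesh` (logical).
#' @export
pmids_via_mesh <- function(pathogen, service) {
  stopifnot(inherits(pathogen, "pm_pathogen"))
  if (!length(pathogen$mesh_descriptors)) {
    return(list(pmids = character(), flagged_no_mesh = TRUE))
  }
  pmids <- unlist(lapply(pathogen$mesh_descriptors, function(d) {
    svc_search_literature(service, sprintf("%s[MH]", d))
  }))
  list(pmids = sort(unique(pmids)), flagged_no_mesh = FALSE)
}

# species with a MeSH heading usable in the prion template; the other common
# host species (elk, greater kudu, moose, mule, nyala, onyx, ostrich) have no
# heading and are flagged not_found
prion_mesh_headings <- c(
  human = "humans", sheep = "sheep", cattle = "cattle", cat = "cats",
  deer = "deer", goat = "goats", mink = "mink"
)

#' Build the PrPSc prion literature query for a species
#'
#' Substitutes the species MeSH heading into the template
#' `"PrPSc Proteins"[MH] AND <species>[MH]`.
#'
#' @param species_name Host species common name (e.g. `"sheep"`, `"human"`).
#' @return List with `status` (`found`/`not_found`) and `query` (`NA` when
#'   the species has no MeSH heading).
#' @export
prion_query <- function(species_name) {
  key <- tolower(trimws(species_name))
  heading <- if (key %in% names(prion_mesh_headings)) prion_mesh_headings[[key]]
             else if (key %in% prion_mesh_headings) key  # already a heading, e.g. "humans"
             else NA_character_
  if (is.na(heading)) return(list(status = "not_found", query = NA_character_))
  list(status = "found",
       query = sprintf('"PrPSc Proteins"[MH] AND %s[MH]', heading))
}

#' Build the pathogen literature data set
#'
#' Routes each pathogen by category: organisms are resolved against the
#' taxonomy (scientific name first, then all name fields; ambiguous names
#' are skipped), expanded to all subspecies, and linked to literature via
#' MeSH indexing and via gene-record links (kept separate in the report —
#' only MeSH-derived PMIDs feed weak labeling); prions use the species query
#' template; toxins use their MeSH mapping. Failures are recorded per
#' pathogen, never aborting the batch. Every input pathogen is accounted for
#' exactly once, and mock-mode builds are bit-reproducible.
#'
#' @param pathogens Data frame with columns `name`, `category`
#'   (`organism`/`prion`/`toxin`), and optional `taxon_id`, `mesh_id`.
#' @param service A record service.
#' @return List with `report` (one row per pathogen: `name`, `category`,
#'   `status`, `taxon_ids`, `mesh`, `n_pmids_mesh`, `n_pmids_genelink`) and
#'   `pmids` (per pathogen, separate `mesh` and `genelink` PMID sets).
#' @export
build_dataset <- function(pathogens, service) {
  stopifnot(all(c("name", "category") %in% names(pathogens)))
  report <- list()
  pmid_sets <- list()
  for (i in seq_len(nrow(pathogens))) {
    name <- pathogens$name[i]
    category <- pathogens$category[i]
    row <- tryCatch(
      build_one_pathogen(name, category,
                         taxon_id = pathogens$taxon_id[i] %||% NA_character_,
                         mesh_id = pathogens$mesh_id[i] %||% NA_character_,
                         service = service),
      error = function(e) list(
        report = data.frame(name = name, category = category, status = "error",
                            taxon_ids = NA_character_, mesh = NA_character_,
                            n_pmids_mesh = 0L, n_pmids_genelink = 0L,
                            stringsAsFactors = FALSE),
        pmids = list(mesh = character(), genelink = character())))
    report[[i]] <- row$report
    pmid_sets[[name]] <- row$pmids
  }
  list(report = do.call(rbind, c(report, make.row.names = FALSE)),
       pmids = pmid_sets)
}

build_one_pathogen <- function(name, category, taxon_id, mesh_id, service) {
  mesh_pmids <- character(); gene_pmids <- character()
  taxa <- character(); descriptors <- character(); status <- "found"
  if (category == "organism") {
    if (is.na(taxon_id) || !nzchar(taxon_id)) {
      res <- resolve_taxon(name, service)
      status <- res$status
      taxon_id <- res$taxon_id
    }
    if (status == "found") {
      taxa <- expand_subspecies(taxon_id, service)
      descriptors <- sort(unique(unlist(lapply(taxa, svc_mesh_descriptors,
                                               service = service))))
      if (!is.na(mesh_id) && nzchar(mesh_id)) {
        descriptors <- sort(unique(c(descriptors, mesh_id)))
      }
      rec <- pathogen_record(paste0("org-", taxon_id), name, "organism",
                             taxon_ids = taxa, mesh_descriptors = descriptors,
                             raw_terms = name)
      mesh_pmids <- pmids_via_mesh(rec, service)$pmids
      gene_pmids <- sort(unique(unlist(lapply(taxa, svc_gene_link_pmids,
                                              service = service))))
    }
  } else if (category == "prion") {
    pq <- prion_query(name)
    status <- pq$status
    if (status == "found") {
      descriptors <- sub('^"PrPSc Proteins"\\[MH\\] AND (.*)\\[MH\\]$', "\\1", pq$query)
      mesh_pmids <- svc_search_literature(service, pq$query)
    }
  } else if (category == "toxin") {
    descriptor <- if (!is.na(mesh_id) && nzchar(mesh_id)) mesh_id else {
      hit <- unique(service$mesh_index$descriptor[
        tolower(service$mesh_index$descriptor) == tolower(name)])
      if (length(hit)) hit[1] else NA_character_
    }
    if (is.na(descriptor)) {
      status <- "not_found"
    } else {
      descriptors <- descriptor
      mesh_pmids <- svc_search_literature(service, sprintf("%s[MH]", descriptor))
    }
  } else {
    stop("unknown pathogen category: ", category, call. = FALSE)
  }
  list(report = data.frame(
         name = name, category = category, status = status,
         taxon_ids = if (length(taxa)) paste(taxa, collapse = ",") else NA_character_,
         mesh = if (length(descriptors)) paste(descriptors, collapse = ",")
                else NA_character_,
         n_pmids_mesh = length(mesh_pmids),
         n_pmids_genelink = length(gene_pmids),
         stringsAsFactors = FALSE),
       pmids = list(mesh = mesh_pmids, genelink = gene_pmids))
}

#' Write an acquisition report as TSV
#'
#' @param report Report data frame from [build_dataset()].
#' @param path File path.
#' @export
write_acquisition_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", na = "")
  invisible(path)
}
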