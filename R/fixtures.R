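# Deterministic synthetic fixtures: taxonomies, citation corpora with
# planted mentions and MeSH labels, and mock-backend directories.
#
# The generators emulate the shapes of the real inputs — an OBO taxonomy
# with subspecies and synonyms, and MEDLINE-like citations whose MeSH lists
# realize the weak-labeling assumption exactly: a citation carries a
# pathogen's descriptor iff the (citation, pathogen) pair is relevant.
# Relevance is additionally signalled lexically by disjoint experimental vs
# background cue vocabularies, so it is learnable from masked text.

with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic-fixture generators
#'
#' The same configuration always yields byte-identical outputs.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param n_species Number of species-level pathogens.
#' @param subspecies_per_species Subspecies (strains) under each species.
#' @param synonyms_per_node Synonyms attached to every taxonomy node.
#' @param n_citations Corpus size.
#' @param fraction_without_abstract Fraction of citations with title only.
#' @param relevant_fraction Probability that a (citation, pathogen) pair is
#'   relevant (experimentally studied).
#' @param experimental_cues,background_cues Disjoint cue vocabularies placed
#'   in relevant vs irrelevant mention sentences; overlap is a validation
#'   error since it would make relevance unlearnable.
#' @param max_pathogens_per_citation Mentions-per-citation cap; the number of
#'   pathogens planted in a citation is uniform on `1..max`.
#' @return A `pm_generator_config`.
#' @export
generator_config <- function(seed = 1L, n_species = 5L,
                             subspecies_per_species = 2L,
                             synonyms_per_node = 1L,
                             n_citations = 100L,
                             fraction_without_abstract = 0.2,
                             relevant_fraction = 0.5,
                             experimental_cues = c("isolated", "cultured",
                                                   "sequenced", "purified",
                                                   "characterised", "assayed"),
                             background_cues = c("reviewed", "surveyed",
                                                 "discussed", "cited",
                                                 "summarised", "compared"),
                             max_pathogens_per_citation = 2L) {
  stopifnot(n_species >= 1, subspecies_per_species >= 0, synonyms_per_node >= 0,
            n_citations >= 0, max_pathogens_per_citation >= 1)
  for (fr in c(fraction_without_abstract, relevant_fraction)) {
    if (fr < 0 || fr > 1) stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (length(intersect(tolower(experimental_cues), tolower(background_cues)))) {
    stop("experimental and background cue vocabularies overlap", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 subspecies_per_species = as.integer(subspecies_per_species),
                 synonyms_per_node = as.integer(synonyms_per_node),
                 n_citations = as.integer(n_citations),
                 fraction_without_abstract = fraction_without_abstract,
                 relevant_fraction = relevant_fraction,
                 experimental_cues = experimental_cues,
                 background_cues = background_cues,
                 max_pathogens_per_citation = as.integer(max_pathogens_per_citation)),
            class = "pm_generator_config")
}

genus_pool <- c("Borrelia", "Klebsiella", "Yersinia", "Francisella", "Brucella",
                "Listeria", "Vibrionella", "Shigellopsis", "Coxiella",
                "Nocardiella", "Serratiella", "Moraxiella")
epithet_pool <- c("fictum", "simulans", "exemplaris", "synthetica", "ludens",
                  "artificialis", "probandi", "generata", "modelica", "arbitraria")

#' Generate a synthetic taxonomy
#'
#' Writes a valid OBO file with `n_species` root species, each carrying the
#' configured number of subspecies (strain) children and synonyms, loadable
#' by [load_taxonomy()].
#'
#' @param config A [generator_config()].
#' @param path Output OBO path.
#' @return List with `path`, `nodes` (taxon_id, scientific_name, parent_id)
#'   and `names`
#'   (taxon_id, name, name_class) tables, invisibly usable as mock-backend
#'   material.
#' @export
generate_taxonomy <- function(config, path = tempfile(fileext = ".obo")) {
  stopifnot(inherits(config, "pm_generator_config"))
  with_seed(config$seed, {
    nodes <- list(); name_rows <- list()
    lines <- c("format-version: 1.2", "")
    add_node <- function(id, name, parent, synonyms) {
      nodes[[length(nodes) + 1L]] <<- data.frame(
        taxon_id = id, scientific_name = name,
        parent_id = if (is.na(parent)) "" else parent, stringsAsFactors = FALSE)
      name_rows[[length(name_rows) + 1L]] <<- data.frame(
        taxon_id = id, name = c(name, synonyms),
        name_class = c("scientific_name", rep("synonym", length(synonyms))),
        stringsAsFactors = FALSE)
      stanza <- c("[Term]", paste0("id: ", id), paste0("name: ", name))
      for (s in synonyms) stanza <- c(stanza, sprintf('synonym: "%s" RELATED []', s))
      if (!is.na(parent)) stanza <- c(stanza, paste0("is_a: ", parent))
      lines <<- c(lines, stanza, "")
    }
    for (i in seq_len(config$n_species)) {
      genus <- genus_pool[(i - 1L) %% length(genus_pool) + 1L]
      epithet <- sprintf("%s%02d", sample(epithet_pool, 1L), i)
      sp_name <- paste(genus, epithet)
      sp_id <- sprintf("TAX:%04d", i)
      syns <- if (config$synonyms_per_node > 0) {
        sprintf("%s agent %s", sp_name,
                vapply(seq_len(config$synonyms_per_node),
                       function(k) paste0(sample(LETTERS, 1L), k), character(1)))
      } else character()
      add_node(sp_id, sp_name, NA_character_, syns)
      for (j in seq_len(config$subspecies_per_species)) {
        ss_id <- sprintf("%s.%d", sp_id, j)
        ss_name <- sprintf("%s strain %s%d", sp_name, sample(LETTERS, 1L), j)
        ss_syns <- if (config$synonyms_per_node > 0) {
          sprintf("%s isolate %s%d", sp_name,
                  vapply(seq_len(config$synonyms_per_node),
                         function(k) paste0(sample(letters, 1L), k), character(1)), j)
        } else character()
        add_node(ss_id, ss_name, sp_id, ss_syns)
      }
    }
    writeLines(lines, path, useBytes = TRUE)
    list(path = path,
         nodes = do.call(rbind, c(nodes, make.row.names = FALSE)),
         names = do.call(rbind, c(name_rows, make.row.names = FALSE)))
  })
}

#' Pathogen records for a generated taxonomy
#'
#' One organism record per species root, with subtree terms collected from
#' the taxonomy and a synthetic MeSH descriptor `MESH:D<index>` assigned to
#' each pathogen.
#'
#' @param taxonomy A `pm_taxonomy` loaded from [generate_taxonomy()] output.
#' @return List of [pathogen_record()] objects.
#' @export
fixture_records <- function(taxonomy) {
  roots <- Filter(function(n) is.na(n$parent_id), taxonomy$nodes)
  root_ids <- sort(vapply(roots, `[[`, character(1), "taxon_id",
                          USE.NAMES = FALSE))
  lapply(seq_along(root_ids), function(i) {
    organism_record(taxonomy, root_ids[i],
                    mesh_descriptors = sprintf("MESH:D%04d", i))
  })
}

# sentence templates; each returns list(pieces, mention_index) where pieces
# is a character vector and mention_index marks the surface slot
mention_sentence <- function(surface, cue, relevant, lead = FALSE) {
  if (relevant) {
    if (lead) list(pieces = c("Experimental analysis of ", surface,
                              " ", cue, " in the laboratory"),
                   mention_index = 2L)
    else list(pieces = c("We ", cue, " and grew ", surface,
                         " under controlled conditions. "), mention_index = 4L)
  } else {
    if (lead) list(pieces = c("A report in which ", surface, " is ", cue,
                              " as background"), mention_index = 2L)
    else list(pieces = c("Earlier studies ", cue, " ", surface,
                         " without direct experiments. "), mention_index = 4L)
  }
}

assemble_field <- function(sentences, pmid, field) {
  text <- ""
  mention_rows <- list()
  for (s in sentences) {
    offset <- nchar(text)
    pos <- cumsum(c(0L, nchar(s$pieces)))
    if (!is.null(s$mention_index)) {
      i <- s$mention_index
      mention_rows[[length(mention_rows) + 1L]] <- data.frame(
        pmid = pmid, field = field,
        start = offset + pos[i], end = offset + pos[i + 1L],
        surface = s$pieces[i], pathogen_id = s$pathogen_id,
        stringsAsFactors = FALSE)
    }
    text <- paste0(text, paste(s$pieces, collapse = ""))
  }
  list(text = text, mentions = if (length(mention_rows)) {
    do.call(rbind, c(mention_rows, make.row.names = FALSE))
  } else NULL)
}

#' Generate a synthetic citation corpus with gold standard
#'
#' Builds `n_citations` template-based citations. Each citation carries one
#' to `max_pathogens_per_citation` pathogens; every planted surface is a
#' dictionary entry of that pathogen, verbatim, at an exactly recorded
#' offset. A pair is relevant with probability `relevant_fraction`; relevant
#' pairs co-occur with experimental cue words and put the pathogen's MeSH
#' descriptor on the citation, irrelevant pairs use background cues and do
#' not. Citations drawn (at rate `fraction_without_abstract`) to have no
#' abstract plant mentions only in the title.
#'
#' @param config A [generator_config()].
#' @param records Pathogen records, typically [fixture_records()]; their
#'   dictionary (via [build_dictionary()]) supplies the planted surfaces.
#' @return List with `corpus` (a `pm_corpus`), `gold` (a list: `mentions`
#'   with exact offsets, `labels` with one relevance label per planted
#'   (pmid, pathogen) pair), and `records`.
#' @export
generate_corpus <- function(config, records) {
  stopifnot(inherits(config, "pm_generator_config"), length(records) > 0)
  dictionary <- build_dictionary(records)
  if (!nrow(dictionary$entries)) stop("lexicon is empty", call. = FALSE)
  descriptors <- vapply(records, function(r) r$mesh_descriptors[1], character(1))
  names(descriptors) <- vapply(records, `[[`, character(1), "pathogen_id")
  surfaces_by_pid <- split(dictionary$entries$surface, dictionary$entries$pathogen_id)
  pids <- names(surfaces_by_pid)

  with_seed(config$seed + 1L, {
    cits <- list(); gold_mentions <- list(); gold_labels <- list()
    for (ci in seq_len(config$n_citations)) {
      pmid <- as.character(2000000L + ci)
      k <- sample.int(config$max_pathogens_per_citation, 1L)
      k <- min(k, length(pids))
      chosen <- sample(pids, k)
      relevant <- stats::runif(k) < config$relevant_fraction
      has_abstract <- stats::runif(1) >= config$fraction_without_abstract
      if (!has_abstract) { chosen <- chosen[1]; relevant <- relevant[1]; k <- 1L }

      cue_for <- function(rel) {
        if (rel) sample(config$experimental_cues, 1L)
        else sample(config$background_cues, 1L)
      }
      pick_surface <- function(pid) sample(surfaces_by_pid[[pid]], 1L)

      title_s <- mention_sentence(pick_surface(chosen[1]), cue_for(relevant[1]),
                                  relevant[1], lead = TRUE)
      title_s$pathogen_id <- chosen[1]
      title <- assemble_field(list(title_s), pmid, "title")

      abstract <- NULL
      if (has_abstract) {
        sents <- lapply(seq_len(k), function(j) {
          s <- mention_sentence(pick_surface(chosen[j]), cue_for(relevant[j]),
                                relevant[j])
          s$pathogen_id <- chosen[j]
          s
        })
        sents <- c(sents, list(list(
          pieces = c("Further methodological details are described in the full report."),
          mention_index = NULL)))
        abstract <- assemble_field(sents, pmid, "abstract")
      }

      mesh <- data.frame(id = "MESH:D0000", name = "Research",
                         stringsAsFactors = FALSE)
      for (j in seq_len(k)) {
        if (relevant[j]) {
          mesh <- rbind(mesh, data.frame(id = descriptors[[chosen[j]]],
                                         name = paste("Descriptor", chosen[j]),
                                         stringsAsFactors = FALSE))
        }
      }
      cits[[ci]] <- citation(pmid, title$text,
                             abstract = if (has_abstract) abstract$text else NULL,
                             mesh = mesh)
      gold_mentions[[ci]] <- rbind(title$mentions,
                                   if (has_abstract) abstract$mentions)
      gold_labels[[ci]] <- data.frame(
        pmid = pmid, pathogen_id = chosen,
        label = ifelse(relevant, "relevant", "irrelevant"),
        stringsAsFactors = FALSE)
    }
    gm <- do.call(rbind, c(gold_mentions, make.row.names = FALSE))
    gl <- do.call(rbind, c(gold_labels, make.row.names = FALSE))
    list(corpus = corpus(cits, source = "synthetic"),
         gold = list(mentions = gm, labels = gl),
         records = records)
  })
}

#' Generate a mock record-service backend directory
#'
#' Writes the five TSV tables of [mock_record_service()] so that they are
#' mutually consistent with the corpus and gold standard this same
#' configuration generates: the taxonomy tables mirror
#' [generate_taxonomy()], each species maps to its synthetic MeSH
#' descriptor, the literature index posts a pathogen's descriptor exactly on
#' the PMIDs whose gold pair is relevant, and gene links carry a subset of
#' those PMIDs.
#'
#' @param config A [generator_config()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
generate_mock_backend <- function(config, dir) {
  stopifnot(inherits(config, "pm_generator_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tax <- generate_taxonomy(config, file.path(dir, "taxonomy.obo"))
  taxonomy <- load_taxonomy(tax$path)
  records <- fixture_records(taxonomy)
  gen <- generate_corpus(config, records)

  write_tab <- function(df, f) {
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  write_tab(tax$nodes, "nodes.tsv")
  write_tab(tax$names, "names.tsv")
  mesh_map <- do.call(rbind, lapply(records, function(r) {
    data.frame(taxon_id = r$pathogen_id, descriptor = r$mesh_descriptors[1],
               stringsAsFactors = FALSE)
  }))
  write_tab(mesh_map, "mesh_map.tsv")

  labels <- gen$gold$labels
  rel <- labels[labels$label == "relevant", , drop = FALSE]
  descriptors <- vapply(records, function(r) r$mesh_descriptors[1], character(1))
  names(descriptors) <- vapply(records, `[[`, character(1), "pathogen_id")
  mesh_index <- data.frame(descriptor = unname(descriptors[rel$pathogen_id]),
                           pmid = rel$pmid, stringsAsFactors = FALSE)
  mesh_index <- mesh_index[order(mesh_index$descriptor, mesh_index$pmid), ,
                           drop = FALSE]
  write_tab(mesh_index, "mesh_index.tsv")

  # gene links: every other relevant citation, linked from the root taxon
  sel <- rel[as.integer(rel$pmid) %% 2L == 0L, , drop = FALSE]
  gene_links <- data.frame(taxon_id = sel$pathogen_id, pmid = sel$pmid,
                           stringsAsFactors = FALSE)
  gene_links <- gene_links[order(gene_links$taxon_id, gene_links$pmid), ,
                           drop = FALSE]
  write_tab(gene_links, "gene_links.tsv")
  invisible(dir)
}
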