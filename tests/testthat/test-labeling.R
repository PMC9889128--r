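link_fixture <- function() {
  mesh_link(list(
    pathogen_record("P:1", "Alpha", "organism", taxon_ids = "T:1",
                    mesh_descriptors = c("D:A1", "D:A2"), raw_terms = "Alpha agent"),
    pathogen_record("P:2", "Beta", "organism", taxon_ids = "T:2",
                    mesh_descriptors = "D:B1", raw_terms = "Beta agent"),
    pathogen_record("P:3", "NoMesh", "organism", taxon_ids = "T:3",
                    raw_terms = "NoMesh agent")))
}

test_that("labels follow MeSH descriptor intersection exactly", {
  link <- link_fixture()
  rel <- citation("1", "T", mesh = data.frame(id = "D:A2", name = "Alpha heading"))
  irr <- citation("2", "T", mesh = data.frame(id = "D:X", name = "Other"))
  none <- citation("3", "T")
  expect_identical(label_pair(rel, "P:1", link), "relevant")
  expect_identical(label_pair(irr, "P:1", link), "irrelevant")
  expect_identical(label_pair(none, "P:1", link), "irrelevant")
  # descriptor names count as well as ids
  byname <- citation("4", "T", mesh = data.frame(id = "D:ZZ", name = "D:B1"))
  expect_identical(label_pair(byname, "P:2", link), "relevant")
  expect_error(label_pair(rel, "P:99", link), "unknown pathogen")
})

test_that("labels equal the set-intersection oracle on random corpora", {
  link <- link_fixture()
  set.seed(55)
  pool <- c("D:A1", "D:A2", "D:B1", "D:X", "D:Y", "D:Z")
  for (i in 1:50) {
    mesh_ids <- sample(pool, sample(0:4, 1))
    cit <- citation(as.character(i), "T",
                    mesh = data.frame(id = mesh_ids,
                                      name = if (length(mesh_ids)) {
                                        paste0("name-", mesh_ids)
                                      } else character()))
    for (pid in c("P:1", "P:2", "P:3")) {
      want <- if (length(intersect(mesh_ids, link[[pid]]))) "relevant" else "irrelevant"
      expect_identical(label_pair(cit, pid, link), want)
    }
  }
})

test_that("masking substitutes spans and leaves everything else intact", {
  cit <- citation("1", "Alphax infects mice",
                  abstract = "Alphax and Alphax were grown. Betax too.")
  mentions <- data.frame(
    pmid = "1", field = c("title", "abstract", "abstract"),
    start = c(0L, 0L, 11L), end = c(6L, 6L, 17L),
    surface = "Alphax", pathogen_id = "P:1", method = "dictionary",
    ambiguous_ids = NA_character_, stringsAsFactors = FALSE)
  masked <- mask_citation(cit, mentions)
  expect_identical(masked,
    "@PATHOGEN$ infects mice\n@PATHOGEN$ and @PATHOGEN$ were grown. Betax too.")
  # title and abstract joined by one newline; single substitution case
  one <- mask_citation(cit, mentions[1, , drop = FALSE])
  expect_identical(one, "@PATHOGEN$ infects mice\nAlphax and Alphax were grown. Betax too.")
})

test_that("masking is lossless outside mention spans (string-diff oracle)", {
  fx <- local({
    cfg <- generator_config(seed = 17, n_species = 4, n_citations = 30)
    taxonomy <- load_taxonomy(generate_taxonomy(cfg)$path)
    records <- fixture_records(taxonomy)
    list(records = records, m = compile_matcher(build_dictionary(records)),
         gen = generate_corpus(cfg, records))
  })
  men <- annotate_corpus(fx$gen$corpus, matcher = fx$m)
  pairs <- unique(men[, c("pmid", "pathogen_id")])
  for (i in seq_len(nrow(pairs))) {
    cit <- get_citation(fx$gen$corpus, pairs$pmid[i])
    sel <- men[men$pmid == pairs$pmid[i] & men$pathogen_id == pairs$pathogen_id[i], ]
    masked <- mask_citation(cit, sel)
    # oracle: rebuild the expected string by splicing the mask into the
    # original fields at the recorded offsets
    splice <- function(text, rows) {
      if (!nrow(rows)) return(text)
      rows <- rows[order(rows$start), ]
      out <- ""; cur <- 0L
      for (j in seq_len(nrow(rows))) {
        out <- paste0(out, substr(text, cur + 1L, rows$start[j]), "@PATHOGEN$")
        cur <- rows$end[j]
      }
      paste0(out, substring(text, cur + 1L))
    }
    want <- splice(cit$title, sel[sel$field == "title", ])
    if (!is.null(cit$abstract)) {
      want <- paste(want, splice(cit$abstract, sel[sel$field == "abstract", ]),
                    sep = "\n")
    }
    expect_identical(masked, want)
    expect_true(grepl("@PATHOGEN$", masked, fixed = TRUE))
  }
})

test_that("masking rejects overlapping or foreign mentions", {
  cit <- citation("1", "Alphax infects mice")
  overlapping <- data.frame(pmid = "1", field = "title", start = c(0L, 3L),
                            end = c(6L, 9L), surface = c("Alphax", "hax in"),
                            pathogen_id = "P:1", method = "dictionary",
                            ambiguous_ids = NA_character_, stringsAsFactors = FALSE)
  expect_error(mask_citation(cit, overlapping), "overlapping")
  foreign <- overlapping[1, ]; foreign$pmid <- "2"
  expect_error(mask_citation(cit, foreign), "belong")
})

test_that("training-set construction: one example per mentioned pair, ordered", {
  link <- link_fixture()
  corp <- corpus(list(
    citation("12", "Alphax agent and Betax agent compared",
             mesh = data.frame(id = "D:A1", name = "Alpha heading")),
    citation("11", "Alphax agent only")))
  men <- data.frame(
    pmid = c("12", "12", "11"), field = "title",
    start = c(0L, 17L, 0L), end = c(12L, 28L, 12L),
    surface = c("Alphax agent", "Betax agent", "Alphax agent"),
    pathogen_id = c("P:1", "P:2", "P:1"), method = "dictionary",
    ambiguous_ids = NA_character_, stringsAsFactors = FALSE)
  ts <- build_training_set(corp, men, link)
  expect_identical(ts$pmid, c("11", "12", "12"))
  expect_identical(ts$pathogen_id, c("P:1", "P:1", "P:2"))
  expect_identical(ts$label, c("irrelevant", "relevant", "irrelevant"))
  expect_true(all(grepl("@PATHOGEN$", ts$text, fixed = TRUE)))
  # citation 12 has two pathogens: two examples, each masking only its own
  row12a <- ts[ts$pmid == "12" & ts$pathogen_id == "P:1", ]
  expect_identical(row12a$text, "@PATHOGEN$ and Betax agent compared")
  bad <- men; bad$pmid[1] <- "99"
  expect_error(build_training_set(corp, bad, link), "unknown PMIDs")
})

test_that("pathogens without MeSH mapping yield no training examples", {
  link <- link_fixture()
  corp <- corpus(list(citation("1", "NoMesh agent studied")))
  men <- data.frame(pmid = "1", field = "title", start = 0L, end = 12L,
                    surface = "NoMesh agent", pathogen_id = "P:3",
                    method = "dictionary", ambiguous_ids = NA_character_,
                    stringsAsFactors = FALSE)
  ts <- build_training_set(corp, men, link)
  expect_identical(nrow(ts), 0L)
  men$pathogen_id <- "P:unregistered"
  expect_error(build_training_set(corp, men, link), "not in MeSH link")
})

test_that("labels are permutation-invariant and the closure holds on fixtures", {
  cfg <- generator_config(seed = 23, n_species = 4, n_citations = 40)
  taxonomy <- load_taxonomy(generate_taxonomy(cfg)$path)
  records <- fixture_records(taxonomy)
  gen <- generate_corpus(cfg, records)
  m <- compile_matcher(build_dictionary(records))
  men <- annotate_corpus(gen$corpus, matcher = m)
  link <- mesh_link(records)
  ts <- build_training_set(gen$corpus, men, link)
  gold <- gen$gold$labels[order(gen$gold$labels$pmid, gen$gold$labels$pathogen_id), ]
  expect_identical(ts$label, gold$label)
  # permuting corpus order never changes any label
  perm <- corpus(rev(gen$corpus$citations))
  ts2 <- build_training_set(perm, men, link)
  expect_identical(ts2, ts)
})

test_that("examples and link tables round-trip through their file formats", {
  link <- link_fixture()
  tf <- tempfile(fileext = ".tsv")
  write_mesh_link(link, tf)
  back <- read_mesh_link(tf)
  expect_identical(back[["P:1"]], c("D:A1", "D:A2"))
  expect_identical(back[["P:3"]], character())
  ex <- data.frame(pmid = "1", pathogen_id = "P:1",
                   text = "@PATHOGEN$ was studied", label = "relevant",
                   stringsAsFactors = FALSE)
  tf2 <- tempfile(fileext = ".jsonl")
  write_examples(ex, tf2)
  expect_identical(read_examples(tf2), ex)
})
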