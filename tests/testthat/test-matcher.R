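toy_dictionary <- function(surfaces, ids = sprintf("P:%d", seq_along(surfaces)),
                           provenance = "synonym") {
  pathomine:::new_dictionary(data.frame(surface = surfaces, pathogen_id = ids,
                                        provenance = rep(provenance,
                                                         length(surfaces)),
                                        stringsAsFactors = FALSE))
}

test_that("longest match prefers the subspecies term", {
  d <- toy_dictionary(c("Borrelia burgdorferi", "Borrelia burgdorferi strain N40"),
                      ids = c("P:1", "P:1"))
  m <- compile_matcher(d)
  hits <- find_dictionary_mentions(m, "Borrelia burgdorferi strain N40 was cultured")
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$surface, "Borrelia burgdorferi strain N40")
  expect_identical(hits$start, 0L)
  expect_identical(hits$end, 31L)
})

test_that("matching respects token boundaries and empty input", {
  d <- toy_dictionary("tick agent")
  m <- compile_matcher(d)
  expect_identical(nrow(find_dictionary_mentions(m, "")), 0L)
  expect_identical(nrow(find_dictionary_mentions(m, "antick agents differ")), 0L)
  hits <- find_dictionary_mentions(m, "The tick agent, reportedly.")
  expect_identical(hits$surface, "tick agent")
  expect_error(compile_matcher(toy_dictionary(character(), ids = character())),
               "empty")
})

test_that("matching is case-insensitive and offsets slice back to the surface", {
  d <- toy_dictionary("Yersinia pestis")
  m <- compile_matcher(d)
  text <- "Cultured YERSINIA PESTIS overnight"
  hits <- find_dictionary_mentions(m, text)
  expect_identical(hits$surface, "YERSINIA PESTIS")
  expect_identical(substr(text, hits$start + 1L, hits$end), hits$surface)
})

test_that("equal-length ambiguity resolves to the lowest pathogen id and is recorded", {
  d <- toy_dictionary(c("dual agent", "dual agent"), ids = c("P:9", "P:2"))
  m <- compile_matcher(d)
  hits <- find_dictionary_mentions(m, "the dual agent spread")
  expect_identical(hits$pathogen_id, "P:2")
  expect_identical(hits$ambiguous_ids, "P:2,P:9")
})

test_that("membership of a large random dictionary matches a hash-set oracle", {
  set.seed(21)
  words <- unique(replicate(12000, paste0(
    paste(sample(letters, sample(4:9, 1), replace = TRUE), collapse = ""))))
  surfaces <- head(words, 10000)
  d <- toy_dictionary(surfaces, ids = sprintf("P:%05d", seq_along(surfaces)))
  m <- compile_matcher(d)
  probe <- c(sample(surfaces, 200), setdiff(words, surfaces)[1:50])
  in_dict <- probe %in% surfaces  # the hash-set oracle
  found <- vapply(probe, function(s) {
    # affixes are 3 characters, shorter than any dictionary word
    nrow(find_dictionary_mentions(m, paste("qq0", s, "0qq"))) == 1L
  }, logical(1), USE.NAMES = FALSE)
  expect_identical(found, in_dict)
})

test_that("scan equals the brute-force every-surface-every-position oracle", {
  for (seed in c(101L, 202L, 303L)) {
    fx <- local({
      cfg <- generator_config(seed = seed, n_species = 4, n_citations = 15)
      taxonomy <- load_taxonomy(generate_taxonomy(cfg)$path)
      records <- fixture_records(taxonomy)
      list(dict = build_dictionary(records),
           gen = generate_corpus(cfg, records))
    })
    m <- compile_matcher(fx$dict)
    for (cit in fx$gen$corpus$citations) {
      for (text in Filter(Negate(is.null), list(cit$title, cit$abstract))) {
        got <- find_dictionary_mentions(m, text)
        want <- oracle_scan(fx$dict$entries, text)
        expect_identical(got[, c("start", "end", "surface", "pathogen_id")],
                         want)
      }
    }
  }
})

test_that("adding a longer extension entry never increases the mention count", {
  base <- toy_dictionary("Borrelia burgdorferi", ids = "P:1")
  ext <- toy_dictionary(c("Borrelia burgdorferi", "Borrelia burgdorferi strain N40"),
                        ids = c("P:1", "P:1"))
  text <- "Borrelia burgdorferi strain N40 and Borrelia burgdorferi were compared"
  n_base <- nrow(find_dictionary_mentions(compile_matcher(base), text))
  n_ext <- nrow(find_dictionary_mentions(compile_matcher(ext), text))
  expect_lte(n_ext, n_base)
})

test_that("toxin regexes catch embedded and case-variant forms", {
  bank <- toxin_regex_bank()
  hits <- find_toxin_mentions(bank, "Injection of onabotulinumtoxinA improved outcomes")
  expect_identical(hits$pathogen_id, "toxin-botulinum")
  expect_identical(hits$surface, "onabotulinumtoxinA")
  hits <- find_toxin_mentions(bank, "the antiaflatoxinB1 antibody titre")
  expect_identical(hits$pathogen_id, "toxin-aflatoxin")
  expect_identical(hits$surface, "antiaflatoxinB1")
  hits <- find_toxin_mentions(bank, "SAXITOXIN levels rose")
  expect_identical(hits$pathogen_id, "toxin-saxitoxin")
  expect_identical(nrow(find_toxin_mentions(bank, "no such agent here")), 0L)
  expect_error(toxin_regex_bank(data.frame(pattern = "botulinum",
                                           pathogen_id = "toxin-botulinum")),
               "\\(\\?i\\)")
  expect_error(toxin_regex_bank(data.frame(pattern = "(?i)[unclosed",
                                           pathogen_id = "toxin-x")),
               "compile")
})

test_that("prion mentions require prion-term and species co-occurrence", {
  rule <- prion_rule()
  cit <- citation("1", "PrPSc accumulation in sheep brain")
  hits <- find_prion_mentions(rule, cit)
  expect_identical(hits$pathogen_id, "prpsc-sheep")
  expect_identical(hits$surface, "sheep")
  # species without a prion term: nothing
  expect_identical(nrow(find_prion_mentions(rule, citation("2", "sheep grazing behaviour"))), 0L)
  # prion term in the abstract licenses a species hit in the title
  cit3 <- citation("3", "Transmission in deer", abstract = "We studied prion strains.")
  hits3 <- find_prion_mentions(rule, cit3)
  expect_identical(hits3$pathogen_id[hits3$field == "title"], "prpsc-deer")
})

test_that("prion detection equals the boolean co-occurrence oracle on random corpora", {
  rule <- prion_rule()
  set.seed(77)
  species_words <- c("sheep", "cattle", "mink", "goats")
  fillers <- c("samples", "analysis", "clinical", "results", "misfolded")
  for (i in 1:40) {
    words <- sample(c(species_words, fillers, "PrPSc", "prion"), 8, replace = TRUE)
    title <- paste(words[1:4], collapse = " ")
    abstract <- paste(words[5:8], collapse = " ")
    cit <- citation(as.character(i), title, abstract = abstract)
    hits <- find_prion_mentions(rule, cit)
    has_prion <- any(c("PrPSc", "prion") %in% words)
    for (sp in c("sheep", "cattle", "mink")) {
      want <- has_prion && sp %in% words
      expect_identical(paste0("prpsc-", sp) %in% hits$pathogen_id, want)
    }
  }
})

test_that("citation annotation unions the recognizers and respects missing abstracts", {
  d <- toy_dictionary("Clostridium botulinum", ids = "T:CB")
  m <- compile_matcher(d)
  bank <- toxin_regex_bank()
  cit <- citation("10", "Clostridium botulinum in soil",
                  abstract = "Purified botulinum toxin was assayed.")
  men <- annotate_citation(cit, matcher = m, bank = bank)
  expect_setequal(men$method, c("dictionary", "regex"))
  expect_identical(men$field, c("title", "abstract"))
  # no abstract: only the title is scanned
  cit2 <- citation("11", "Clostridium botulinum in soil")
  men2 <- annotate_citation(cit2, matcher = m, bank = bank)
  expect_identical(unique(men2$field), "title")
})

test_that("cross-method overlaps keep the longer span, dictionary on ties", {
  d <- toy_dictionary("botulinum toxin serotype A", ids = "T:CB")
  m <- compile_matcher(d)
  bank <- toxin_regex_bank()
  cit <- citation("12", "Effects of botulinum toxin serotype A injections")
  men <- annotate_citation(cit, matcher = m, bank = bank)
  expect_identical(nrow(men), 1L)
  expect_identical(men$method, "dictionary")
  expect_identical(men$surface, "botulinum toxin serotype A")
  # tie in length: dictionary wins
  d2 <- toy_dictionary("botulinum toxin", ids = "T:CB")
  men2 <- annotate_citation(citation("13", "botulinum toxin assays"),
                            matcher = compile_matcher(d2), bank = bank)
  expect_identical(men2$method, "dictionary")
})

test_that("recognizer output is invariant to text case", {
  fx <- local({
    cfg <- generator_config(seed = 5, n_species = 3, n_citations = 10)
    taxonomy <- load_taxonomy(generate_taxonomy(cfg)$path)
    records <- fixture_records(taxonomy)
    list(m = compile_matcher(build_dictionary(records)),
         gen = generate_corpus(cfg, records))
  })
  for (cit in fx$gen$corpus$citations) {
    a <- find_dictionary_mentions(fx$m, cit$title)
    b <- find_dictionary_mentions(fx$m, toupper(cit$title))
    expect_identical(a[, c("start", "end", "pathogen_id")],
                     b[, c("start", "end", "pathogen_id")])
  }
})

test_that("mentions round-trip through JSON Lines", {
  d <- toy_dictionary("Yersinia pestis")
  cit <- citation("7", "Yersinia pestis genomics",
                  abstract = "Yersinia pestis was sequenced.")
  men <- annotate_citation(cit, matcher = compile_matcher(d))
  tf <- tempfile(fileext = ".jsonl")
  write_mentions(men, tf)
  back <- read_mentions(tf)
  expect_identical(back, men)
})
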