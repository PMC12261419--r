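make_three_taxa <- function(counts = c(7L, 5L, 2L)) {
  list(
    list(name = "Halanaerobium", rank = "genus", proteome_count = counts[1],
         seqs = c(c1 = "MKVLWAAL", c2 = "GGHHEELL"),
         annotations = tibble::tibble(
           cluster_id = c("c1", "c2"),
           protein_members = c("p1,p2", "p3"),
           annotation_labels = c("mcrA", ""))),
    list(name = "Clostridia", rank = "class", proteome_count = counts[2],
         seqs = c(k1 = "MSTNPKPQ"), annotations = NULL),
    list(name = "Rarebug", rank = "genus", proteome_count = counts[3],
         seqs = c(r1 = "MAAAAAAA"), annotations = NULL))
}

test_that("archive creation applies the proteome-count inclusion threshold", {
  dir <- withr::local_tempdir()
  input <- write_db_input(file.path(dir, "in"), make_three_taxa())
  archive <- file.path(dir, "db.zip")
  expect_message(idx <- build_taxon_db(input, archive, min_proteomes = 5),
                 "Rarebug")
  expect_equal(nrow(idx), 2)
  expect_setequal(idx$taxon_name, c("Halanaerobium", "Clostridia"))
  excluded <- attr(idx, "excluded")
  expect_equal(excluded$taxon_name, "Rarebug")
  expect_true(all(read_db_index(archive)$proteome_count >= 5))
})

test_that("raising the inclusion threshold never adds taxa", {
  dir <- withr::local_tempdir()
  input <- write_db_input(file.path(dir, "in"), make_three_taxa(c(9L, 5L, 3L)))
  sizes <- sapply(c(1, 4, 6, 10), function(m) {
    a <- file.path(dir, sprintf("db%d.zip", m))
    suppressWarnings(suppressMessages(
      nrow(build_taxon_db(input, a, min_proteomes = m))))
  })
  expect_true(all(diff(sizes) <= 0))
})

test_that("degenerate database inputs error", {
  dir <- withr::local_tempdir()
  empty <- file.path(dir, "empty")
  dir.create(empty)
  expect_error(build_taxon_db(empty, file.path(dir, "a.zip")), "no taxa")

  # annotation naming a cluster id absent from the FASTA
  taxa <- make_three_taxa()
  taxa[[1]]$annotations$cluster_id[2] <- "ghost"
  input <- write_db_input(file.path(dir, "bad"), taxa[1])
  expect_error(
    build_taxon_db(input, file.path(dir, "b.zip"), min_proteomes = 1),
    "Halanaerobium.*ghost")
})

test_that("archive round trip preserves sequences, members and annotations", {
  dir <- withr::local_tempdir()
  input <- write_db_input(file.path(dir, "in"), make_three_taxa())
  archive <- file.path(dir, "db.zip")
  suppressMessages(build_taxon_db(input, archive))

  rec <- read_taxon_record(archive, "Halanaerobium")
  expect_equal(rec$cluster_id, c("c1", "c2"))
  expect_equal(rec$consensus_sequence, c("MKVLWAAL", "GGHHEELL"))
  expect_equal(rec$protein_members[[1]], c("p1", "p2"))
  expect_equal(rec$annotation_labels[[1]], "mcrA")
  expect_equal(rec$annotation_labels[[2]], character(0))
  expect_equal(attr(rec, "rank"), "genus")
})

test_that("record loading reports missing members and tolerates stray annotations", {
  dir <- withr::local_tempdir()
  input <- write_db_input(file.path(dir, "in"), make_three_taxa())
  archive <- file.path(dir, "db.zip")
  suppressMessages(build_taxon_db(input, archive))
  expect_error(read_taxon_record(archive, "NotInDb"), "not in archive")

  # hand-rolled archive (as built elsewhere) with a stray annotation row
  stage <- file.path(dir, "stage")
  dir.create(file.path(stage, "proteomes"), recursive = TRUE)
  dir.create(file.path(stage, "annotations"), recursive = TRUE)
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(c(a = "MKVL", b = "GGHH", c = "WYFP",
                              d = "ASDE")),
    file.path(stage, "proteomes", "Fourbug.faa"))
  readr::write_tsv(tibble::tibble(
    cluster_id = c("a", "b", "c", "d", "zz"),
    protein_members = c("p1", "p2", "p3", "p4", "p5"),
    annotation_labels = c("x", "", "y", "", "")),
    file.path(stage, "annotations", "Fourbug.tsv"), progress = FALSE)
  readr::write_tsv(tibble::tibble(
    taxon_name = "Fourbug", rank = "genus", proteome_count = 6L,
    proteome_path = "proteomes/Fourbug.faa",
    annotation_path = "annotations/Fourbug.tsv"),
    file.path(stage, "index.tsv"), progress = FALSE)
  archive4 <- file.path(dir, "db4.zip")
  zip::zip(archive4, files = c("index.tsv", "proteomes/Fourbug.faa",
                               "annotations/Fourbug.tsv"),
           root = stage, mode = "mirror")
  expect_warning(rec <- read_taxon_record(archive4, "Fourbug"), "zz")
  expect_equal(sum(!is.na(rec$consensus_sequence)), 4)
  expect_equal(rec$annotation_labels[[match("a", rec$cluster_id)]], "x")

  # archive whose index names a member that is absent
  idx <- readr::read_tsv(file.path(stage, "index.tsv"),
                         show_col_types = FALSE)
  idx$proteome_path <- "proteomes/Missing.faa"
  readr::write_tsv(idx, file.path(stage, "index.tsv"), progress = FALSE)
  archive5 <- file.path(dir, "db5.zip")
  zip::zip(archive5, files = c("index.tsv", "annotations/Fourbug.tsv"),
           root = stage, mode = "mirror")
  expect_error(read_taxon_record(archive5, "Fourbug"), "Missing.faa")

  # empty annotation table: clusters come back with empty label lists
  readr::write_tsv(tibble::tibble(cluster_id = character(0),
                                  protein_members = character(0),
                                  annotation_labels = character(0)),
                   file.path(stage, "annotations", "Fourbug.tsv"),
                   progress = FALSE)
  idx$proteome_path <- "proteomes/Fourbug.faa"
  readr::write_tsv(idx, file.path(stage, "index.tsv"), progress = FALSE)
  archive6 <- file.path(dir, "db6.zip")
  zip::zip(archive6, files = c("index.tsv", "proteomes/Fourbug.faa",
                               "annotations/Fourbug.tsv"),
           root = stage, mode = "mirror")
  rec6 <- read_taxon_record(archive6, "Fourbug")
  expect_equal(nrow(rec6), 4)
  expect_true(all(lengths(rec6$annotation_labels) == 0))
})

test_that("resolution walks the lineage most-specific-first", {
  index <- tibble::tibble(
    taxon_name = c("Halanaerobium", "Halanaerobiaceae", "Clostridia"),
    rank = c("genus", "family", "class"),
    proteome_count = c(7L, 12L, 40L),
    proteome_path = "", annotation_path = "")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_affiliation_file(tf, c(
    "obs1\tBacteria;Bacillota;Clostridia;Halanaerobiales;Halanaerobiaceae;Halanaerobium;Halanaerobium congolense",
    "obs2\tBacteria;Bacillota;Clostridia;Halanaerobiales;Halanaerobiaceae",
    "obs3\tBacteria;Pseudomonadota;Gammaproteobacteria"))
  aff <- read_affiliations(tf)
  res <- resolve_affiliations(aff, index)

  expect_equal(res$matched_rank[res$observation_id == "obs1"], "genus")
  expect_equal(res$matched_taxon[res$observation_id == "obs1"],
               "Halanaerobium")
  expect_equal(res$matched_rank[res$observation_id == "obs2"], "family")
  expect_equal(res$status[res$observation_id == "obs3"], "unresolved")
  expect_true(is.na(res$matched_taxon[res$observation_id == "obs3"]))
})

test_that("species match wins before the genus is consulted", {
  index <- tibble::tibble(
    taxon_name = c("Halanaerobium congolense", "Halanaerobium"),
    rank = c("species", "genus"),
    proteome_count = c(6L, 7L), proteome_path = "", annotation_path = "")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_affiliation_file(tf, "obs1\tBacteria;Bacillota;Clostridia;Halanaerobiales;Halanaerobiaceae;Halanaerobium;Halanaerobium congolense")
  res <- resolve_affiliations(read_affiliations(tf), index)
  expect_equal(res$matched_rank, "species")
})

test_that("resolution matches a brute-force scan and ignores index order", {
  set.seed(11)
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
             "species")
  for (case in 1:25) {
    depth <- sample(3:7, 1)
    names_in_lineage <- sprintf("taxon_%d_%d", case, seq_len(depth))
    tf <- withr::local_tempfile(fileext = ".tsv")
    write_affiliation_file(tf, sprintf(
      "obs\t%s", paste(names_in_lineage, collapse = ";")))
    aff <- read_affiliations(tf)
    # random index: some lineage names at the right rank, some decoys
    in_index <- sample(c(TRUE, FALSE), depth, replace = TRUE)
    index <- tibble::tibble(
      taxon_name = c(names_in_lineage[in_index],
                     sprintf("decoy_%d", 1:3)),
      rank = c(ranks[seq_len(depth)][in_index],
               sample(ranks, 3, replace = TRUE)),
      proteome_count = 9L, proteome_path = "", annotation_path = "")
    index <- index[sample(nrow(index)), ]
    res <- resolve_affiliations(aff, index)

    # brute force: most specific lineage element present at its rank
    expected <- rev(which(in_index))[1]
    if (is.na(expected)) {
      expect_equal(res$status, "unresolved")
    } else {
      expect_equal(res$matched_taxon, names_in_lineage[expected])
      expect_equal(res$matched_rank, ranks[expected])
    }
    # order independence
    res2 <- resolve_affiliations(aff, index[order(index$taxon_name), ])
    expect_equal(res2$matched_taxon, res$matched_taxon)
  }
})

test_that("database summaries aggregate per rank with grand totals", {
  dir <- withr::local_tempdir()
  taxa <- list(
    list(name = "Sp one", rank = "species", proteome_count = 6L,
         seqs = c(s1 = "MKVL"), annotations = NULL),
    list(name = "Sp two", rank = "species", proteome_count = 8L,
         seqs = c(s2 = "MKVD"), annotations = NULL),
    list(name = "Gen one", rank = "genus", proteome_count = 11L,
         seqs = c(g1 = "MKVE"), annotations = NULL))
  input <- write_db_input(file.path(dir, "in"), taxa)
  archive <- file.path(dir, "db.zip")
  suppressMessages(build_taxon_db(input, archive))
  sm <- summarize_db(archive)
  expect_equal(sm$included_taxa[sm$rank == "species"], 2L)
  expect_equal(sm$included_taxa[sm$rank == "genus"], 1L)
  expect_equal(db_grand_totals(sm)$included_taxa_total, 3L)
  expect_equal(db_grand_totals(sm)$proteomes_total, 25L)

  empty <- summarize_db(tibble::tibble(rank = character(0),
                                       proteome_count = integer(0)))
  expect_equal(nrow(empty), 0)
  expect_equal(db_grand_totals(empty)$included_taxa_total, 0L)
})
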