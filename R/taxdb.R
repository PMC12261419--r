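#' Build a precomputed consensus-proteome archive
#'
#' Compiles per-taxon consensus proteomes and cluster annotations into a
#' single zip archive with a root-level index, keeping only taxa backed
#' by at least `min_proteomes` source proteomes.  This is the archive
#' format consumed by [resolve_affiliations()] and [read_taxon_record()].
#'
#' The input directory holds one subdirectory per taxon, each containing:
#' \describe{
#'   \item{`taxon.tsv`}{columns `taxon_name`, `rank`, `proteome_count`.}
#'   \item{`proteome.faa`}{consensus sequences, FASTA, header = cluster id.}
#'   \item{`annotations.tsv`}{columns `cluster_id`, `protein_members`
#'     (comma-separated), `annotation_labels` (comma-separated, may be
#'     empty).}
#' }
#'
#' @param input_dir Directory of per-taxon subdirectories (see Details).
#' @param archive Path of the zip archive to create.
#' @param min_proteomes Minimum number of source proteomes a taxon needs
#'   to be included (default 5).
#' @return Invisibly, the index tibble of included taxa, with the
#'   excluded taxa in attribute `"excluded"`.
#' @export
build_taxon_db <- function(input_dir, archive, min_proteomes = 5) {
  taxon_dirs <- list.dirs(input_dir, full.names = TRUE, recursive = FALSE)
  taxon_dirs <- sort(taxon_dirs)
  if (length(taxon_dirs) == 0) {
    abort("no taxa found in input directory")
  }

  meta <- bind_rows(map(taxon_dirs, function(d) {
    mf <- file.path(d, "taxon.tsv")
    if (!file.exists(mf)) {
      abort(sprintf("missing taxon.tsv in %s", d))
    }
    m <- read_tsv_quiet(mf)
    tibble(dir = d,
           taxon_name = as.character(m$taxon_name[1]),
           rank = normalize_rank(m$rank[1]),
           proteome_count = as.integer(m$proteome_count[1]))
  }))
  dup <- meta$taxon_name[duplicated(paste(meta$taxon_name, meta$rank))]
  if (length(dup) > 0) {
    abort(sprintf("duplicate taxon in input: %s", dup[1]))
  }

  included <- meta[meta$proteome_count >= min_proteomes, , drop = FALSE]
  excluded <- meta[meta$proteome_count < min_proteomes, , drop = FALSE]
  if (nrow(excluded) > 0) {
    walk(seq_len(nrow(excluded)), function(i) {
      message(sprintf(
        "excluding taxon %s (rank %s): %d proteomes < threshold %d",
        excluded$taxon_name[i], excluded$rank[i],
        excluded$proteome_count[i], min_proteomes))
    })
  }
  if (nrow(included) == 0) {
    warn(sprintf("no taxa with proteome_count >= %d; archive will be empty",
                 min_proteomes))
  }

  # Validate cluster-id agreement between FASTA and annotation table.
  walk(seq_len(nrow(included)), function(i) {
    d <- included$dir[i]
    seqs <- Biostrings::readAAStringSet(file.path(d, "proteome.faa"))
    ann <- read_tsv_quiet(file.path(d, "annotations.tsv"),
                          col_types = readr::cols(.default = "c"))
    unknown <- setdiff(ann$cluster_id, names(seqs))
    if (length(unknown) > 0) {
      abort(sprintf(
        "taxon %s: annotation references unknown cluster id %s",
        included$taxon_name[i], unknown[1]))
    }
  })

  stage <- tempfile("taxdb_stage")
  dir.create(file.path(stage, "proteomes"), recursive = TRUE)
  dir.create(file.path(stage, "annotations"), recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)

  tok <- unique_tokens(paste0(included$taxon_name, "_", included$rank))
  index <- tibble(
    taxon_name = included$taxon_name,
    rank = included$rank,
    proteome_count = included$proteome_count,
    proteome_path = file.path("proteomes", paste0(tok, ".faa")),
    annotation_path = file.path("annotations", paste0(tok, ".tsv")))
  walk(seq_len(nrow(included)), function(i) {
    file.copy(file.path(included$dir[i], "proteome.faa"),
              file.path(stage, index$proteome_path[i]))
    file.copy(file.path(included$dir[i], "annotations.tsv"),
              file.path(stage, index$annotation_path[i]))
  })
  write_tsv_file(index, file.path(stage, "index.tsv"))

  # pin member timestamps so identical inputs give byte-identical archives
  staged <- list.files(stage, recursive = TRUE, full.names = TRUE,
                       include.dirs = TRUE)
  walk(c(stage, staged), Sys.setFileTime,
       time = as.POSIXct("2020-01-01 00:00:00", tz = "UTC"))

  archive <- normalizePath(archive, mustWork = FALSE)
  if (file.exists(archive)) unlink(archive)
  zip::zip(archive,
           files = c("index.tsv", index$proteome_path, index$annotation_path),
           root = stage, mode = "mirror")
  attr(index, "excluded") <- as_tibble(excluded[, c("taxon_name", "rank",
                                                    "proteome_count")])
  attr(index, "archive") <- archive
  invisible(index)
}

#' Read the index of a consensus-proteome archive
#'
#' @param archive Path to an archive built by [build_taxon_db()].
#' @return A tibble with columns `taxon_name`, `rank`, `proteome_count`,
#'   `proteome_path`, `annotation_path`.
#' @export
read_db_index <- function(archive) {
  if (!file.exists(archive)) {
    abort(sprintf("archive not found: %s", archive))
  }
  tmp <- tempfile("taxdb_index")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  utils::unzip(archive, files = "index.tsv", exdir = tmp)
  idx <- read_tsv_quiet(file.path(tmp, "index.tsv"),
                        col_types = readr::cols(
                          taxon_name = "c", rank = "c",
                          proteome_count = "i",
                          proteome_path = "c", annotation_path = "c"))
  idx$rank <- normalize_rank(idx$rank)
  idx
}

#' Load one taxon's consensus proteome and annotations from an archive
#'
#' Extracts the taxon's FASTA and annotation members and joins them on
#' cluster id.  Every FASTA record is returned; annotation rows naming a
#' cluster id absent from the FASTA raise a warning and are kept with a
#' missing consensus sequence.
#'
#' @param archive Archive path.
#' @param taxon_name Taxon to load (must be in the archive index).
#' @param rank Optional rank to disambiguate homonyms at different ranks.
#' @return A tibble of protein clusters: `cluster_id`,
#'   `consensus_sequence`, `protein_members` (list of character),
#'   `annotation_labels` (list of character), plus `taxon_name`, `rank`,
#'   `proteome_count` attributes.
#' @export
read_taxon_record <- function(archive, taxon_name, rank = NULL) {
  idx <- read_db_index(archive)
  hit <- idx[idx$taxon_name == taxon_name, , drop = FALSE]
  if (!is.null(rank)) {
    hit <- hit[hit$rank == normalize_rank(rank), , drop = FALSE]
  }
  if (nrow(hit) == 0) {
    abort(sprintf("taxon not in archive index: %s", taxon_name))
  }
  hit <- hit[1, ]

  tmp <- tempfile("taxdb_rec")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  members <- c(hit$proteome_path, hit$annotation_path)
  listed <- utils::unzip(archive, list = TRUE)$Name
  missing <- setdiff(members, listed)
  if (length(missing) > 0) {
    abort(sprintf("archive member missing: %s", missing[1]))
  }
  utils::unzip(archive, files = members, exdir = tmp)

  seqs <- Biostrings::readAAStringSet(file.path(tmp, hit$proteome_path))
  ann <- read_tsv_quiet(file.path(tmp, hit$annotation_path),
                        col_types = readr::cols(.default = "c"))
  split_field <- function(x) {
    map(x, function(v) {
      if (is.na(v) || !nzchar(trimws(v))) character(0)
      else trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    })
  }
  rec <- tibble(cluster_id = names(seqs),
                consensus_sequence = unname(as.character(seqs)))
  if (nrow(ann) > 0) {
    unknown <- setdiff(ann$cluster_id, rec$cluster_id)
    if (length(unknown) > 0) {
      warn(sprintf(
        "taxon %s: %d annotation row(s) with unknown cluster id (e.g. %s)",
        taxon_name, length(unknown), unknown[1]))
    }
    ann_t <- tibble(cluster_id = ann$cluster_id,
                    protein_members = split_field(ann$protein_members),
                    annotation_labels = split_field(ann$annotation_labels))
    rec <- dplyr::full_join(rec, ann_t, by = "cluster_id")
  } else {
    rec$protein_members <- rep(list(character(0)), nrow(rec))
    rec$annotation_labels <- rep(list(character(0)), nrow(rec))
  }
  rec$protein_members <- map(rec$protein_members, ~ .x %||% character(0))
  rec$annotation_labels <- map(rec$annotation_labels, ~ .x %||% character(0))
  attr(rec, "taxon_name") <- hit$taxon_name
  attr(rec, "rank") <- hit$rank
  attr(rec, "proteome_count") <- hit$proteome_count
  rec
}

#' Resolve affiliations against an archive index with rank fallback
#'
#' Walks each observation's lineage from its most specific element to
#' its broadest and reports the first (name, rank) pair present in the
#' index; observations whose lineage shares no pair with the index are
#' returned as unresolved.  Matching is exact after whitespace trimming
#' and case-sensitive; homonyms at different ranks are distinguished by
#' the (name, rank) pair.
#'
#' @param affiliations Long affiliation tibble from [read_affiliations()].
#' @param index Archive index tibble from [read_db_index()], or an
#'   archive path.
#' @return A tibble with one row per observation: `observation_id`,
#'   `status` (`"resolved"` or `"unresolved"`), `matched_taxon`,
#'   `matched_rank`, `proteome_count` (NA when unresolved).
#' @export
resolve_affiliations <- function(affiliations, index) {
  if (is.character(index) && length(index) == 1) {
    index <- read_db_index(index)
  }
  key <- paste(index$taxon_name, index$rank, sep = "\r")
  obs <- unique(affiliations$observation_id)
  rows <- map(obs, function(id) {
    lin <- affiliations[affiliations$observation_id == id, , drop = FALSE]
    lin <- lin[order(lin$level, decreasing = TRUE), , drop = FALSE]
    pos <- match(paste(lin$name, lin$rank, sep = "\r"), key)
    hit <- which(!is.na(pos))
    if (length(hit) == 0) {
      tibble(observation_id = id, status = "unresolved",
             matched_taxon = NA_character_, matched_rank = NA_character_,
             proteome_count = NA_integer_)
    } else {
      j <- pos[hit[1]]
      tibble(observation_id = id, status = "resolved",
             matched_taxon = index$taxon_name[j],
             matched_rank = index$rank[j],
             proteome_count = index$proteome_count[j])
    }
  })
  bind_rows(rows)
}

#' Summarize an archive's contents by taxonomic rank
#'
#' @param archive Archive path or an index tibble.
#' @return A tibble with one row per rank present in the archive, ordered
#'   from species to phylum: `rank`, `included_taxa`, `proteomes`.
#' @seealso [db_grand_totals()]
#' @export
summarize_db <- function(archive) {
  idx <- if (is.character(archive)) read_db_index(archive) else archive
  if (nrow(idx) == 0) {
    return(tibble(rank = character(0), included_taxa = integer(0),
                  proteomes = integer(0)))
  }
  out <- idx |>
    group_by(rank = .data$rank) |>
    summarise(included_taxa = dplyr::n(),
              proteomes = sum(.data$proteome_count), .groups = "drop")
  ord <- match(out$rank, rev(TAXCYCLE_RANKS))
  out[order(ord), , drop = FALSE]
}

#' Grand totals of a per-rank database summary
#'
#' Sums the per-rank included-taxon and proteome counts of a summary
#' table as produced by [summarize_db()] or shipped with the package for
#' the published precomputed database (see [published_db_summary()]).
#'
#' @param summary A tibble with columns `included_taxa` and `proteomes`
#'   (extra columns are ignored).
#' @return A one-row tibble: `ranks`, `included_taxa_total`,
#'   `proteomes_total`.
#' @export
db_grand_totals <- function(summary) {
  tibble(ranks = nrow(summary),
         included_taxa_total = sum(summary$included_taxa),
         proteomes_total = sum(summary$proteomes))
}

#' Per-rank contents of the published precomputed database
#'
#' Returns the packaged summary of the published UniProt-derived
#' precomputed consensus-proteome database (version 1.0.0): for each
#' taxonomic rank, the number of UniProt taxa considered, the number of
#' taxa included (those with at least five associated proteomes) and the
#' number of source proteomes.
#'
#' @return A tibble with columns `rank`, `uniprot_taxa`, `included_taxa`,
#'   `proteomes`.
#' @export
published_db_summary <- function() {
  path <- system.file("extdata", "published_db_summary.tsv",
                      package = "taxcycle", mustWork = TRUE)
  read_tsv_quiet(path, col_types = readr::cols(
    rank = "c", uniprot_taxa = "i", included_taxa = "i", proteomes = "i"))
}
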