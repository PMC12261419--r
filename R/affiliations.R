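#' Read a taxonomic-affiliation table
#'
#' Reads the tabulated affiliation file produced by amplicon taxonomic
#' assignment: one row per observation (OTU/ASV), with the observation
#' identifier in the first column and a semicolon-separated lineage,
#' ordered from the broadest to the most specific rank, in the second.
#'
#' Ranks are assigned positionally onto the seven-slot ladder
#' kingdom, phylum, class, order, family, genus, species.  With
#' `align = "broad"` (the default) a short lineage is anchored at the
#' broadest rank, so a three-element lineage spans kingdom to class;
#' with `align = "specific"` it is anchored at species.
#'
#' @param path Path to a TSV file with columns `observation_name` and
#'   `taxonomic_affiliation`.
#' @param header Logical; does the file carry a header row? Default `TRUE`.
#' @param align Either `"broad"` or `"specific"`; how short lineages are
#'   placed on the rank ladder.
#' @return A tibble with one row per lineage element: columns
#'   `observation_id`, `level` (1 = broadest element of that lineage),
#'   `rank` and `name`, ordered broad to specific within observation.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("observation_name\ttaxonomic_affiliation",
#'              "ASV_1\tBacteria;Bacillota;Clostridia"), tf)
#' read_affiliations(tf)
#' @export
read_affiliations <- function(path, header = TRUE,
                              align = c("broad", "specific")) {
  align <- match.arg(align)
  lines <- readLines(path)
  if (header && length(lines) > 0) {
    lines <- lines[-1]
    offset <- 1L
  } else {
    offset <- 0L
  }
  while (length(lines) > 0 && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]  # trailing blank lines only
  }
  if (length(lines) == 0) {
    abort("no affiliation rows found")
  }
  no_tab <- which(!grepl("\t", lines, fixed = TRUE))
  if (length(no_tab) > 0) {
    abort(sprintf("expected at least 2 tab-separated columns at line %d",
                  no_tab[1] + offset))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- trimws(map_chr(parts, 1))
  lineages <- trimws(map_chr(parts, ~ if (length(.x) >= 2) .x[2] else ""))
  empty <- which(!nzchar(lineages))
  if (length(empty) > 0) {
    abort(sprintf("empty lineage at line %d", empty[1] + offset))
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate observation id: %s", dup[1]))
  }
  rows <- map2(ids, lineages, function(id, lin) {
    nm <- trimws(strsplit(lin, ";", fixed = TRUE)[[1]])
    nm <- nm[nzchar(nm)]
    if (length(nm) == 0) {
      abort(sprintf("empty lineage for observation %s", id))
    }
    if (length(nm) > length(TAXCYCLE_RANKS)) {
      abort(sprintf(
        "lineage for observation %s has %d elements; at most %d supported",
        id, length(nm), length(TAXCYCLE_RANKS)))
    }
    k <- length(nm)
    ranks <- if (identical(align, "broad")) {
      TAXCYCLE_RANKS[seq_len(k)]
    } else {
      TAXCYCLE_RANKS[seq.int(length(TAXCYCLE_RANKS) - k + 1,
                             length(TAXCYCLE_RANKS))]
    }
    tibble(observation_id = id, level = seq_len(k), rank = ranks, name = nm)
  })
  bind_rows(rows)
}

# Normalize a rank label: "domain" is accepted as a synonym for the
# broadest slot.
normalize_rank <- function(rank) {
  rank <- tolower(trimws(rank))
  rank[rank == "domain"] <- "kingdom"
  unknown <- setdiff(unique(rank), TAXCYCLE_RANKS)
  if (length(unknown) > 0) {
    abort(sprintf("unknown taxonomic rank: %s",
                  paste(unknown, collapse = ", ")))
  }
  rank
}
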