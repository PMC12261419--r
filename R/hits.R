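#' Read a per-profile bit-score cutoff table
#'
#' @param path TSV with columns `profile_name`, `bit_cutoff`.
#' @return Named numeric vector of cutoffs (bits).
#' @export
read_cutoffs <- function(path) {
  tb <- read_tsv_quiet(path, col_types = readr::cols(
    profile_name = "c", bit_cutoff = "d"))
  if (any(!is.finite(tb$bit_cutoff))) {
    abort("cutoff table contains non-finite thresholds")
  }
  stats::setNames(tb$bit_cutoff, tb$profile_name)
}

as_protein_set <- function(proteome) {
  if (inherits(proteome, "AAStringSet")) {
    stats::setNames(as.character(proteome), names(proteome))
  } else if (is.character(proteome) && length(proteome) == 1 &&
             file.exists(proteome)) {
    seqs <- Biostrings::readAAStringSet(proteome)
    stats::setNames(as.character(seqs), names(seqs))
  } else if (is.character(proteome) && !is.null(names(proteome))) {
    proteome
  } else {
    abort("proteome must be a FASTA path, AAStringSet or named character vector")
  }
}

#' Score a proteome against a profile collection and call hits
#'
#' Scores every (sequence, profile) pair with [viterbi_score()] and
#' marks a hit as passed when its bit score reaches the effective
#' cutoff: the cutoff table entry for the profile if present, else the
#' profile's own `cutoff_bits` (GA line), else `default_cutoff`.  A
#' profile is considered present in the proteome when at least one
#' sequence passes.
#'
#' @param profiles A list of [profile_hmm()] objects or a path to a
#'   HMMER3 file / directory of `.hmm` files.
#' @param proteome FASTA path, `AAStringSet`, or named character vector
#'   of amino-acid sequences.
#' @param cutoffs Optional named numeric vector from [read_cutoffs()].
#' @param default_cutoff Fallback bit-score threshold (default 40).
#' @return A tibble with columns `sequence_id`, `profile_name`,
#'   `bit_score`, `span_start`, `span_end`, `passed`, ordered by
#'   sequence then profile name.
#' @export
call_hits <- function(profiles, proteome, cutoffs = NULL,
                      default_cutoff = 40) {
  profiles <- as_profile_list(profiles)
  seqs <- as_protein_set(proteome)
  if (length(seqs) == 0) abort("proteome is empty")

  tables <- map(profiles, profile_tables)
  effs <- map_dbl(profiles, effective_cutoff, cutoffs = cutoffs,
                  default_cutoff = default_cutoff)
  rows <- map(names(seqs), function(sid) {
    x <- encode_sequence(seqs[[sid]])
    bind_rows(map(seq_along(profiles), function(j) {
      sc <- viterbi_score_tb(tables[[j]], x)
      tibble(sequence_id = sid, profile_name = profiles[[j]]$name,
             bit_score = sc$bit_score,
             span_start = sc$span[1], span_end = sc$span[2],
             passed = is.finite(sc$bit_score) && sc$bit_score >= effs[j])
    }))
  })
  out <- bind_rows(rows)
  out[order(out$sequence_id, out$profile_name), , drop = FALSE]
}

effective_cutoff <- function(profile, cutoffs, default_cutoff) {
  if (!is.null(cutoffs) && profile$name %in% names(cutoffs)) {
    cutoffs[[profile$name]]
  } else if (!is.null(profile$cutoff_bits)) {
    profile$cutoff_bits
  } else {
    default_cutoff
  }
}

as_profile_list <- function(profiles) {
  if (inherits(profiles, "profile_hmm")) {
    return(stats::setNames(list(profiles), profiles$name))
  }
  if (is.character(profiles)) {
    paths <- if (length(profiles) == 1 && dir.exists(profiles)) {
      sort(list.files(profiles, pattern = "\\.hmm$", full.names = TRUE))
    } else {
      profiles
    }
    out <- list()
    for (p in paths) out <- c(out, read_hmm(p))
    return(out)
  }
  if (is.list(profiles)) {
    stopifnot(all(map_lgl(profiles, inherits, "profile_hmm")))
    return(stats::setNames(profiles, map_chr(profiles, "name")))
  }
  abort("profiles must be profile_hmm objects or a .hmm path")
}

#' Profiles present in a hit table
#'
#' @param hits Hit tibble from [call_hits()].
#' @return Character vector of profile names with at least one passed hit.
#' @export
profiles_present <- function(hits) {
  sort(unique(hits$profile_name[hits$passed]))
}

#' Write a hit table to TSV
#'
#' Bit scores are rounded to 3 decimals in the file; the in-memory
#' table keeps full precision.
#'
#' @param hits Hit tibble from [call_hits()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_hits <- function(hits, path) {
  hits$bit_score <- round(hits$bit_score, 3)
  write_tsv_file(hits, path)
}
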