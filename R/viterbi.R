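# Local Viterbi scoring of protein sequences against profile HMMs.
#
# Alignment convention: unihit local over match states.  A path enters
# the profile at any match state and leaves from any match state, both
# at zero cost; inside the profile it follows plan7 core transitions
# (match/insert/delete).  The score of a path is the sum of log2-odds
# emission scores (emission probability over background; insert states
# included) plus log2 transition probabilities.  Delete states emit
# nothing.  Ambiguity codes B/Z/X (and J/U/O) score log-odds 0; "*" in
# a sequence is skipped.

encode_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 ||
      is.na(sequence) || !nzchar(sequence)) {
    abort("sequence must be a non-empty string")
  }
  chars <- strsplit(toupper(sequence), "")[[1]]
  chars <- chars[chars != "*"]
  if (length(chars) == 0) {
    abort("sequence contains no scorable residues")
  }
  idx <- match(chars, AA_ALPHABET)
  amb <- chars %in% AA_AMBIGUOUS
  bad <- is.na(idx) & !amb
  if (any(bad)) {
    abort(sprintf("invalid residue '%s' in sequence", chars[which(bad)[1]]))
  }
  idx[amb] <- 0L
  idx
}

# Per-profile scoring tables in bits; ambiguity residues (index 0)
# handled by prepending a zero column.
profile_tables <- function(profile, background = NULL) {
  bg <- background %||% profile$background
  lm <- log2(sweep(profile$match_emissions, 2, bg, "/"))
  li <- log2(sweep(profile$insert_emissions, 2, bg, "/"))
  tr <- log2(profile$transitions)
  list(lm = cbind(0, lm), li = cbind(0, li),
       tmm = tr[, "mm"], tmi = tr[, "mi"], tmd = tr[, "md"],
       tim = tr[, "im"], tii = tr[, "ii"],
       tdm = tr[, "dm"], tdd = tr[, "dd"],
       M = profile$length)
}

#' Score a sequence against a profile HMM (local Viterbi)
#'
#' Computes the best single local alignment of the sequence to the
#' profile under the convention described in [profile_hmm()]: entry and
#' exit at any match state are free; emissions are scored in log2-odds
#' against the background; transitions cost their log2 probability.
#' The returned span is the 1-based inclusive range of sequence residues
#' consumed by the best path.
#'
#' @param profile A [profile_hmm()].
#' @param sequence Amino-acid string (ambiguity codes `B`, `Z`, `X`
#'   score neutrally; `*` characters are skipped).
#' @param background Optional override of the profile's background.
#' @param with_span Track the aligned span (default `TRUE`); scoring
#'   without the traceback is faster for screening.
#' @return A list with elements `bit_score` (may be `-Inf` when no
#'   residue can be emitted by any match state) and `span`
#'   (`c(start, end)`, `NA` when the score is infinite).
#' @seealso [brute_force_score()] for the exhaustive-path oracle.
#' @export
viterbi_score <- function(profile, sequence, background = NULL,
                          with_span = TRUE) {
  x <- encode_sequence(sequence)
  tb <- profile_tables(profile, background)
  viterbi_score_tb(tb, x, with_span)
}

# DP on precomputed tables (callers scoring many sequences against one
# profile build the tables once).
viterbi_score_tb <- function(tb, x, with_span = TRUE) {
  r <- .viterbi_dp(tb$lm, tb$li, tb$tmm, tb$tmi, tb$tmd,
                   tb$tim, tb$tii, tb$tdm, tb$tdd,
                   as.integer(x), with_span)
  if (!is.finite(r$bit_score)) {
    return(list(bit_score = -Inf, span = c(NA_integer_, NA_integer_)))
  }
  list(bit_score = r$bit_score, span = c(r$span_start, r$span_end))
}

#' Exhaustive-path local alignment score (test oracle)
#'
#' Enumerates every legal state path under the same local-alignment
#' convention as [viterbi_score()] and returns the maximum path score.
#' Exponential in profile and sequence length; restricted to small
#' problems.
#'
#' @inheritParams viterbi_score
#' @param max_states,max_length Enumeration bounds (defaults 4 and 6).
#' @return Maximum path bit score (`-Inf` when no path is finite).
#' @export
brute_force_score <- function(profile, sequence, background = NULL,
                              max_states = 4, max_length = 6) {
  x <- encode_sequence(sequence)
  tb <- profile_tables(profile, background)
  M <- tb$M
  L <- length(x)
  if (M > max_states || L > max_length) {
    abort(sprintf(
      "exhaustive enumeration limited to M <= %d, L <= %d", max_states,
      max_length))
  }
  em <- function(k, i) tb$lm[k, x[i] + 1L]
  ei <- function(k, i) tb$li[k, x[i] + 1L]

  best <- -Inf
  # state: type in {m,i,d}, node k, last consumed residue i, score
  explore <- function(type, k, i, score) {
    if (!is.finite(score)) return()
    if (type == "m") {
      if (score > best) best <<- score
    }
    if (type == "m") {
      if (i < L && k < M) {
        explore("m", k + 1L, i + 1L, score + tb$tmm[k] + em(k + 1L, i + 1L))
      }
      if (i < L) {
        explore("i", k, i + 1L, score + tb$tmi[k] + ei(k, i + 1L))
      }
      if (k < M) {
        explore("d", k + 1L, i, score + tb$tmd[k])
      }
    } else if (type == "i") {
      if (i < L && k < M) {
        explore("m", k + 1L, i + 1L, score + tb$tim[k] + em(k + 1L, i + 1L))
      }
      if (i < L) {
        explore("i", k, i + 1L, score + tb$tii[k] + ei(k, i + 1L))
      }
    } else {
      if (i < L && k < M) {
        explore("m", k + 1L, i + 1L, score + tb$tdm[k] + em(k + 1L, i + 1L))
      }
      if (k < M) {
        explore("d", k + 1L, i, score + tb$tdd[k])
      }
    }
  }
  for (s in seq_len(L)) {
    for (j in seq_len(M)) {
      explore("m", j, s, em(j, s))
    }
  }
  unname(best)
}
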