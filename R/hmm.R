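#' Profile hidden Markov models
#'
#' A `profile_hmm` is a plan7-style protein profile: per-node match and
#' insert emission distributions over the 20 amino acids, per-node
#' transition probabilities (m->m, m->i, m->d, i->m, i->i, d->m, d->d)
#' and a background distribution used for log-odds scoring.  HMMER3
#' ASCII files store probabilities as negative natural logs, with `*`
#' for probability zero; [read_hmm()] converts them back.
#'
#' The background is not part of the HMMER3 file; a uniform 1/20
#' distribution is used (the convention of the packaged toy profiles).
#' The model's average composition (`COMPO` line) is retained when
#' present but not used for scoring.
#'
#' @param name Model name.
#' @param match_emissions,insert_emissions M x 20 probability matrices,
#'   columns in HMMER amino order `ACDEFGHIKLMNPQRSTVWY`.
#' @param transitions M x 7 probability matrix with columns
#'   `mm, mi, md, im, ii, dm, dd`; row k holds the transitions out of
#'   node k.
#' @param background Length-20 background distribution (default uniform).
#' @param cutoff_bits Optional sequence bit-score cutoff (GA/TC line).
#' @param accession Optional accession.
#' @return An object of class `profile_hmm`.
#' @export
profile_hmm <- function(name, match_emissions, insert_emissions,
                        transitions, background = rep(1 / 20, 20),
                        cutoff_bits = NULL, accession = NULL) {
  match_emissions <- as.matrix(match_emissions)
  insert_emissions <- as.matrix(insert_emissions)
  transitions <- as.matrix(transitions)
  colnames(match_emissions) <- AA_ALPHABET
  colnames(insert_emissions) <- AA_ALPHABET
  colnames(transitions) <- c("mm", "mi", "md", "im", "ii", "dm", "dd")
  obj <- structure(list(
    name = name, accession = accession,
    length = nrow(match_emissions),
    match_emissions = match_emissions,
    insert_emissions = insert_emissions,
    transitions = transitions,
    background = background,
    cutoff_bits = cutoff_bits), class = "profile_hmm")
  validate_profile_hmm(obj)
  obj
}

validate_profile_hmm <- function(x, tol = 1e-5) {
  M <- x$length
  if (M < 1) abort("profile must have at least one match state")
  if (ncol(x$match_emissions) != 20 || ncol(x$insert_emissions) != 20) {
    abort("emission tables must have 20 columns")
  }
  if (any(abs(rowSums(x$match_emissions) - 1) > tol) ||
      any(abs(rowSums(x$insert_emissions) - 1) > tol)) {
    abort(sprintf("emission rows of profile %s do not sum to 1", x$name))
  }
  tr <- x$transitions
  sums <- cbind(tr[, "mm"] + tr[, "mi"] + tr[, "md"],
                tr[, "im"] + tr[, "ii"],
                tr[, "dm"] + tr[, "dd"])
  if (any(abs(sums - 1) > tol)) {
    abort(sprintf("transition triples of profile %s do not sum to 1",
                  x$name))
  }
  if (abs(sum(x$background) - 1) > tol) {
    abort("background distribution does not sum to 1")
  }
  invisible(x)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("<profile_hmm> %s  (M = %d%s)\n", x$name, x$length,
              if (!is.null(x$cutoff_bits))
                sprintf(", cutoff %.2f bits", x$cutoff_bits) else ""))
  invisible(x)
}

# value <-> stored-field conversion for HMMER3 ASCII
hmmer_num <- function(tokens) {
  v <- suppressWarnings(as.numeric(tokens))
  v[tokens == "*"] <- Inf
  if (anyNA(v)) abort("unparseable numeric field in HMM file")
  exp(-v)
}

hmmer_field <- function(p) {
  ifelse(p <= 0, "*", sprintf("%.12f", -log(p)))
}

#' Read profile HMMs from a HMMER3 ASCII file
#'
#' Parses one or more concatenated models from a `HMMER3` format text
#' file.  Stored negative-natural-log values are converted to
#' probabilities (`*` becomes probability 0).  A `GA` (else `TC`)
#' cutoff line populates `cutoff_bits` with its sequence-level value.
#'
#' @param path Path to a `.hmm` file (possibly multi-model).
#' @return A named list of [profile_hmm()] objects, in file order.
#' @export
read_hmm <- function(path) {
  lines <- readLines(path)
  models <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    # skip blank lines between models
    while (i <= n && !nzchar(trimws(lines[i]))) i <- i + 1L
    if (i > n) break
    if (!startsWith(lines[i], "HMMER3")) {
      abort(sprintf("line %d: expected HMMER3 format header", i))
    }
    i <- i + 1L
    name <- NULL; acc <- NULL; leng <- NULL; cutoff <- NULL; tc <- NULL
    while (i <= n && !startsWith(lines[i], "HMM ")) {
      toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(toks) >= 2) {
        tag <- toks[1]
        if (tag == "NAME") name <- toks[2]
        if (tag == "ACC") acc <- toks[2]
        if (tag == "LENG") leng <- as.integer(toks[2])
        if (tag == "GA") cutoff <- as.numeric(sub(";", "", toks[2]))
        if (tag == "TC") tc <- as.numeric(sub(";", "", toks[2]))
      }
      i <- i + 1L
    }
    if (i > n) abort("truncated HMM file: no HMM line")
    if (is.null(leng)) abort("HMM model missing LENG line")
    if (is.null(name)) name <- "unnamed"
    if (is.null(cutoff)) cutoff <- tc
    i <- i + 1L  # HMM column header
    if (i <= n && grepl("m->m", lines[i])) i <- i + 1L  # transition header
    compo <- NULL
    if (i <= n && grepl("^\\s*COMPO", lines[i])) {
      toks <- strsplit(trimws(lines[i]), "\\s+")[[1]][-1]
      if (length(toks) != 20) {
        abort(sprintf("line %d: COMPO row must have 20 fields", i))
      }
      compo <- hmmer_num(toks)
      i <- i + 1L
    }
    # node 0: insert emissions + transitions
    ins0 <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(ins0) != 20) {
      abort(sprintf("line %d: node-0 insert row must have 20 fields", i))
    }
    i <- i + 1L
    tr0 <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tr0) != 7) {
      abort(sprintf("line %d: node-0 transition row must have 7 fields", i))
    }
    i <- i + 1L

    me <- matrix(0, leng, 20)
    ie <- matrix(0, leng, 20)
    tr <- matrix(0, leng, 7)
    for (k in seq_len(leng)) {
      if (i > n) abort(sprintf("truncated HMM model %s at node %d", name, k))
      toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (suppressWarnings(as.integer(toks[1])) != k) {
        abort(sprintf("line %d: expected node %d", i, k))
      }
      if (length(toks) < 21) {
        abort(sprintf("line %d: match row must have 20 emission fields", i))
      }
      me[k, ] <- hmmer_num(toks[2:21])
      i <- i + 1L
      toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(toks) != 20) {
        abort(sprintf("line %d: insert row must have 20 fields", i))
      }
      ie[k, ] <- hmmer_num(toks)
      i <- i + 1L
      toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(toks) != 7) {
        abort(sprintf("line %d: transition row must have 7 fields", i))
      }
      tr[k, ] <- hmmer_num(toks)
      i <- i + 1L
    }
    if (i > n || trimws(lines[i]) != "//") {
      abort(sprintf("model %s: missing // end marker", name))
    }
    i <- i + 1L
    # Last node: m->d is impossible; force exact closure of the triple so
    # files rounding M->E into m->m validate.
    tr[leng, 3] <- max(0, 1 - tr[leng, 1] - tr[leng, 2])
    hmm <- profile_hmm(name, me, ie, tr, cutoff_bits = cutoff,
                       accession = acc)
    hmm$compo <- compo
    models[[name]] <- hmm
  }
  if (length(models) == 0) abort("no HMM models found in file")
  models
}

#' Write profile HMMs to a HMMER3 ASCII file
#'
#' Inverse of [read_hmm()]: probabilities are stored as negative natural
#' logs (probability 0 as `*`), so `read_hmm(write_hmm(x))` round-trips
#' within numerical precision.
#'
#' @param hmms A `profile_hmm` or list of them.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hmm <- function(hmms, path) {
  if (inherits(hmms, "profile_hmm")) hmms <- list(hmms)
  out <- unlist(map(hmms, function(h) {
    M <- h$length
    header <- c(
      "HMMER3/f [taxcycle | profile]",
      sprintf("NAME  %s", h$name),
      if (!is.null(h$accession)) sprintf("ACC   %s", h$accession),
      sprintf("LENG  %d", M),
      "ALPH  amino",
      if (!is.null(h$cutoff_bits))
        sprintf("GA    %.4f %.4f;", h$cutoff_bits, h$cutoff_bits),
      paste0("HMM   ", paste(sprintf("%8s", AA_ALPHABET), collapse = " ")),
      paste0("      ", paste(sprintf("%8s",
        c("m->m", "m->i", "m->d", "i->m", "i->i", "d->m", "d->d")),
        collapse = " ")),
      paste0("  COMPO ",
             paste(hmmer_field(colMeans(h$match_emissions)), collapse = " ")),
      paste0("        ",
             paste(hmmer_field(h$insert_emissions[1, ]), collapse = " ")),
      paste0("        ",
             paste(hmmer_field(c(1, 0, 0, 1, 0, 1, 0)), collapse = " ")))
    nodes <- unlist(map(seq_len(M), function(k) {
      c(sprintf("%7d %s %7d %s", k,
                paste(hmmer_field(h$match_emissions[k, ]), collapse = " "),
                k, "x - - -"),
        paste0("        ",
               paste(hmmer_field(h$insert_emissions[k, ]), collapse = " ")),
        paste0("        ",
               paste(hmmer_field(h$transitions[k, ]), collapse = " ")))
    }))
    c(header, nodes, "//")
  }))
  writeLines(out, path)
  invisible(path)
}
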