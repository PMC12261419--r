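# Shared generators: random profiles/sequences for the scoring oracle,
# random Boolean formulas for the rule-engine oracle, and a tiny
# database-input builder.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_profile <- function(M) {
  dirichlet_row <- function(n) {
    x <- stats::rgamma(n, shape = 1)
    x / sum(x)
  }
  me <- t(replicate(M, dirichlet_row(20)))
  ie <- t(replicate(M, dirichlet_row(20)))
  tr <- t(sapply(seq_len(M), function(k) {
    c(dirichlet_row(3), dirichlet_row(2), dirichlet_row(2))
  }))
  profile_hmm(sprintf("rnd_M%d", M), me, ie, tr,
              background = dirichlet_row(20))
}

random_sequence <- function(L, p_ambiguous = 0.1) {
  chars <- sample(AA, L, replace = TRUE)
  amb <- stats::runif(L) < p_ambiguous
  chars[amb] <- "X"
  paste(chars, collapse = "")
}

# Random AND/OR formula text over the given leaf names.
random_formula <- function(leaves) {
  build <- function(ids) {
    if (length(ids) == 1) return(ids)
    split_at <- sample(seq_len(length(ids) - 1), 1)
    lhs <- build(ids[seq_len(split_at)])
    rhs <- build(ids[-seq_len(split_at)])
    op <- sample(c("AND", "OR"), 1)
    paren <- function(s) if (stats::runif(1) < 0.4) paste0("(", s, ")") else s
    paste(paren(lhs), op, paren(rhs))
  }
  build(sample(leaves, length(leaves)))
}

# Independent formula oracle: translate to an R logical expression
# (& / | share AND/OR's relative precedence) and evaluate leaves as
# membership in the present set.
oracle_eval <- function(text, present, leaves) {
  expr <- gsub("\\bAND\\b", "&", text)
  expr <- gsub("\\bOR\\b", "|", expr)
  env <- new.env()
  for (l in leaves) assign(l, l %in% present, envir = env)
  eval(parse(text = expr), envir = env)
}

# Write a minimal per-taxon database input directory; `taxa` is a list
# of lists with name, rank, proteome_count, seqs (named character),
# annotations (tibble cluster_id/protein_members/annotation_labels).
write_db_input <- function(dir, taxa) {
  for (tx in taxa) {
    d <- file.path(dir, gsub("[^A-Za-z0-9]", "_", tx$name))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(tibble::tibble(taxon_name = tx$name, rank = tx$rank,
                                    proteome_count = tx$proteome_count),
                     file.path(d, "taxon.tsv"), progress = FALSE)
    Biostrings::writeXStringSet(Biostrings::AAStringSet(tx$seqs),
                                file.path(d, "proteome.faa"))
    ann <- tx$annotations
    if (is.null(ann)) {
      ann <- tibble::tibble(cluster_id = names(tx$seqs),
                            protein_members = paste0(names(tx$seqs), "_p1"),
                            annotation_labels = "")
    }
    readr::write_tsv(ann, file.path(d, "annotations.tsv"), progress = FALSE)
  }
  dir
}

# A small ready-made affiliation file.
write_affiliation_file <- function(path, rows) {
  writeLines(c("observation_name\ttaxonomic_affiliation", rows), path)
  path
}

read_raw <- function(path) readBin(path, "raw", file.info(path)$size)
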