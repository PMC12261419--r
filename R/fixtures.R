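# Seeded synthetic inputs with known ground truth: toy profiles,
# proteomes with planted marker motifs plus background decoys, a
# taxonomy, abundance tables and a database archive.  Every stage of
# the pipeline, and the pipeline end to end, is testable against the
# truth tables these generators emit.

#' Build a toy profile HMM around a consensus peptide
#'
#' Match state i emits the i-th consensus residue with probability
#' `sharpness` and spreads the remainder uniformly over the other 19
#' residues; insert emissions and the background are uniform; the
#' match-to-match transition is exact (probability 1), so the consensus
#' peptide scores exactly `length * log2(sharpness * 20)` bits.
#' The profile's gathering cutoff is set to half the consensus score
#' unless overridden, giving planted motifs a two-fold margin.
#'
#' @param consensus Peptide of 3 to 10 standard residues.
#' @param sharpness Probability mass on the consensus residue, in
#'   `(0.5, 1]`.
#' @param name Profile name (default the consensus itself).
#' @param cutoff_bits Bit-score cutoff; default half the consensus
#'   score.
#' @return A [profile_hmm()].
#' @export
make_toy_hmm <- function(consensus, sharpness = 1.0, name = consensus,
                         cutoff_bits = NULL) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  if (length(chars) < 3 || length(chars) > 10) {
    abort("consensus length must be between 3 and 10")
  }
  idx <- match(chars, AA_ALPHABET)
  if (anyNA(idx)) {
    abort(sprintf("invalid consensus residue '%s'",
                  chars[which(is.na(idx))[1]]))
  }
  if (sharpness <= 0.5 || sharpness > 1) {
    abort("sharpness must be in (0.5, 1]")
  }
  M <- length(chars)
  me <- matrix((1 - sharpness) / 19, M, 20)
  me[cbind(seq_len(M), idx)] <- sharpness
  ie <- matrix(1 / 20, M, 20)
  tr <- matrix(rep(c(1, 0, 0, 1, 0, 1, 0), each = M), M, 7)
  cutoff <- cutoff_bits %||% (consensus_bits(consensus, sharpness) / 2)
  profile_hmm(name, me, ie, tr, cutoff_bits = cutoff)
}

#' Closed-form consensus score of a toy profile
#'
#' @inheritParams make_toy_hmm
#' @return `nchar(consensus) * log2(sharpness * 20)` bits.
#' @export
consensus_bits <- function(consensus, sharpness = 1.0) {
  nchar(consensus) * log2(sharpness * 20)
}

# Default compact marker/rule set used by generated fixture specs.
fixture_default_rules <- function() {
  tibble(
    function_name = c("methanogenesis", "acetogenesis_wl",
                      "sulfate_reduction", "hydrogen_generation"),
    cycle = c("carbon", "carbon", "sulfur", "carbon"),
    formula = c("mcrA", "acsB AND fthfs", "dsrA AND dsrB",
                "hycE OR hydA"))
}

fixture_lineage <- function(i, genus) {
  sprintf("Bacteria;Phylum_%d;Class_%d;Order_%d;Family_%d;%s",
          (i - 1) %% 3 + 1, (i - 1) %% 3 + 1, i, i, genus)
}

#' Specify a synthetic community fixture
#'
#' Designs (from the seed) a community of taxa with planted marker
#' profiles, integer per-sample abundances and a Boolean rule set, and
#' derives the implied ground-truth function-presence and community
#' profiles.  [make_community_fixture()] materializes the files.
#'
#' Integer abundances keep the expected profile fractions exactly
#' rational; planted motifs score exactly twice their profile cutoff
#' and decoys are rejection-sampled below half of it, so recovery is
#' margin-safe by construction.
#'
#' @param seed Integer seed; the whole design is a deterministic
#'   function of it.
#' @param n_taxa Number of taxa (observations) in the community.
#' @param n_samples Number of abundance samples.
#' @param decoys_per_proteome Background decoy sequences added to every
#'   consensus proteome.
#' @param taxa Optional custom taxa tibble (`name`, `lineage`,
#'   `planted` list-column, optional `proteome_count`); generated when
#'   `NULL`.
#' @param samples Optional custom abundance tibble (`observation_name`
#'   + one integer column per sample).
#' @param rules Optional custom rule tibble (`function_name`, `cycle`,
#'   `formula`).
#' @param consensus_length,sharpness,decoy_length Toy-profile geometry.
#' @return A `fixture_spec` list with the design tables, the marker
#'   inventory and the truth tables `presence_truth` (wide logical) and
#'   `profile_truth` (long, per sample and function).
#' @export
fixture_spec <- function(seed, n_taxa = 5, n_samples = 2,
                         decoys_per_proteome = 8,
                         taxa = NULL, samples = NULL, rules = NULL,
                         consensus_length = 8, sharpness = 1.0,
                         decoy_length = 30) {
  set.seed(seed)
  rules <- rules %||% fixture_default_rules()
  rules$ast <- map(rules$formula, parse_rule)
  markers <- sort(unique(unlist(map(rules$ast, rule_leaves))))

  if (is.null(taxa)) {
    nm <- sprintf("Genus_%02d", seq_len(n_taxa))
    planted <- map(seq_len(n_taxa), function(i) {
      p <- markers[stats::runif(length(markers)) < 0.5]
      if (length(p) == 0) p <- sample(markers, 1)
      sort(p)
    })
    taxa <- tibble(name = nm,
                   lineage = map_chr(seq_len(n_taxa), ~ fixture_lineage(
                     .x, nm[.x])),
                   planted = planted,
                   proteome_count = 6L + seq_len(n_taxa) %% 3)
  }
  if (is.null(taxa$proteome_count)) taxa$proteome_count <- 6L
  if (anyDuplicated(taxa$name) > 0) {
    abort("duplicate taxon names in fixture spec")
  }
  taxa$observation_id <- paste0("obs_", taxa$name)

  if (is.null(samples)) {
    samples <- tibble(observation_name = taxa$observation_id)
    for (s in seq_len(n_samples)) {
      samples[[sprintf("sample_%d", s)]] <-
        sample(1:100, nrow(taxa), replace = TRUE)
    }
  }

  # marker consensus peptides: distinct, and no peptide may reach
  # another marker's cutoff (a chance shared 4-mer would otherwise
  # plant a cross-hit no flank choice could avoid)
  consensus <- character(length(markers))
  repeat {
    consensus <- map_chr(markers, ~ paste(
      sample(AA_ALPHABET, consensus_length, replace = TRUE), collapse = ""))
    if (anyDuplicated(consensus) > 0) next
    probe <- map(consensus, make_toy_hmm, sharpness = sharpness)
    cross <- FALSE
    for (i in seq_along(probe)) {
      for (j in seq_along(probe)) {
        if (i == j) next
        sc <- viterbi_score(probe[[i]], consensus[j],
                            with_span = FALSE)$bit_score
        if (is.finite(sc) && sc >= probe[[i]]$cutoff_bits) cross <- TRUE
      }
    }
    if (!cross) break
  }
  profiles_design <- tibble(marker = markers, consensus = consensus,
                            sharpness = sharpness,
                            cutoff_bits = consensus_bits(
                              consensus[1], sharpness) / 2)

  presence_truth <- truth_presence(taxa, rules)
  profile_truth <- truth_profile(presence_truth, samples)

  structure(list(seed = seed, taxa = taxa, samples = samples,
                 rules = rules, markers = markers,
                 profiles_design = profiles_design,
                 decoys_per_proteome = decoys_per_proteome,
                 decoy_length = decoy_length,
                 presence_truth = presence_truth,
                 profile_truth = profile_truth),
            class = "fixture_spec")
}

# Ground-truth presence by evaluating the rules on the planted sets.
truth_presence <- function(taxa, rules) {
  out <- tibble(taxon = taxa$observation_id)
  for (j in seq_len(nrow(rules))) {
    out[[rules$function_name[j]]] <-
      map_lgl(taxa$planted, ~ eval_rule(rules$ast[[j]], .x))
  }
  out
}

# Ground-truth per-sample profiles by direct arithmetic on the truth
# presence matrix (membership: abundance > 0).
truth_profile <- function(presence_truth, samples) {
  fn <- setdiff(names(presence_truth), "taxon")
  sample_cols <- setdiff(names(samples), "observation_name")
  bind_rows(map(sample_cols, function(s) {
    ab <- stats::setNames(samples[[s]], samples$observation_name)
    members <- intersect(presence_truth$taxon, names(ab)[ab > 0])
    sub <- presence_truth[match(members, presence_truth$taxon), ,
                          drop = FALSE]
    tibble(sample = s, function_name = fn,
           occurrence = map_dbl(fn, ~ sum(sub[[.x]]) / length(members)),
           relative_abundance = map_dbl(
             fn, ~ sum(ab[members][sub[[.x]]]) / sum(ab[members])))
  }))
}

#' Materialize a synthetic community fixture on disk
#'
#' Writes every input the pipeline consumes, in its external format:
#' `affiliations.tsv`, `abundances.tsv`, the per-taxon database input
#' tree `taxdb_input/`, the built archive `taxdb.zip`, the multi-model
#' profile file `profiles.hmm`, `rules.tsv`, and the ground-truth
#' tables under `truth/`.  Output bytes are a deterministic function of
#' the spec.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created; must be empty or absent).
#' @return Invisibly, a named list of the paths written plus the spec.
#' @export
make_community_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed + 1L)

  profiles <- map(seq_len(nrow(spec$profiles_design)), function(j) {
    d <- spec$profiles_design[j, ]
    make_toy_hmm(d$consensus, d$sharpness, name = d$marker,
                 cutoff_bits = d$cutoff_bits)
  })
  names(profiles) <- spec$profiles_design$marker
  profile_cache <- map(profiles, profile_tables)
  hmm_path <- file.path(dir, "profiles.hmm")
  write_hmm(profiles, hmm_path)

  # per-taxon database input: planted motifs + rejected decoys
  input_dir <- file.path(dir, "taxdb_input")
  flank <- function(k) paste(sample(AA_ALPHABET, k, replace = TRUE),
                             collapse = "")
  for (i in seq_len(nrow(spec$taxa))) {
    tdir <- file.path(input_dir, sanitize_token(spec$taxa$name[i]))
    dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
    planted <- spec$taxa$planted[[i]]
    seqs <- character(0)
    labels <- character(0)
    for (m in planted) {
      cons <- spec$profiles_design$consensus[
        spec$profiles_design$marker == m]
      # random flanks must not create a passing hit on any other profile
      repeat {
        cand <- paste0(flank(4), cons, flank(4))
        clean <- all(map_lgl(seq_along(profiles), function(j) {
          if (names(profiles)[j] == m) return(TRUE)
          sc <- viterbi_score_tb(profile_cache[[j]], encode_sequence(cand),
                                 with_span = FALSE)$bit_score
          !is.finite(sc) || sc < profiles[[j]]$cutoff_bits
        }))
        if (clean) break
      }
      seqs <- c(seqs, cand)
      labels <- c(labels, m)
    }
    for (d in seq_len(spec$decoys_per_proteome)) {
      seqs <- c(seqs, make_decoy(profiles, spec$decoy_length,
                                 tables = profile_cache))
      labels <- c(labels, "")
    }
    ids <- sprintf("%s_cluster_%02d", sanitize_token(spec$taxa$name[i]),
                   seq_along(seqs))
    aa <- Biostrings::AAStringSet(stats::setNames(seqs, ids))
    Biostrings::writeXStringSet(aa, file.path(tdir, "proteome.faa"))
    ann <- tibble(cluster_id = ids,
                  protein_members = paste0(ids, "_p1,", ids, "_p2"),
                  annotation_labels = labels)
    write_tsv_file(ann, file.path(tdir, "annotations.tsv"))
    lin <- strsplit(spec$taxa$lineage[i], ";", fixed = TRUE)[[1]]
    write_tsv_file(tibble(taxon_name = spec$taxa$name[i],
                          rank = TAXCYCLE_RANKS[length(lin)],
                          proteome_count = spec$taxa$proteome_count[i]),
                   file.path(tdir, "taxon.tsv"))
  }
  archive <- file.path(dir, "taxdb.zip")
  build_taxon_db(input_dir, archive, min_proteomes = 5)

  # margin check: planted motifs clear 2x cutoff, decoys stay below half
  check_fixture_margins(spec, profiles, input_dir)

  aff_path <- file.path(dir, "affiliations.tsv")
  write_tsv_file(tibble(observation_name = spec$taxa$observation_id,
                        taxonomic_affiliation = spec$taxa$lineage),
                 aff_path)
  ab_path <- file.path(dir, "abundances.tsv")
  write_tsv_file(spec$samples, ab_path)
  rules_path <- file.path(dir, "rules.tsv")
  write_tsv_file(spec$rules[, c("function_name", "cycle", "formula")],
                 rules_path)

  # synthetic diagram template covering exactly the fixture's functions,
  # so rendering is exercised end to end with any custom rule set
  tpl_dir <- file.path(dir, "templates")
  dir.create(tpl_dir, showWarnings = FALSE)
  write_fixture_template(spec$rules, file.path(tpl_dir, "synthetic"))

  truth_dir <- file.path(dir, "truth")
  dir.create(truth_dir, showWarnings = FALSE)
  write_presence(spec$presence_truth,
                 file.path(truth_dir, "presence_truth.tsv"))
  write_tsv_file(spec$profile_truth,
                 file.path(truth_dir, "profile_truth.tsv"))

  invisible(list(dir = dir, affiliations = aff_path, abundances = ab_path,
                 archive = archive, profiles = hmm_path,
                 rules = rules_path, templates = tpl_dir,
                 truth_dir = truth_dir, spec = spec))
}

# Minimal single-cycle template: one labelled edge per function.
write_fixture_template <- function(rules, prefix) {
  fn <- rules$function_name
  anchors <- paste0(fn, "_w")
  edges <- tibble(function_name = fn, anchor_id = anchors,
                  substrate = paste0("substrate_", fn),
                  product = paste0("product_", fn))
  write_tsv_file(edges, paste0(prefix, "_edges.tsv"))
  y <- 30 + 30 * seq_along(fn)
  body <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="420" height="%d">',
            max(y) + 30),
    "<style>text{font-family:sans-serif;font-size:12px}",
    ".weight{fill:#b30000;font-weight:bold}.weight.zero{fill:#bbb}</style>",
    sprintf('<text x="20" y="%d">%s</text><text class="{{%s.class}}" x="280" y="%d">{{%s.label}}</text>',
            y, fn, anchors, y, anchors),
    "</svg>")
  writeLines(body, paste0(prefix, ".svg"))
  invisible(prefix)
}

# Background decoy: uniform random residues, rejected while any profile
# scores it at or above 45% of its cutoff, keeping decoys strictly below
# the half-cutoff margin even after cutoff values round-trip through
# the HMM file format.
make_decoy <- function(profiles, decoy_length, max_tries = 1000,
                       tables = NULL) {
  tables <- tables %||% map(profiles, profile_tables)
  cut <- map_dbl(profiles, "cutoff_bits")
  for (try in seq_len(max_tries)) {
    s <- sample(seq_len(20), decoy_length, replace = TRUE)
    ok <- all(map_lgl(seq_along(tables), function(j) {
      sc <- viterbi_score_tb(tables[[j]], s, with_span = FALSE)$bit_score
      !is.finite(sc) || sc < 0.45 * cut[j]
    }))
    if (ok) return(paste(AA_ALPHABET[s], collapse = ""))
  }
  abort("decoy rejection sampling failed")
}

check_fixture_margins <- function(spec, profiles, input_dir) {
  for (i in seq_len(nrow(spec$taxa))) {
    tdir <- file.path(input_dir, sanitize_token(spec$taxa$name[i]))
    seqs <- Biostrings::readAAStringSet(file.path(tdir, "proteome.faa"))
    ann <- read_tsv_quiet(file.path(tdir, "annotations.tsv"),
                          col_types = readr::cols(.default = "c"))
    for (j in seq_len(nrow(ann))) {
      lab <- ann$annotation_labels[j]
      s <- as.character(seqs[[ann$cluster_id[j]]])
      if (!is.na(lab) && nzchar(lab)) {
        h <- profiles[[lab]]
        sc <- viterbi_score(h, s, with_span = FALSE)$bit_score
        if (sc < 2 * h$cutoff_bits - 1e-9) {
          abort(sprintf("planted motif for %s under margin in %s",
                        lab, ann$cluster_id[j]))
        }
      }
    }
  }
  invisible(TRUE)
}
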