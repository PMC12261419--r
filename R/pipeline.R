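#' Run the full affiliation-to-cycle-diagram pipeline
#'
#' Executes the three stages end to end: (1) resolve taxonomic
#' affiliations against the consensus-proteome archive with rank
#' fallback; (2) score each matched taxon's consensus proteome against
#' the marker-profile collection and call coarse-grained functions with
#' the Boolean rules; (3) aggregate per-sample occurrence/abundance
#' profiles and project them onto the cycle diagrams.  Per-taxon HMM
#' searches are distributed over `cores` workers; results are merged in
#' deterministic taxon order, so every file under the numbered stage
#' directories is byte-identical for any worker count.
#'
#' Output layout under `output_dir`:
#' `0_resolution/`, `1_hits/`, `2_functions/`, `3_profiles/`,
#' `4_diagrams/`, plus `run_report.json` (a log: versions, counts,
#' warnings and wall-clock stage timings).
#'
#' @param affiliations Path to the affiliation TSV.
#' @param archive Path to the consensus-proteome archive.
#' @param profiles Path to a HMMER3 profile file or directory of
#'   `.hmm` files.
#' @param output_dir Output directory (created if needed).
#' @param abundances Optional path to the abundance TSV.
#' @param rules Optional path to a rule TSV; default the packaged set.
#' @param templates Optional directory of custom diagram templates
#'   (`<cycle>.svg` + `<cycle>_edges.tsv`); default the packaged carbon,
#'   nitrogen and sulfur templates.
#' @param cores Workers for the per-taxon HMM search (default 1).
#' @param cutoffs Optional path to a cutoff TSV ([read_cutoffs()]).
#' @param default_cutoff Fallback bit-score cutoff (default 40).
#' @param min_display Polar-plot display threshold (default 0.10).
#' @return Invisibly, a list: `profile` (the `community_profile`),
#'   `presence`, `resolution`, `report` (the run-report list).
#' @export
run_pipeline <- function(affiliations, archive, profiles, output_dir,
                         abundances = NULL, rules = NULL,
                         templates = NULL, cores = 1,
                         cutoffs = NULL, default_cutoff = 40,
                         min_display = 0.10) {
  # configuration checks before any work
  mandatory <- c(affiliations = affiliations, archive = archive,
                 profiles = profiles)
  for (nm in names(mandatory)) {
    if (!file.exists(mandatory[[nm]])) {
      abort(sprintf("config error: %s path does not exist: %s", nm,
                    mandatory[[nm]]))
    }
  }
  if (!is.null(abundances) && !file.exists(abundances)) {
    abort(sprintf("config error: abundances path does not exist: %s",
                  abundances))
  }
  if (cores < 1) abort("config error: cores must be >= 1")

  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("0_resolution", "1_hits", "2_functions", "3_profiles",
              "4_diagrams")) {
    dir.create(file.path(output_dir, d), showWarnings = FALSE)
  }
  warnings_seen <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  timings <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("[stage %s] %s", name, conditionMessage(e)))
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }

  # stage 1: resolution
  res <- stage("resolve", {
    aff <- read_affiliations(affiliations)
    idx <- read_db_index(archive)
    r <- resolve_affiliations(aff, idx)
    write_tsv_file(r, file.path(output_dir, "0_resolution",
                                "resolution.tsv"))
    r
  })

  # stage 2: HMM search + function calls
  rules_tb <- collect(read_rules(rules))
  hmms <- as_profile_list(profiles)
  cutoff_tb <- if (!is.null(cutoffs)) read_cutoffs(cutoffs) else NULL

  presence <- stage("search", {
    resolved <- res[res$status == "resolved", , drop = FALSE]
    taxa <- sort(unique(resolved$matched_taxon))
    scan_one <- function(tx) {
      rec <- suppressWarnings(read_taxon_record(archive, tx))
      seqs <- stats::setNames(rec$consensus_sequence, rec$cluster_id)
      seqs <- seqs[!is.na(seqs)]
      call_hits(hmms, seqs, cutoffs = cutoff_tb,
                default_cutoff = default_cutoff)
    }
    hit_list <- if (cores > 1 &&
                    requireNamespace("parallel", quietly = TRUE) &&
                    .Platform$OS.type == "unix") {
      parallel::mclapply(taxa, scan_one, mc.cores = cores)
    } else {
      map(taxa, scan_one)
    }
    names(hit_list) <- taxa
    all_hits <- bind_rows(imap(hit_list, ~ mutate(.x, taxon = .y,
                                                  .before = 1)))
    write_hits(all_hits, file.path(output_dir, "1_hits", "hits.tsv"))

    taxon_sets <- map(hit_list, profiles_present)
    obs_sets <- stats::setNames(
      map(seq_len(nrow(resolved)),
          ~ taxon_sets[[resolved$matched_taxon[.x]]]),
      resolved$observation_id)
    pres <- collect(call_functions(obs_sets, rules_tb,
                                   known_profiles = names(hmms)))
    write_presence(pres, file.path(output_dir, "2_functions",
                                   "function_presence.tsv"))
    pres
  })

  # stage 3: profiles + diagrams
  profile <- stage("profile", {
    ab <- if (!is.null(abundances)) read_abundances(abundances) else NULL
    pr <- profile_community(presence, res, ab, rules_tb)
    write_profile_tables(pr, file.path(output_dir, "3_profiles"))
    write_tsv_file(polar_summary(pr, min_display = min_display),
                   file.path(output_dir, "3_profiles",
                             "polar_summary.tsv"))
    write_tsv_file(heatmap_table(pr),
                   file.path(output_dir, "3_profiles",
                             "heatmap_table.tsv"))
    pr
  })

  rendered <- stage("render", {
    prefixes <- if (is.null(templates)) {
      file.path(system.file("extdata", "templates", package = "taxcycle",
                            mustWork = TRUE),
                c("carbon", "nitrogen", "sulfur"))
    } else {
      sub("\\.svg$", "",
          sort(list.files(templates, pattern = "\\.svg$",
                          full.names = TRUE)))
    }
    mode <- if (profile$has_abundance) "abundance" else "occurrence"
    out <- character(0)
    for (p in prefixes) {
      dg <- read_cycle_template(prefix = p)
      if (!all(dg$edges$function_name %in% rules_tb$function_name)) {
        next  # template covers functions this rule set does not define
      }
      for (s in glance(profile)$sample) {
        proj <- project_profile(profile, dg, mode = mode, sample = s)
        f <- file.path(output_dir, "4_diagrams",
                       sprintf("%s_%s.svg", dg$cycle, s))
        render_diagram(proj, f)
        out <- c(out, f)
      }
    }
    out
  })

  report <- list(
    tool = "taxcycle",
    version = as.character(utils::packageVersion("taxcycle")),
    config = list(affiliations = affiliations, archive = archive,
                  profiles = profiles, abundances = abundances,
                  rules = rules %||% "packaged default",
                  cores = cores, default_cutoff = default_cutoff,
                  min_display = min_display),
    n_observations = nrow(res),
    n_resolved = sum(res$status == "resolved"),
    unresolved = res$observation_id[res$status == "unresolved"],
    n_profiles = length(hmms),
    n_functions = nrow(rules_tb),
    diagrams = basename(rendered),
    warnings = unique(warnings_seen),
    stage_timings_s = timings)
  jsonlite::write_json(report, file.path(output_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(profile = profile, presence = presence,
                 resolution = res, report = report))
}
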