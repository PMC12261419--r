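#' Read an observation-by-sample abundance table
#'
#' @param path TSV with first column `observation_name` and one column
#'   per sample (non-negative counts or relative abundances).
#' @return A tibble; negative entries are an error.
#' @export
read_abundances <- function(path) {
  tb <- read_tsv_quiet(path)
  names(tb)[1] <- "observation_name"
  tb$observation_name <- as.character(tb$observation_name)
  sample_cols <- setdiff(names(tb), "observation_name")
  if (length(sample_cols) == 0) {
    abort("abundance table has no sample columns")
  }
  for (s in sample_cols) {
    tb[[s]] <- as.numeric(tb[[s]])
    if (any(is.na(tb[[s]])) || any(tb[[s]] < 0)) {
      abort(sprintf("negative or missing abundance in sample %s", s))
    }
  }
  dup <- tb$observation_name[duplicated(tb$observation_name)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate observation in abundance table: %s", dup[1]))
  }
  tb
}

#' Occurrence of each function among a sample's member taxa
#'
#' Occurrence of a function is the number of member taxa possessing it
#' divided by the number of member taxa.
#'
#' @param presence Wide presence tibble from [call_functions()] (rows =
#'   observations/taxa).
#' @param members Character vector of member observation ids.
#' @return A tibble `function_name`, `occurrence`.
#' @export
compute_occurrence <- function(presence, members) {
  if (length(members) == 0) {
    abort("no resolved taxa in sample")
  }
  sub <- presence[match(members, presence$taxon), , drop = FALSE]
  if (anyNA(sub$taxon)) {
    abort("members absent from presence matrix")
  }
  fn <- setdiff(names(presence), "taxon")
  tibble(function_name = fn,
         occurrence = map_dbl(fn, ~ sum(sub[[.x]]) / length(members)))
}

#' Abundance-weighted fraction of each function in a sample
#'
#' The relative abundance of a function is the summed abundance of the
#' member taxa possessing it divided by the summed abundance of all
#' member taxa in the sample.
#'
#' @inheritParams compute_occurrence
#' @param abundances Abundance tibble from [read_abundances()].
#' @param sample Sample column name.
#' @param members Optional member set; defaults to the presence rows
#'   with positive abundance in the sample.
#' @return A tibble `function_name`, `relative_abundance`.
#' @export
compute_relative_abundance <- function(presence, abundances, sample,
                                       members = NULL) {
  if (!sample %in% names(abundances)) {
    abort(sprintf("unknown sample: %s", sample))
  }
  ab <- stats::setNames(abundances[[sample]], abundances$observation_name)
  if (is.null(members)) {
    members <- intersect(presence$taxon,
                         names(ab)[ab > 0])
  }
  if (length(members) == 0) {
    abort(sprintf("no resolved taxa in sample %s", sample))
  }
  denom <- sum(ab[members])
  if (!(denom > 0)) {
    abort(sprintf("zero total abundance for sample %s", sample))
  }
  sub <- presence[match(members, presence$taxon), , drop = FALSE]
  fn <- setdiff(names(presence), "taxon")
  tibble(function_name = fn,
         relative_abundance =
           map_dbl(fn, ~ sum(ab[members][sub[[.x]]]) / denom))
}

#' Per-sample community function profiles
#'
#' Aggregates a per-observation function-presence matrix into
#' per-sample profiles.  Sample membership is the set of resolved
#' observations with strictly positive abundance in the sample;
#' unresolved observations enter neither numerator nor denominator of
#' the fractions and are reported separately through
#' `resolved_fraction` (abundance-weighted when abundances are given).
#' Without an abundance table a single pseudo-sample `"community"` is
#' emitted with occurrences only.
#'
#' @param presence Wide presence tibble from [call_functions()], one row
#'   per resolved observation.
#' @param resolutions Resolution tibble from [resolve_affiliations()].
#' @param abundances Optional abundance tibble from [read_abundances()];
#'   every observation it names must appear in `resolutions`.
#' @param rules Optional rule tibble; when given, function cycles are
#'   attached to the profile.
#' @return A `community_profile` object; see [tidy.community_profile()]
#'   and [glance.community_profile()].
#' @export
profile_community <- function(presence, resolutions, abundances = NULL,
                              rules = NULL) {
  resolved <- resolutions$observation_id[resolutions$status == "resolved"]
  fn <- setdiff(names(presence), "taxon")
  missing_rows <- setdiff(resolved, presence$taxon)
  if (length(missing_rows) > 0) {
    abort(sprintf("resolved observation missing from presence matrix: %s",
                  missing_rows[1]))
  }

  if (is.null(abundances)) {
    occ <- compute_occurrence(presence, resolved)
    profile <- occ |>
      mutate(sample = "community", .before = 1) |>
      mutate(relative_abundance = NA_real_)
    resolution <- tibble(
      sample = "community",
      n_observations = nrow(resolutions),
      n_members = length(resolved),
      resolved_fraction = length(resolved) / nrow(resolutions))
  } else {
    unknown <- setdiff(abundances$observation_name,
                       resolutions$observation_id)
    if (length(unknown) > 0) {
      abort(sprintf(
        "abundance table references unknown observation id(s): %s",
        paste(unknown, collapse = ", ")))
    }
    samples <- setdiff(names(abundances), "observation_name")
    per_sample <- map(samples, function(s) {
      ab <- stats::setNames(abundances[[s]], abundances$observation_name)
      pos <- names(ab)[ab > 0]
      members <- intersect(resolved, pos)
      if (length(members) == 0) {
        abort(sprintf("no resolved taxa in sample %s", s))
      }
      occ <- compute_occurrence(presence, members)
      rel <- compute_relative_abundance(presence, abundances, s, members)
      prof <- left_join(occ, rel, by = "function_name") |>
        mutate(sample = s, .before = 1)
      res <- tibble(
        sample = s,
        n_observations = length(pos),
        n_members = length(members),
        resolved_fraction = sum(ab[members]) / sum(ab[pos]))
      list(prof = prof, res = res)
    })
    profile <- bind_rows(map(per_sample, "prof"))
    resolution <- bind_rows(map(per_sample, "res"))
  }

  if (!is.null(rules)) {
    profile <- left_join(profile,
                         rules[, c("function_name", "cycle")],
                         by = "function_name")
  }
  structure(list(profile = as_tibble(profile),
                 resolution = resolution,
                 functions = fn,
                 has_abundance = !is.null(abundances)),
            class = "community_profile")
}

#' @export
print.community_profile <- function(x, ...) {
  cat(sprintf(
    "<community_profile> %d function(s) x %d sample(s)%s\n",
    length(x$functions), nrow(x$resolution),
    if (x$has_abundance) ", abundance-weighted" else ""))
  print(x$profile, n = 6)
  invisible(x)
}

#' Tidy a community profile into a long tibble
#'
#' @param x A `community_profile`.
#' @param ... Unused.
#' @return Long tibble: `sample`, `function_name`, `occurrence`,
#'   `relative_abundance` (NA without abundance input), and `cycle`
#'   when rules were attached.
#' @export
tidy.community_profile <- function(x, ...) {
  x$profile
}

#' One-row-per-sample summary of a community profile
#'
#' @inheritParams tidy.community_profile
#' @return Tibble: `sample`, `n_observations`, `n_members`,
#'   `resolved_fraction`.
#' @export
glance.community_profile <- function(x, ...) {
  x$resolution
}

#' Wide function-by-sample table of a profile
#'
#' @param profile A `community_profile`.
#' @param mode `"occurrence"` or `"abundance"`.
#' @return Wide tibble, first column `function_name`, one column per
#'   sample.
#' @export
profile_matrix <- function(profile, mode = c("occurrence", "abundance")) {
  mode <- match.arg(mode)
  value <- if (mode == "occurrence") "occurrence" else "relative_abundance"
  if (mode == "abundance" && !profile$has_abundance) {
    abort("profile has no abundance values")
  }
  tidy(profile) |>
    select("function_name", "sample", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "sample",
                       values_from = dplyr::all_of(value))
}

#' Write profile tables (occurrence, abundance, resolution report)
#'
#' @param profile A `community_profile`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_profile_tables <- function(profile, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "function_occurrence.tsv")
  write_tsv_file(profile_matrix(profile, "occurrence"), paths[1])
  if (profile$has_abundance) {
    p <- file.path(dir, "function_abundance.tsv")
    write_tsv_file(profile_matrix(profile, "abundance"), p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "resolution_report.tsv")
  write_tsv_file(glance(profile), p)
  invisible(c(paths, p))
}
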