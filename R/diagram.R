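# Biogeochemical cycle diagrams: compound-transformation graphs whose
# edges are coarse-grained metabolic functions.  A template pairs an
# SVG body containing per-edge placeholder anchors
# ("{{<anchor_id>.label}}" / "{{<anchor_id>.class}}") with a TSV edge
# map relating each function to its anchor, substrate and product.

#' Load a cycle-diagram template
#'
#' With only `cycle`, loads the packaged carbon, nitrogen or sulfur
#' template.  A custom template is a pair `<prefix>.svg` +
#' `<prefix>_edges.tsv`, the edge map having columns `function_name`,
#' `anchor_id`, `substrate`, `product`.
#'
#' @param cycle `"carbon"`, `"nitrogen"` or `"sulfur"` (ignored when
#'   `prefix` is given).
#' @param prefix Optional path prefix of a custom template.
#' @param rules Optional rule tibble; when given, every edge function
#'   must exist in it.
#' @return A `cycle_diagram`: list with `cycle`, `svg` (single string),
#'   `edges` (tibble), `nodes` (character).
#' @export
read_cycle_template <- function(cycle = c("carbon", "nitrogen", "sulfur"),
                                prefix = NULL, rules = NULL) {
  if (is.null(prefix)) {
    cycle <- match.arg(cycle)
    prefix <- file.path(system.file("extdata", "templates",
                                    package = "taxcycle", mustWork = TRUE),
                        cycle)
  } else {
    cycle <- basename(prefix)
  }
  svg_path <- paste0(prefix, ".svg")
  map_path <- paste0(prefix, "_edges.tsv")
  if (!file.exists(svg_path)) abort(sprintf("template SVG not found: %s",
                                            svg_path))
  svg <- paste(readLines(svg_path), collapse = "\n")
  edges <- read_tsv_quiet(map_path, col_types = readr::cols(.default = "c"))
  needed <- c("function_name", "anchor_id", "substrate", "product")
  if (!all(needed %in% names(edges))) {
    abort("edge map must have columns function_name, anchor_id, substrate, product")
  }
  missing <- edges$anchor_id[
    !map_lgl(edges$anchor_id,
             ~ grepl(paste0("{{", .x, ".label}}"), svg, fixed = TRUE))]
  if (length(missing) > 0) {
    bad <- edges$function_name[edges$anchor_id == missing[1]][1]
    abort(sprintf("anchor %s (function %s) absent from template SVG",
                  missing[1], bad))
  }
  if (!is.null(rules)) {
    unknown <- setdiff(edges$function_name, rules$function_name)
    if (length(unknown) > 0) {
      abort(sprintf("edge function not in rule set: %s", unknown[1]))
    }
  }
  structure(list(cycle = cycle, svg = svg, edges = as_tibble(edges),
                 nodes = unique(c(edges$substrate, edges$product))),
            class = "cycle_diagram")
}

#' @export
print.cycle_diagram <- function(x, ...) {
  cat(sprintf("<cycle_diagram> %s: %d node(s), %d edge(s)\n",
              x$cycle, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Project a sample's profile onto a cycle diagram
#'
#' Each diagram edge is weighted by the sample's occurrence or relative
#' abundance of its function; diagram edges whose function is absent
#' from the profile are weighted 0, and profile functions absent from
#' the diagram are ignored.
#'
#' @param profile A `community_profile` from [profile_community()].
#' @param diagram A `cycle_diagram` from [read_cycle_template()].
#' @param mode `"occurrence"` or `"abundance"` (abundance requires an
#'   abundance-weighted profile).
#' @param sample Sample id present in the profile.
#' @return A `projected_diagram`: the diagram plus per-edge `weight`
#'   in `[0, 1]`, the mode and the sample id.
#' @export
project_profile <- function(profile, diagram,
                            mode = c("abundance", "occurrence"),
                            sample = NULL) {
  mode <- match.arg(mode)
  long <- tidy(profile)
  samples <- unique(long$sample)
  sample <- sample %||% samples[1]
  if (!sample %in% samples) {
    abort(sprintf("unknown sample id: %s", sample))
  }
  if (mode == "abundance" && !profile$has_abundance) {
    abort("profile has no abundance values; use mode = \"occurrence\"")
  }
  value_col <- if (mode == "abundance") "relative_abundance" else "occurrence"
  vals <- long[long$sample == sample, , drop = FALSE]
  w <- vals[[value_col]][match(diagram$edges$function_name,
                               vals$function_name)]
  w[is.na(w)] <- 0
  out <- diagram
  out$edges$weight <- w
  out$mode <- mode
  out$sample <- sample
  class(out) <- c("projected_diagram", "cycle_diagram")
  out
}

#' Render a projected diagram to an SVG file
#'
#' Replaces each anchor's placeholder with the edge weight formatted as
#' a whole percentage (half-up rounding); zero-weight edges keep their
#' label but receive the `"weight zero"` styling class so absent
#' functions stay visibly absent.  Output bytes are a pure function of
#' the inputs.
#'
#' @param projected A `projected_diagram` from [project_profile()].
#' @param path Output SVG path.
#' @return Invisibly, `path`.
#' @export
render_diagram <- function(projected, path) {
  if (!inherits(projected, "projected_diagram")) {
    abort("render_diagram() expects a projected_diagram")
  }
  svg <- projected$svg
  for (i in seq_len(nrow(projected$edges))) {
    a <- projected$edges$anchor_id[i]
    w <- projected$edges$weight[i]
    svg <- gsub(paste0("{{", a, ".label}}"), format_percent(w), svg,
                fixed = TRUE)
    svg <- gsub(paste0("{{", a, ".class}}"),
                if (w > 0) "weight" else "weight zero", svg, fixed = TRUE)
  }
  ok <- tryCatch({
    con <- file(path, open = "wb")
    on.exit(close(con), add = TRUE)
    writeLines(svg, con, sep = "\n", useBytes = TRUE)
    TRUE
  }, error = function(e) {
    abort(sprintf("cannot write %s: %s", path, conditionMessage(e)))
  })
  invisible(path)
}

#' Restrict a profile to functions worth displaying
#'
#' A function is retained when its value reaches `min_display` in at
#' least one of the selected samples (the convention of the summary
#' polar plots: only functions with at least 10% relative abundance in
#' a sample are shown).  Retained functions keep their values in every
#' selected sample.
#'
#' @param profile A `community_profile`.
#' @param min_display Display threshold in `[0, 1]`; default 0.10.
#' @param samples Samples to consider (default all).
#' @param mode `"abundance"` (default when available) or `"occurrence"`.
#' @return Wide tibble `function_name` x samples, displayed functions
#'   only.
#' @export
polar_summary <- function(profile, min_display = 0.10, samples = NULL,
                          mode = NULL) {
  if (min_display < 0 || min_display > 1) {
    abort("min_display must be in [0, 1]")
  }
  mode <- mode %||% if (profile$has_abundance) "abundance" else "occurrence"
  wide <- profile_matrix(profile, mode)
  samples <- samples %||% setdiff(names(wide), "function_name")
  unknown <- setdiff(samples, names(wide))
  if (length(unknown) > 0) {
    abort(sprintf("unknown sample id: %s", unknown[1]))
  }
  vals <- as.matrix(wide[, samples, drop = FALSE])
  keep <- apply(vals, 1, function(r) any(r >= min_display))
  wide[keep, c("function_name", samples), drop = FALSE]
}

#' Full function-by-sample table backing the heatmap
#'
#' @inheritParams polar_summary
#' @return Wide tibble `function_name` x samples (all functions).
#' @export
heatmap_table <- function(profile, mode = NULL) {
  mode <- mode %||% if (profile$has_abundance) "abundance" else "occurrence"
  profile_matrix(profile, mode)
}
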