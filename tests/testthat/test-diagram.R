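make_demo_profile <- function(values_by_sample) {
  # values_by_sample: named list sample -> named numeric (function -> value)
  fns <- unique(unlist(lapply(values_by_sample, names)))
  prof <- dplyr::bind_rows(lapply(names(values_by_sample), function(s) {
    v <- values_by_sample[[s]]
    tibble::tibble(sample = s, function_name = fns,
                   occurrence = unname(v[fns]),
                   relative_abundance = unname(v[fns]))
  }))
  structure(list(profile = prof,
                 resolution = tibble::tibble(
                   sample = names(values_by_sample),
                   n_observations = 10L, n_members = 10L,
                   resolved_fraction = 1),
                 functions = fns, has_abundance = TRUE),
            class = "community_profile")
}

test_that("packaged templates load with their edge inventories", {
  rules <- read_rules()
  carbon <- read_cycle_template("carbon", rules = rules)
  expect_s3_class(carbon, "cycle_diagram")
  methano <- carbon$edges[carbon$edges$function_name == "methanogenesis", ]
  expect_equal(nrow(methano), 1)
  expect_equal(methano$substrate, "CO2")
  expect_equal(methano$product, "CH4")
  for (cy in c("nitrogen", "sulfur")) {
    dg <- read_cycle_template(cy, rules = rules)
    expect_true(all(dg$edges$function_name %in% rules$function_name))
  }
})

test_that("template validation flags unmapped anchors and empty maps", {
  d <- withr::local_tempdir()
  writeLines('<svg><text>{{known_w.label}}</text></svg>',
             file.path(d, "tpl.svg"))
  readr::write_tsv(tibble::tibble(
    function_name = c("known", "ghost"),
    anchor_id = c("known_w", "ghost_w"),
    substrate = "A", product = "B"),
    file.path(d, "tpl_edges.tsv"), progress = FALSE)
  expect_error(read_cycle_template(prefix = file.path(d, "tpl")),
               "ghost")

  # empty edge map: nodes only, no anchors to validate
  readr::write_tsv(tibble::tibble(function_name = character(0),
                                  anchor_id = character(0),
                                  substrate = character(0),
                                  product = character(0)),
                   file.path(d, "tpl_edges.tsv"), progress = FALSE)
  dg <- read_cycle_template(prefix = file.path(d, "tpl"))
  expect_equal(nrow(dg$edges), 0)
})

test_that("projection carries profile values onto edges", {
  prof <- make_demo_profile(list(
    SC02 = c(methanogenesis = 0.63, acetogenesis_wl = 0.2),
    SC03 = c(methanogenesis = 0.19, acetogenesis_wl = 0.4)))
  carbon <- read_cycle_template("carbon")
  proj <- project_profile(prof, carbon, mode = "abundance",
                          sample = "SC02")
  w <- proj$edges$weight
  expect_equal(w[proj$edges$function_name == "methanogenesis"], 0.63)
  # profile functions absent from the diagram are simply ignored
  expect_equal(w[proj$edges$function_name == "sulfur_oxidation"],
               numeric(0))
  # diagram edges without profile values weigh zero
  expect_equal(w[proj$edges$function_name == "hydrogen_oxidation"], 0)
  expect_equal(w[proj$edges$function_name == "fermentation"], 0)
  expect_true(all(w >= 0 & w <= 1))
  expect_error(project_profile(prof, carbon, sample = "nope"),
               "unknown sample")
})

test_that("rendering substitutes half-up rounded percent labels", {
  prof <- make_demo_profile(list(
    SC02 = c(methanogenesis = 0.63, acetogenesis_wl = 0.005)))
  carbon <- read_cycle_template("carbon")
  proj <- project_profile(prof, carbon, sample = "SC02")
  tf <- withr::local_tempfile(fileext = ".svg")
  render_diagram(proj, tf)
  svg <- paste(readLines(tf), collapse = "\n")
  expect_match(svg, ">63%<")
  expect_match(svg, ">1%<")       # 0.005 rounds half-up to 1%
  expect_match(svg, ">0%<")       # absent functions are visibly absent
  expect_match(svg, 'class="weight zero"')
  expect_false(grepl("{{", svg, fixed = TRUE))

  # stored weights remain unrounded
  expect_equal(proj$edges$weight[
    proj$edges$function_name == "acetogenesis_wl"], 0.005)

  # byte-determinism of re-rendering
  tf2 <- withr::local_tempfile(fileext = ".svg")
  render_diagram(proj, tf2)
  expect_identical(read_raw(tf), read_raw(tf2))
})

test_that("per-sample rendering produces distinct files", {
  prof <- make_demo_profile(list(A1 = c(methanogenesis = 0.1),
                                 D1 = c(methanogenesis = 0.9)))
  carbon <- read_cycle_template("carbon")
  d <- withr::local_tempdir()
  for (s in c("A1", "D1")) {
    render_diagram(project_profile(prof, carbon, sample = s),
                   file.path(d, sprintf("carbon_%s.svg", s)))
  }
  files <- list.files(d)
  expect_setequal(files, c("carbon_A1.svg", "carbon_D1.svg"))
  expect_false(identical(read_raw(file.path(d, files[1])),
                         read_raw(file.path(d, files[2]))))
})

test_that("display threshold keeps a function if any sample reaches it", {
  prof <- make_demo_profile(list(
    s1 = c(low_everywhere = 0.08, borderline = 0.12, big = 0.5),
    s2 = c(low_everywhere = 0.08, borderline = 0.02, big = 0.6)))
  kept <- polar_summary(prof, min_display = 0.10)
  expect_setequal(kept$function_name, c("borderline", "big"))
  # retained functions keep values in every column
  expect_equal(kept$s2[kept$function_name == "borderline"], 0.02)
  # threshold 0 is the identity on the function set
  all_kept <- polar_summary(prof, min_display = 0)
  expect_setequal(all_kept$function_name,
                  c("low_everywhere", "borderline", "big"))
  # restricting samples restricts the test set
  only_s2 <- polar_summary(prof, min_display = 0.10, samples = "s2")
  expect_setequal(only_s2$function_name, "big")
  expect_error(polar_summary(prof, min_display = 1.5), "0, 1")
})
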