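make_presence <- function(taxa, fns, mat) {
  out <- tibble::tibble(taxon = taxa)
  for (j in seq_along(fns)) out[[fns[j]]] <- mat[, j]
  out
}

test_that("occurrence is the member fraction possessing the function", {
  pres <- make_presence(paste0("t", 1:4), c("fA", "fB", "fC"),
                        cbind(c(TRUE, TRUE, TRUE, FALSE),
                              c(TRUE, TRUE, TRUE, TRUE),
                              c(FALSE, FALSE, FALSE, FALSE)))
  occ <- compute_occurrence(pres, paste0("t", 1:4))
  expect_equal(occ$occurrence[occ$function_name == "fA"], 0.75)
  expect_equal(occ$occurrence[occ$function_name == "fB"], 1.0)
  expect_equal(occ$occurrence[occ$function_name == "fC"], 0.0)
  expect_error(compute_occurrence(pres, character(0)), "no resolved taxa")
})

test_that("relative abundance weights possessors by sample abundance", {
  pres <- make_presence(paste0("t", 1:4), c("fA", "fB"),
                        cbind(c(TRUE, FALSE, FALSE, TRUE),
                              c(TRUE, TRUE, TRUE, TRUE)))
  ab <- tibble::tibble(observation_name = paste0("t", 1:4),
                       s1 = c(10, 20, 30, 40))
  rel <- compute_relative_abundance(pres, ab, "s1")
  expect_equal(rel$relative_abundance[rel$function_name == "fA"], 0.5)
  expect_equal(rel$relative_abundance[rel$function_name == "fB"], 1.0)
  expect_error(compute_relative_abundance(pres, ab, "nope"),
               "unknown sample")

  # uniform abundances reduce relative abundance to occurrence
  ab_u <- tibble::tibble(observation_name = paste0("t", 1:4), s1 = 7)
  rel_u <- compute_relative_abundance(pres, ab_u, "s1")
  occ <- compute_occurrence(pres, paste0("t", 1:4))
  expect_equal(rel_u$relative_abundance, occ$occurrence)
})

test_that("profiles without abundances collapse to one pseudo-sample", {
  pres <- make_presence(paste0("t", 1:3), "fA", cbind(c(TRUE, TRUE, FALSE)))
  res <- tibble::tibble(
    observation_id = c(paste0("t", 1:3), "t4"),
    status = c("resolved", "resolved", "resolved", "unresolved"),
    matched_taxon = c(paste0("t", 1:3), NA),
    matched_rank = c(rep("genus", 3), NA), proteome_count = NA_integer_)
  pr <- profile_community(pres, res)
  td <- tidy(pr)
  expect_equal(unique(td$sample), "community")
  expect_equal(td$occurrence[td$function_name == "fA"], 2 / 3)
  expect_true(all(is.na(td$relative_abundance)))
  expect_equal(glance(pr)$resolved_fraction, 3 / 4)
})

test_that("unresolved observations count only in the resolved fraction", {
  pres <- make_presence(c("t1", "t2"), "fA", cbind(c(TRUE, FALSE)))
  res <- tibble::tibble(
    observation_id = c("t1", "t2", "u1"),
    status = c("resolved", "resolved", "unresolved"),
    matched_taxon = c("t1", "t2", NA),
    matched_rank = c("genus", "genus", NA), proteome_count = NA_integer_)
  ab <- tibble::tibble(observation_name = c("t1", "t2", "u1"),
                       s1 = c(60, 40, 50))
  pr <- profile_community(pres, res, ab)
  # abundance-weighted resolved fraction: 100 of 150
  expect_equal(glance(pr)$resolved_fraction, 100 / 150)
  # occurrence and abundance exclude the unresolved observation entirely
  td <- tidy(pr)
  expect_equal(td$occurrence, 0.5)
  expect_equal(td$relative_abundance, 0.6)
})

test_that("sample membership requires strictly positive abundance", {
  pres <- make_presence(paste0("t", 1:3), "fA",
                        cbind(c(TRUE, FALSE, TRUE)))
  res <- tibble::tibble(
    observation_id = paste0("t", 1:3), status = "resolved",
    matched_taxon = paste0("t", 1:3), matched_rank = "genus",
    proteome_count = 9L)
  ab <- tibble::tibble(observation_name = paste0("t", 1:3),
                       s1 = c(5, 5, 0), s2 = c(0, 0, 12))
  pr <- profile_community(pres, res, ab)
  td <- tidy(pr)
  expect_equal(td$occurrence[td$sample == "s1"], 0.5)
  expect_equal(td$occurrence[td$sample == "s2"], 1.0)
  expect_equal(glance(pr)$n_members, c(2L, 1L))

  bad <- tibble::tibble(observation_name = c("t1", "zz"), s1 = c(1, 1))
  expect_error(profile_community(pres, res, bad), "zz")
})

test_that("profile fractions are normalized, additive and scale-free", {
  set.seed(601)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    taxa <- paste0("t", seq_len(n))
    # partition: each taxon possesses exactly one of three functions
    assign3 <- sample(1:3, n, replace = TRUE)
    pres <- make_presence(taxa, c("f1", "f2", "f3"),
                          cbind(assign3 == 1, assign3 == 2, assign3 == 3))
    res <- tibble::tibble(observation_id = taxa, status = "resolved",
                          matched_taxon = taxa, matched_rank = "genus",
                          proteome_count = 9L)
    ab <- tibble::tibble(observation_name = taxa,
                         s1 = sample(1:50, n, replace = TRUE))
    pr <- tidy(profile_community(pres, res, ab))
    expect_true(all(pr$occurrence >= 0 & pr$occurrence <= 1))
    expect_true(all(pr$relative_abundance >= 0 &
                      pr$relative_abundance <= 1))
    expect_equal(sum(pr$occurrence), 1)
    expect_equal(sum(pr$relative_abundance), 1)

    # scaling one sample's abundances changes nothing
    ab2 <- ab
    ab2$s1 <- ab2$s1 * 37.5
    pr2 <- tidy(profile_community(pres, res, ab2))
    expect_equal(pr2$relative_abundance, pr$relative_abundance)
  }
})
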