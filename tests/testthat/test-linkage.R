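test_that("normalization strips, case-folds and derives keys", {
  r <- toy_roster(codes = c(" 01234 ", ""),
                  ids = c(NA, "77"),
                  names = c("Ali", "Ali"),
                  surnames = c("Shokri", "Shokri"))
  n <- normalize_roster(r)
  expect_identical(n$key_code, c("01234", NA)) # leading zeros kept
  expect_identical(n$key_name[1], paste("ali", "shokri", sep = "\x1f"))
  expect_false(any(n$unlinkable))

  bare <- normalize_roster(toy_roster(codes = "", ids = "",
                                      names = "", surnames = ""))
  expect_true(bare$unlinkable)
})

test_that("within-source dedup collapses by the key cascade", {
  r <- toy_roster(codes = c("X", "X"))
  r$age <- c(40, 55)
  d <- dedup_within(r)
  expect_identical(nrow(d), 1L)
  expect_identical(d$age, 40) # first-seen row kept
  expect_identical(attr(d, "n_merged"), 1L)

  # distinct code beats shared lower-tier keys; code-less rows collapse by id
  r2 <- toy_roster(codes = c("X", "", ""), ids = c(NA, "Y", "Y"))
  expect_identical(nrow(dedup_within(r2)), 2L)

  # identity on the empty roster
  empty <- toy_roster(character(0))
  expect_identical(nrow(dedup_within(empty)), 0L)
})

test_that("reference enrichment fills only unambiguous codes", {
  ref <- data.frame(
    council_code = c("Z", "W1", "W2"),
    national_id = c("Y", NA, NA),
    name = c("x", "dana", "dana"),
    surname = c("x", "k", "k"),
    stringsAsFactors = FALSE
  )
  r <- toy_roster(codes = c("", "", "K5"),
                  ids = c("Y", NA, NA),
                  names = c("a", "dana", "b"),
                  surnames = c("a", "k", "b"))
  out <- enrich_from_reference(r, ref)
  expect_identical(out$council_code[1], "z") # filled via national id
  expect_identical(out$council_code[2], "") # ambiguous name match
  expect_identical(out$council_code[3], "K5") # already coded: untouched
  expect_identical(attr(out, "enrich_log")$event, "ambiguous_reference")
})

test_that("tabulation counts the hand-enumerable toy overlap", {
  mk <- function(codes) toy_roster(codes)
  tab <- tabulate_rosters(mk(c("p1", "p2", "p3")),
                          mk(c("p2", "p3", "p4")),
                          mk("p3"))
  expect_equal(as.numeric(tab),
               c(1, 1, 0, 1, 0, 0, 1)) # n100,n010,n001,n110,n101,n011,n111
  expect_equal(n_obs(tab), 4)

  empty <- toy_roster(character(0))
  tab0 <- tabulate_rosters(empty, empty, empty)
  expect_equal(as.numeric(tab0), rep(0, 7))
})

test_that("zero-corruption linkage round-trips the sampled counts exactly", {
  truth <- build_truth(population_size = 3000, seed = 42)
  sim <- simulate_registry(truth, corruption_config(0, 0, 0, 0, seed = 7),
                           dir = withr::local_tempdir())
  tab <- tabulate_rosters(dedup_within(sim$rosters$A),
                          dedup_within(sim$rosters$B),
                          dedup_within(sim$rosters$C))
  truth_counts <- table(factor(sim$histories$pattern,
                               levels = recap3:::.PATTERNS_OBS))
  expect_equal(as.numeric(tab), as.numeric(truth_counts))
  expect_equal(linkage_accuracy(tab, sim$sidecar_path), 1.0)
})

test_that("linkage is order-invariant and respects roster-size bounds", {
  truth <- build_truth(population_size = 1200, seed = 8)
  sim <- simulate_registry(truth,
                           corruption_config(0.15, 0.1, 0.05, 0.1, seed = 21),
                           dir = withr::local_tempdir())
  rosters <- lapply(sim$rosters, dedup_within)
  tab <- suppressWarnings(
    tabulate_rosters(rosters$A, rosters$B, rosters$C))

  perm <- recap3:::with_seed(4, lapply(rosters, function(r) {
    r[sample.int(nrow(r)), , drop = FALSE]
  }))
  tab_perm <- suppressWarnings(
    tabulate_rosters(perm$A, perm$B, perm$C))
  expect_equal(as.numeric(tab_perm), as.numeric(tab))

  sizes <- vapply(rosters, nrow, integer(1))
  expect_lte(n_obs(tab), sum(sizes))
  expect_gte(n_obs(tab), max(sizes))
})

test_that("cross-tier conflicts keep code-distinct entities separate", {
  a <- toy_roster(codes = c("c1", "c2"), ids = c("Y", "Y"))
  b <- toy_roster(codes = "", ids = "Y")
  b$source <- "B"
  tab <- tabulate_rosters(a, b, toy_roster(character(0)))
  # the code-less B row is ambiguous between two A entities: it forms
  # its own entity rather than guessing, and the conflict is logged
  expect_equal(as.numeric(tab), c(2, 1, 0, 0, 0, 0, 0))
  expect_true("conflict" %in% attr(tab, "audit")$event)
})

test_that("records with no usable key are excluded with a warning", {
  a <- toy_roster(codes = c("c1", ""), ids = c(NA, ""),
                  names = c(NA, ""), surnames = c(NA, ""))
  expect_warning(
    tab <- tabulate_rosters(a, toy_roster(character(0)),
                            toy_roster(character(0))),
    "no usable key")
  expect_equal(n_obs(tab), 1)
  expect_identical(attr(tab, "n_unlinkable"), 1L)
})
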