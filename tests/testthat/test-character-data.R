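make_records <- function(...) {
  rows <- list(...)
  rec <- data.frame(family = vapply(rows, `[[`, character(1), "family"),
                    passerine = vapply(rows, `[[`, logical(1), "passerine"),
                    missing_reason = vapply(rows, `[[`, character(1), "missing_reason"),
                    stringsAsFactors = FALSE)
  for (ch in c("structure", "site", "attachment"))
    rec[[ch]] <- lapply(rows, `[[`, ch)
  rec
}

fam <- function(family, structure, site, attachment, passerine = FALSE,
                missing_reason = "none") {
  list(family = family, passerine = passerine, missing_reason = missing_reason,
       structure = structure, site = site, attachment = attachment)
}

test_that("the vocabularies carry the fixed state counts", {
  v <- nest_state_vocabulary()
  expect_length(v$structure, 7L)
  expect_length(v$site, 7L)
  expect_length(v$attachment, 4L)
  path <- withr::local_tempfile(fileext = ".json")
  write_nest_vocabulary(path)
  expect_identical(lapply(jsonlite::read_json(path), unlist)$attachment,
                   v$attachment)
})

test_that("character matrices round-trip through the CSV dialect", {
  m <- character_matrix(make_records(
    fam("Sittidae", c("cup", "secondary cavity"), "tree", "basal", TRUE),
    fam("Tytonidae", "secondary cavity", c("tree", "cliff/bank"), "basal"),
    fam("Cuculidae", character(0), character(0), character(0),
        missing_reason = "brood_parasite")), "effective")
  path <- withr::local_tempfile(fileext = ".csv")
  write_character_matrix(m, path)
  m2 <- read_character_matrix(path, "effective")
  expect_true(m == m2)
  expect_identical(state_sets(m2, "structure")$Sittidae,
                   c("cup", "secondary cavity"))

  empty <- character_matrix(make_records()[0, ], "all")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_character_matrix(empty, p2)
  expect_identical(nrow(read_character_matrix(p2)$records), 0L)
})

test_that("matrix invariants are enforced", {
  expect_error(character_matrix(make_records(
    fam("A", "cup", "tree", "basal"), fam("A", "cup", "tree", "basal"))),
    class = "nestevo_duplicate_record")
  expect_error(character_matrix(make_records(
    fam("A", "igloo", "tree", "basal"))), class = "nestevo_vocabulary_error")
  # a brood parasite must not carry states
  expect_error(character_matrix(make_records(
    fam("A", "cup", "tree", "basal", missing_reason = "brood_parasite"))),
    class = "nestevo_vocabulary_error")
  # a characterizable family needs a state for every character
  expect_error(character_matrix(make_records(
    fam("A", "cup", character(0), "basal"))),
    class = "nestevo_invariant_error")
})

test_that("the effective-state rule is strictly 'more than 10%'", {
  sp50 <- function(n_cup) data.frame(
    species = sprintf("sp%02d", 1:50),
    genus = rep(sprintf("g%d", 1:5), each = 10),
    states = c(rep("cup", n_cup), rep("scrape", 50 - n_cup)),
    stringsAsFactors = FALSE)
  expect_setequal(derive_effective_states(sp50(6)), c("scrape", "cup"))   # 12%
  expect_identical(derive_effective_states(sp50(5)), "scrape")            # exactly 10%
  uni <- data.frame(species = sprintf("sp%d", 1:40), genus = "g1",
                    states = "scrape", stringsAsFactors = FALSE)
  expect_identical(derive_effective_states(uni), "scrape")
  expect_warning(out <- derive_effective_states(uni[0, ]), "no species")
  expect_length(out, 0L)
})

test_that("down-sampling large families is genus-stratified, seeded and order-invariant", {
  set.seed(9)
  big <- data.frame(
    species = sprintf("sp%03d", 1:200),
    genus = sample(sprintf("g%d", 1:12), 200, replace = TRUE),
    stringsAsFactors = FALSE)
  big$states <- ifelse(seq_len(200) %% 4 == 0, "cup", "platform")
  a <- derive_effective_states(big, seed = 5)
  b <- derive_effective_states(big[sample.int(200), ], seed = 5)
  expect_identical(a, b)
  # effective set is a subset of all observed states
  expect_true(all(a %in% unlist(big$states)))
})

test_that("binary recoding follows the later-derived-state rule", {
  m <- character_matrix(make_records(
    fam("Struthionidae", "scrape", "ground", "basal"),
    fam("Mixed", c("scrape", "platform"), c("ground", "tree"), "basal"),
    fam("Paridae", "cup", "tree", "basal", TRUE),
    fam("Cuculidae", character(0), character(0), character(0),
        missing_reason = "brood_parasite")), "effective")
  r <- binary_recode(m, "structure", "scrape", "non-scrape", "scrape")
  expect_identical(unname(r[c("Struthionidae", "Mixed", "Paridae")]),
                   c("scrape", "non-scrape", "non-scrape"))
  expect_true(is.na(r[["Cuculidae"]]))
  # total on non-missing families
  expect_identical(sum(is.na(r)), 1L)
  expect_error(binary_recode(m, "structure", character(0), "x", "y"),
               class = "nestevo_invalid_parameter")
  expect_error(binary_recode(m, "structure", "igloo", "x", "y"),
               class = "nestevo_vocabulary_error")
})

test_that("state frequencies separate exclusive and inclusive use", {
  rows <- c(lapply(1:8, function(i) fam(sprintf("B%d", i), "cup", "tree", "basal")),
            list(fam("Mix", "cup", "tree", c("basal", "pensile")),
                 fam("Lat", "cup", "tree", "lateral")))
  m <- character_matrix(do.call(make_records, rows), "effective")
  f <- state_frequencies(m, "attachment")
  basal <- f[f$state == "basal", ]
  expect_equal(basal$p_exclusive, 0.8)
  expect_equal(basal$p_inclusive, 0.9)
  expect_true(all(f$p_exclusive <= f$p_inclusive))
  expect_lte(sum(f$p_exclusive), 1)
  expect_gte(sum(f$p_inclusive), 1)

  allmiss <- character_matrix(make_records(
    fam("A", character(0), character(0), character(0),
        missing_reason = "no_data")), "all")
  expect_warning(ef <- state_frequencies(allmiss, "site"), "no family")
  expect_identical(nrow(ef), 0L)
})
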