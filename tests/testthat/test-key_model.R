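# Key parsing, structure validation, traversal, serialization.

test_that("the packaged key parses to 37 couplets and 38 species leaves", {
  key <- wickerhamomyces_key()
  expect_equal(length(key$couplets), 37L)
  expect_equal(length(key_species(key)), 38L)
  expect_equal(key$root, 1L)
  # tree arithmetic: leaves = couplets + 1
  met <- key_metrics(key)
  expect_equal(met$leaf_count, met$couplet_count + 1L)
  # transcription QC: lead a asserts the positive outcome in every couplet
  for (cp in key$couplets) {
    a <- Filter(function(l) l$label == "a", cp$leads)[[1]]
    expect_equal(a$outcome, "positive")
  }
})

test_that("structural invariants are enforced at parse time", {
  k1 <- toy_key_1()
  expect_equal(length(k1$couplets), 1L)
  expect_setequal(key_species(k1), c("SpX", "SpY"))

  # couplet 2 referenced from both leads of couplet 1
  bad <- '{
    "couplets": [
      {"number": 1, "leads": [
        {"label": "a", "character": "c1", "outcome": "positive", "target": {"couplet": 2}},
        {"label": "b", "character": "c1", "outcome": "negative", "target": {"couplet": 2}}
      ]},
      {"number": 2, "leads": [
        {"label": "a", "character": "c2", "outcome": "positive", "target": {"species": "SpX"}},
        {"label": "b", "character": "c2", "outcome": "negative", "target": {"species": "SpY"}}
      ]}
    ]}'
  expect_error(parse_key(bad), class = "dk_structure_error")

  # cycle: 1 -> 2 -> 1 leaves no root
  cyc <- '{
    "couplets": [
      {"number": 1, "leads": [
        {"label": "a", "character": "c1", "outcome": "positive", "target": {"couplet": 2}},
        {"label": "b", "character": "c1", "outcome": "negative", "target": {"species": "SpY"}}
      ]},
      {"number": 2, "leads": [
        {"label": "a", "character": "c2", "outcome": "positive", "target": {"couplet": 1}},
        {"label": "b", "character": "c2", "outcome": "negative", "target": {"species": "SpX"}}
      ]}
    ]}'
  expect_error(parse_key(cyc), class = "dk_structure_error")

  # leads must assert opposite outcomes of one character
  sch <- '{
    "couplets": [
      {"number": 1, "leads": [
        {"label": "a", "character": "c1", "outcome": "positive", "target": {"species": "SpX"}},
        {"label": "b", "character": "c2", "outcome": "negative", "target": {"species": "SpY"}}
      ]}
    ]}'
  expect_error(parse_key(sch), class = "dk_key_schema_error")
})

test_that("validate_structure flags exactly the couplet-26 annotation slip", {
  key <- wickerhamomyces_key()
  rep <- validate_structure(key)
  expect_length(rep$violations, 0L)
  expect_equal(nrow(rep$annotation_discrepancies), 1L)
  expect_equal(rep$annotation_discrepancies$couplet, 26L)
  expect_equal(rep$annotation_discrepancies$printed, 24L)
  expect_equal(rep$annotation_discrepancies$actual, 25L)
  # a toy key with correct annotations reports nothing
  expect_equal(nrow(validate_structure(toy_key_1())$annotation_discrepancies), 0L)
})

test_that("identification walks the printed key as hand-traced", {
  key <- wickerhamomyces_key()

  res <- identify_specimen(key, wickerhamomyces_profile("lannaensis"))
  expect_equal(res$status, "identified")
  expect_equal(res$species, "W. lannaensis")
  expect_equal(res$path$couplet, c(1L, 7L, 19L, 21L, 23L, 27L, 28L, 29L, 36L, 37L))
  expect_equal(res$path$lead, c("b", "b", "b", "b", "b", "b", "a", "b", "b", "b"))

  res <- identify_specimen(key, wickerhamomyces_profile("nanensis"))
  expect_equal(res$status, "identified")
  expect_equal(res$species, "W. nanensis")
  expect_equal(res$path$couplet, c(1L, 7L, 19L, 21L, 23L, 24L, 25L, 26L))
  expect_equal(res$path$lead, c("b", "b", "b", "b", "a", "b", "b", "a"))

  # missing melibiose outcome stalls at the first couplet
  prof <- wickerhamomyces_profile("lannaensis")
  prof$outcomes <- prof$outcomes[names(prof$outcomes) != "Mlb"]
  res <- identify_specimen(key, prof)
  expect_equal(res$status, "stalled")
  expect_equal(res$stalled_at, 1L)

  # a variable observation forks: frontier reported as ambiguous
  prof2 <- wickerhamomyces_profile("lannaensis")
  prof2$outcomes[["Mlb"]] <- "v"
  res <- identify_specimen(key, prof2)
  expect_equal(res$status, "ambiguous")
  expect_true("W. lannaensis" %in% res$species)
  expect_gt(length(res$species), 1L)
})

test_that("reachable_leaves expands uncertainty exhaustively", {
  key <- wickerhamomyces_key()
  m <- wickerhamomyces_matrix()
  # a row of pure no-data reaches every leaf
  expect_length(reachable_leaves(key, c(Mlb = "n")), 38L)
  # the all-definite row of the new species pins down a single leaf
  expect_equal(reachable_leaves(key, matrix_row(m, "W. nanensis")), "W. nanensis")
  expect_equal(reachable_leaves(key, matrix_row(m, "W. lannaensis")), "W. lannaensis")
  # toy: definite distinct rows give singletons
  toy <- toy_matrix(list(SpX = "+", SpY = "-"))
  k1 <- toy_key_1()
  expect_equal(reachable_leaves(k1, matrix_row(toy, "SpX")), "SpX")
})

test_that("adding information never enlarges the reachable set (monotonicity)", {
  key <- wickerhamomyces_key()
  m <- wickerhamomyces_matrix()
  set.seed(42)
  for (rep in 1:20) {
    sp <- sample(m$species, 1)
    row <- matrix_row(m, sp)
    # blank out a random subset of characters, then restore one at a time
    hide <- sample(names(row), sample(3:10, 1))
    blanked <- row
    blanked[hide] <- "n"
    before <- reachable_leaves(key, blanked)
    for (code in hide) {
      blanked[code] <- row[code]
      after <- reachable_leaves(key, blanked)
      expect_true(all(after %in% before),
                  label = sprintf("%s restoring %s", sp, code))
      before <- after
    }
  }
})

test_that("keys serialize and reparse structurally unchanged", {
  key <- wickerhamomyces_key()
  f <- tempfile(fileext = ".json")
  serialize_key(key, f)
  key2 <- parse_key(f)
  expect_equal(length(key2$couplets), length(key$couplets))
  expect_equal(key2$root, key$root)
  for (n in names(key$couplets)) {
    expect_identical(key2$couplets[[n]], key$couplets[[n]])
  }
  # parent annotations survive verbatim (incl. the erroneous one at 26)
  expect_equal(key2$couplets[["26"]]$parent_annotation, 24L)
  # toy round-trip
  k1 <- toy_key_1()
  expect_identical(parse_key(serialize_key(k1))$couplets, k1$couplets)
})
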