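# State-token grammar, supports algebra, matrix parsing, distinguishability.

test_that("token grammar parses atoms, alternations, and dash variants", {
  expect_equal(parse_state_token("+")$atoms, "positive")
  expect_equal(parse_state_token("n")$atoms, "no-data")
  expect_setequal(parse_state_token("w/+")$atoms, c("weak", "positive"))
  expect_setequal(parse_state_token("+,‒")$atoms, c("positive", "negative"))

  # hyphen-minus, en dash, figure dash all mean negative
  dashes <- c("-", "–", "‒")
  atoms <- lapply(dashes, function(d) parse_state_token(d)$atoms)
  expect_true(all(vapply(atoms, identical, logical(1), "negative")))

  expect_error(parse_state_token("x"), class = "dk_unknown_token_error")
  expect_error(parse_state_token("  "), class = "dk_unknown_token_error")
  expect_error(parse_state_token("n/+"), class = "dk_unknown_token_error")
})

test_that("canonical serialization orders atoms and round-trips", {
  expect_equal(canonical_token("w/+"), "+/w")
  expect_equal(canonical_token("+,‒"), "+/-")
  expect_equal(canonical_token("n"), "n")
  # parse -> canonicalize -> parse is a fixed point for every fixture token
  m <- wickerhamomyces_matrix()
  for (tok in unique(as.character(m$tokens))) {
    expect_identical(canonical_token(canonical_token(tok)), tok)
  }
})

test_that("state_supports implements the polarity rules", {
  expect_true(state_supports("+", "positive"))
  expect_false(state_supports("+", "negative"))
  expect_true(state_supports("v", "positive"))
  expect_true(state_supports("v", "negative"))
  expect_true(state_supports("n", "positive"))
  expect_true(state_supports("n", "negative"))
  # weak/latent/slow count as positive by default
  for (tok in c("w", "l", "s")) {
    expect_true(state_supports(tok, "positive"))
    expect_false(state_supports(tok, "negative"))
  }
  # strict mode lets weak (only) support both
  expect_true(state_supports("w", "negative", polarity = "strict"))
  expect_false(state_supports("l", "negative", polarity = "strict"))
  # an alternation supports an outcome if any atom does
  expect_true(state_supports("+/-", "negative"))
  expect_true(state_supports("+/-", "positive"))
  expect_false(state_supports("+/w", "negative"))
})

test_that("every state supports at least one outcome", {
  tokens <- c("+", "-", "w", "l", "s", "v", "n", "+/w", "+/-", "l/-", "w/s", "s/-")
  for (tok in tokens) for (pol in c("default", "strict")) {
    expect_true(state_supports(tok, "positive", pol) ||
                  state_supports(tok, "negative", pol),
                label = sprintf("token %s under %s polarity", tok, pol))
  }
})

test_that("the packaged genus matrix parses to 38 species x 22 characters", {
  m <- wickerhamomyces_matrix()
  expect_equal(dim(m), c(38L, 22L))
  expect_equal(length(unique(m$species)), 38L)
  expect_equal(nrow(m$vocabulary), 22L)
  expect_setequal(unique(m$vocabulary$kind),
                  c("assimilation", "growth-condition", "morphology"))
  # rows of the two newly described species match their descriptions
  lan <- matrix_row(m, "W. lannaensis")
  expect_true(state_supports(lan[["NO3"]], "positive"))   # nitrate positive
  expect_false(state_supports(lan[["g37C"]], "positive")) # no growth at 37 C
  expect_true(state_supports(lan[["g37C"]], "negative"))
  expect_equal(lan[["vitfree"]], "w")                     # weak vitamin-free growth
  nan <- matrix_row(m, "W. nanensis")
  expect_equal(nan[["Ga"]], "+")    # assimilates D-galactose
  expect_equal(nan[["Man"]], "+")   # assimilates D-mannitol
  expect_equal(nan[["NO3"]], "w")   # nitrate weak
  # each packaged profile is a valid resolution of its matrix row: whatever
  # outcome the (definite) profile supports, the row state supports too
  for (sp in c("lannaensis", "nanensis")) {
    prof <- wickerhamomyces_profile(sp)$outcomes
    row <- matrix_row(m, paste0("W. ", sp))
    for (code in names(prof)) for (oc in c("positive", "negative")) {
      if (state_supports(prof[[code]], oc) && !state_supports(prof[[code]], setdiff(c("positive", "negative"), oc))) {
        expect_true(state_supports(row[[code]], oc),
                    label = sprintf("%s %s supports %s", sp, code, oc))
      }
    }
  }
})

test_that("matrix TSV reader validates shape and cell tokens with coordinates", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("species\tc1", "SpA\t+", "SpB\t-"), f)
  m <- read_character_matrix(f)
  expect_equal(dim(m), c(2L, 1L))

  writeLines(c("species\tc1\tc2", "SpA\t+\t-", "SpB\t-"), f)
  expect_error(read_character_matrix(f), class = "dk_matrix_shape_error")

  writeLines(c("species\tc1", "SpA\tq"), f)
  err <- tryCatch(read_character_matrix(f), error = function(e) e)
  expect_s3_class(err, "dk_unknown_token_error")
  expect_match(conditionMessage(err), "SpA")
  expect_match(conditionMessage(err), "c1")
})

test_that("matrix writer round-trips bit-exactly", {
  m <- wickerhamomyces_matrix()
  f <- tempfile(fileext = ".tsv")
  write_character_matrix(m, f)
  m2 <- read_character_matrix(f, vocabulary = m$vocabulary)
  expect_identical(m$tokens, m2$tokens)
  expect_identical(m$species, m2$species)
  # and the written file matches the packaged fixture body line for line
  fixture <- readLines(dichokey_fixture("matrix"), encoding = "UTF-8")
  fixture <- fixture[!grepl("^#", fixture)]
  expect_identical(readLines(f), fixture)
})

test_that("distinguishing characters require disjoint supported outcomes", {
  m <- wickerhamomyces_matrix()
  d <- distinguishing_characters(m, "W. lannaensis", "W. nanensis")
  # verified against an independent per-cell comparison of support sets
  ref <- Filter(function(code) {
    a <- matrix_row(m, "W. lannaensis")[[code]]
    b <- matrix_row(m, "W. nanensis")[[code]]
    sup <- function(t) c(state_supports(t, "positive"), state_supports(t, "negative"))
    !any(sup(a) & sup(b))
  }, m$characters)
  expect_setequal(d, ref)
  expect_true(all(c("DXy", "Rh", "DGlu", "Ga", "Cit") %in% d))
  expect_false("Cel" %in% d)
  expect_false("Mlb" %in% d)
  # "+" vs "w" share the positive outcome, so NO3 cannot distinguish
  expect_false("NO3" %in% d)

  expect_equal(distinguishing_characters(m, "W. alni", "W. alni"), character(0))
  toy <- toy_matrix(list(SpA = "v", SpB = "+"))
  expect_equal(distinguishing_characters(toy, "SpA", "SpB"), character(0))
  expect_error(distinguishing_characters(m, "W. alni", "W. atlantis"),
               class = "dk_unknown_species_error")
})
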