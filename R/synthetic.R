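# Seeded synthetic data: matrices with a controlled state-token mix,
# specimens drawn from matrix rows by resolving uncertain states, and
# occurrence tables. Everything is a pure function of its seed: each
# generator calls set.seed() with the seed it was handed, so a given
# (spec, seed) pair always reproduces the identical artifact.

DK_STATE_CATEGORIES <- c("definite-positive", "definite-negative", "weak",
                         "variable", "latent", "slow", "no-data", "alternation")

#' Empirical state-token mix of the packaged genus matrix
#'
#' Classifies every cell of the packaged character matrix into the eight
#' token categories and returns their relative frequencies. Used as the
#' default `state_mix` so synthetic matrices resemble real assimilation data.
#'
#' @return Named numeric vector over the eight categories, summing to 1.
#' @export
fixture_state_mix <- function() {
  m <- wickerhamomyces_matrix()
  toks <- as.character(m$tokens)
  cat <- ifelse(grepl("/", toks, fixed = TRUE), "alternation",
         ifelse(toks == "+", "definite-positive",
         ifelse(toks == "-", "definite-negative",
         ifelse(toks == "w", "weak",
         ifelse(toks == "v", "variable",
         ifelse(toks == "l", "latent",
         ifelse(toks == "s", "slow", "no-data")))))))
  p <- table(factor(cat, levels = DK_STATE_CATEGORIES))
  out <- as.numeric(p) / length(toks)
  stats::setNames(out, DK_STATE_CATEGORIES)
}

#' Specification for a synthetic character matrix
#'
#' @param n_species,n_characters Matrix dimensions.
#' @param state_mix Named probabilities over the eight token categories
#'   (default: the empirical mix of the packaged matrix, see
#'   [fixture_state_mix()]). Probabilities must sum to 1.
#' @param guarantee_distinguishable If `TRUE`, every species pair must share
#'   at least one distinguishing character; enforced by row repair with a
#'   capped retry budget.
#' @param seed Integer RNG seed.
#' @return A `matrix_spec` list.
#' @export
matrix_spec <- function(n_species, n_characters, state_mix = NULL,
                        guarantee_distinguishable = TRUE, seed = 1L) {
  if (is.null(state_mix)) state_mix <- fixture_state_mix()
  stopifnot(setequal(names(state_mix), DK_STATE_CATEGORIES),
            abs(sum(state_mix) - 1) < 1e-8, all(state_mix >= 0))
  if (guarantee_distinguishable && n_characters < ceiling(log2(n_species))) {
    dk_stop("dk_infeasible_spec_error",
            sprintf("%d characters cannot distinguish %d species (< log2)",
                    n_characters, n_species))
  }
  structure(list(n_species = as.integer(n_species),
                 n_characters = as.integer(n_characters),
                 state_mix = state_mix[DK_STATE_CATEGORIES],
                 guarantee_distinguishable = isTRUE(guarantee_distinguishable),
                 seed = as.integer(seed)),
            class = "matrix_spec")
}

dk_sample_token <- function(category) {
  switch(category,
         "definite-positive" = "+",
         "definite-negative" = "-",
         "weak" = "w", "variable" = "v", "latent" = "l", "slow" = "s",
         "no-data" = "n",
         "alternation" = {
           atoms <- sample(c("+", "w", "l", "s", "-"), 2L)
           canonical_token(paste(atoms, collapse = "/"))
         })
}

#' Generate a synthetic character matrix
#'
#' Cells are drawn i.i.d. from the spec's state mix. When pairwise
#' distinguishability is guaranteed, offending rows are resampled (repair) up
#' to 100 rounds before an infeasibility error: a mix dominated by states
#' that support both outcomes (variable, no-data) can make the guarantee
#' unattainable.
#'
#' @param spec A [matrix_spec()].
#' @return A `character_matrix`. The generating seed is kept in attribute
#'   `"seed"`.
#' @export
gen_matrix <- function(spec) {
  stopifnot(inherits(spec, "matrix_spec"))
  set.seed(spec$seed)
  draw_row <- function() {
    cats <- sample(DK_STATE_CATEGORIES, spec$n_characters, replace = TRUE,
                   prob = spec$state_mix)
    vapply(cats, dk_sample_token, character(1))
  }
  toks <- matrix(NA_character_, spec$n_species, spec$n_characters,
                 dimnames = list(sprintf("sp%02d", seq_len(spec$n_species)),
                                 sprintf("ch%02d", seq_len(spec$n_characters))))
  for (i in seq_len(spec$n_species)) toks[i, ] <- draw_row()
  m <- character_matrix(toks)
  if (spec$guarantee_distinguishable && spec$n_species > 1L) {
    for (round in seq_len(100L)) {
      bad <- NULL
      pairs <- utils::combn(m$species, 2L)
      for (k in seq_len(ncol(pairs))) {
        if (!length(distinguishing_characters(m, pairs[1, k], pairs[2, k]))) {
          bad <- pairs[, k]; break
        }
      }
      if (is.null(bad)) break
      if (round == 100L) {
        dk_stop("dk_infeasible_spec_error",
                sprintf("could not make all pairs distinguishable within 100 repair rounds (stuck on %s vs %s)",
                        bad[1], bad[2]),
                pair = bad)
      }
      toks <- m$tokens
      toks[bad[2], ] <- draw_row()
      m <- character_matrix(toks)
    }
  }
  attr(m, "seed") <- spec$seed
  m
}

#' Generate a specimen from a matrix row
#'
#' Resolves each uncertain state to one concrete observation: a variable
#' state becomes `+` or `-` uniformly at random, an alternation becomes one
#' of its atoms; no-data cells are left out of the profile; definite cells
#' (including weak/latent/slow) are copied as-is.
#'
#' @param matrix A `character_matrix`.
#' @param species Species name of the row to resolve.
#' @param resolution_seed Integer RNG seed.
#' @return A `specimen_profile`.
#' @export
gen_specimen <- function(matrix, species, resolution_seed = 1L) {
  dk_require_species(matrix, species)
  set.seed(resolution_seed)
  row <- matrix_row(matrix, species)
  out <- character(0)
  for (code in names(row)) {
    st <- parse_state_token(row[[code]])
    tok <- if (identical(st$atoms, "no-data")) {
      NA_character_
    } else if (identical(st$atoms, "variable")) {
      sample(c("+", "-"), 1L)
    } else if (length(st$atoms) > 1L) {
      tokens <- unname(DK_ATOM_TOKEN[st$atoms])
      # a variable atom inside an alternation also resolves to +/-
      tokens[tokens == "v"] <- sample(c("+", "-"), 1L)
      sample(tokens, 1L)
    } else {
      row[[code]]
    }
    if (!is.na(tok)) out[code] <- tok
  }
  specimen_profile(out, identifier = sprintf("%s::seed%d", species, resolution_seed),
                   vocabulary = matrix$vocabulary)
}

#' Generate a synthetic occurrence table (plus discovery years)
#'
#' Each species gets one country from the pool; with probability
#' `multi_country_rate` it gets one or two extra countries. Years are uniform
#' over `year_range`.
#'
#' @param n_species Number of species records.
#' @param country_pool Character vector of available country names.
#' @param multi_country_rate Probability a species is multi-country.
#' @param year_range Integer length-2 vector, inclusive.
#' @param seed Integer RNG seed.
#' @return List with `table` (an `occurrence_table`) and `years` (named
#'   integer vector).
#' @export
gen_occurrences <- function(n_species, country_pool, multi_country_rate = 0.2,
                            year_range = c(1891L, 2021L), seed = 1L) {
  stopifnot(length(country_pool) >= 1L, multi_country_rate >= 0,
            multi_country_rate <= 1, length(year_range) == 2L)
  set.seed(seed)
  species <- sprintf("synthsp%02d", seq_len(n_species))
  localities <- lapply(seq_len(n_species), function(i) {
    n_extra <- if (stats::runif(1) < multi_country_rate && length(country_pool) > 1L) {
      sample(1:min(2L, length(country_pool) - 1L), 1L)
    } else 0L
    sample(country_pool, 1L + n_extra)
  })
  years <- stats::setNames(
    sample(seq(year_range[1], year_range[2]), n_species, replace = TRUE),
    species)
  list(table = occurrence_table(species, localities,
                                sources = "synthetic", years = years),
       years = years)
}
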