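# Packaged fixtures: the genus-wide character matrix, its vocabulary, the
# printed species key, the global distribution table, the default
# place-to-continent mapping, and the two new-species specimen profiles.
# All are plain-text files under inst/extdata, addressable by name.

DK_FIXTURES <- c(
  matrix = "wickerhamomyces_matrix.tsv",
  vocabulary = "wickerhamomyces_characters.tsv",
  key = "wickerhamomyces_key.json",
  occurrences = "wickerhamomyces_occurrences.tsv",
  continent_mapping = "continent_mapping.tsv",
  profile_lannaensis = "profile_lannaensis.tsv",
  profile_nanensis = "profile_nanensis.tsv"
)

#' Names and paths of the packaged fixtures
#'
#' @return Data frame with columns `name`, `file`, `path`.
#' @export
dichokey_fixtures <- function() {
  data.frame(name = names(DK_FIXTURES), file = unname(DK_FIXTURES),
             path = vapply(unname(DK_FIXTURES), function(f) {
               system.file("extdata", f, package = "dichokey")
             }, character(1)),
             stringsAsFactors = FALSE)
}

#' Path to one packaged fixture
#'
#' @param name One of `"matrix"`, `"vocabulary"`, `"key"`, `"occurrences"`,
#'   `"continent_mapping"`, `"profile_lannaensis"`, `"profile_nanensis"`.
#' @return File path.
#' @export
dichokey_fixture <- function(name) {
  name <- match.arg(name, names(DK_FIXTURES))
  system.file("extdata", DK_FIXTURES[[name]], package = "dichokey")
}

#' The genus-wide character matrix (38 species x 22 characters)
#'
#' Transcription of the published key-characteristics table for all accepted
#' species of *Wickerhamomyces*: 18 carbon/nitrogen assimilation tests, two
#' growth conditions (vitamin-free medium, 37 degrees C), and two
#' morphological characters (ascospores on 5% MEA, true hyphae).
#'
#' @return A `character_matrix`.
#' @export
wickerhamomyces_matrix <- function() {
  read_character_matrix(dichokey_fixture("matrix"),
                        vocabulary = read_vocabulary(dichokey_fixture("vocabulary")))
}

#' The printed dichotomous key to species (37 couplets, 38 leaves)
#'
#' @return A `dichotomous_key`.
#' @export
wickerhamomyces_key <- function() {
  parse_key(dichokey_fixture("key"))
}

#' The global distribution table (36 previously described species)
#'
#' @return An `occurrence_table`.
#' @export
wickerhamomyces_occurrences <- function() {
  read_occurrences(dichokey_fixture("occurrences"))
}

#' Default place-to-continent mapping for the distribution table
#'
#' UN-style geoscheme with explicit pins for every place in the packaged
#' table: Russia resolves to Europe, the Dominican Republic to North America,
#' King George Island to Antarctica, Ivory Coast to Africa.
#'
#' @return Named character vector place -> continent.
#' @export
wickerhamomyces_continent_mapping <- function() {
  read_continent_mapping(dichokey_fixture("continent_mapping"))
}

#' Specimen profiles of the two newly described species
#'
#' Test outcomes transcribed from the species descriptions of
#' *W. lannaensis* and *W. nanensis*, restricted to the 22 characters of the
#' genus matrix.
#'
#' @param species `"lannaensis"` or `"nanensis"`.
#' @return A `specimen_profile`.
#' @export
wickerhamomyces_profile <- function(species = c("lannaensis", "nanensis")) {
  species <- match.arg(species)
  read_specimen_profile(dichokey_fixture(paste0("profile_", species)),
                        vocabulary = read_vocabulary(dichokey_fixture("vocabulary")))
}
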