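# Occurrence tables and diversity bookkeeping.
#
# An occurrence table maps each species to the set of places it has been
# recorded from (literature-compiled, so "places" can include islands or
# regions, not only countries), with free-text isolation sources and an
# optional discovery year. Summaries: distinct-species counts per continent,
# species per country, grand totals with proposed additions, and a per-decade
# discovery histogram.

DK_CONTINENTS <- c("Africa", "Antarctica", "Asia", "Europe",
                   "North America", "Oceania", "South America")

#' Construct an occurrence table
#'
#' @param species Character vector of species names (unique).
#' @param localities List of character vectors (one non-empty set of place
#'   names per species), or a single `;`-joined string per species.
#' @param sources Optional free-text isolation sources.
#' @param years Optional integer years (NA allowed).
#' @return An `occurrence_table` (a data frame with a list-column
#'   `localities`).
#' @export
occurrence_table <- function(species, localities, sources = NA_character_,
                             years = NA_integer_) {
  if (anyDuplicated(species)) {
    dk_stop("dk_duplicate_species_error",
            sprintf("duplicate species in table: %s",
                    paste(unique(species[duplicated(species)]), collapse = ", ")))
  }
  if (is.character(localities)) {
    localities <- lapply(strsplit(localities, ";", fixed = TRUE), trimws)
  }
  stopifnot(length(localities) == length(species))
  if (any(lengths(localities) == 0L) ||
      any(vapply(localities, function(l) any(!nzchar(l)), logical(1)))) {
    dk_stop("dk_matrix_shape_error", "every species needs at least one locality")
  }
  out <- data.frame(species = species, stringsAsFactors = FALSE)
  out$localities <- localities
  out$source <- rep_len(sources, length(species))
  out$year <- rep_len(as.integer(years), length(species))
  class(out) <- c("occurrence_table", "data.frame")
  out
}

#' Read an occurrence table from TSV
#'
#' Columns `species`, `localities` (`;`-joined), optional `source`, `year`.
#'
#' @param path File path.
#' @return An `occurrence_table`.
#' @export
read_occurrences <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                         check.names = FALSE, encoding = "UTF-8")
  stopifnot(all(c("species", "localities") %in% names(d)))
  occurrence_table(d$species, d$localities,
                   sources = if ("source" %in% names(d)) d$source else NA,
                   years = if ("year" %in% names(d)) d$year else NA)
}

#' Read a place-to-continent mapping from TSV
#'
#' Two columns, `place` and `continent`; continents must be one of the seven
#' standard names.
#'
#' @param path File path.
#' @return Named character vector: place -> continent.
#' @export
read_continent_mapping <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                         check.names = FALSE, encoding = "UTF-8")
  stopifnot(all(c("place", "continent") %in% names(d)))
  bad <- setdiff(unique(d$continent), DK_CONTINENTS)
  if (length(bad)) {
    dk_stop("dk_unmapped_place_error",
            sprintf("unknown continent name(s): %s", paste(bad, collapse = ", ")))
  }
  stats::setNames(d$continent, d$place)
}

#' Distinct species per continent
#'
#' A species counts once in every continent where it has at least one
#' locality, so multi-continent species contribute to several counts.
#'
#' @param table An `occurrence_table`.
#' @param mapping Named character vector place -> continent (see
#'   [read_continent_mapping()]).
#' @return Named integer vector over all seven continents.
#' @export
continent_counts <- function(table, mapping) {
  counts <- stats::setNames(integer(length(DK_CONTINENTS)), DK_CONTINENTS)
  if (!nrow(table)) return(counts)
  places <- unique(unlist(table$localities))
  unmapped <- setdiff(places, names(mapping))
  if (length(unmapped)) {
    dk_stop("dk_unmapped_place_error",
            sprintf("localities with no continent mapping: %s",
                    paste(unmapped, collapse = ", ")),
            places = unmapped)
  }
  for (i in seq_len(nrow(table))) {
    for (cont in unique(unname(mapping[table$localities[[i]]]))) {
      counts[cont] <- counts[cont] + 1L
    }
  }
  counts
}

#' Species recorded from a given country
#'
#' @param table An `occurrence_table`.
#' @param country Place name; unknown places yield an empty set.
#' @return Character vector of species names.
#' @export
species_in_country <- function(table, country) {
  hit <- vapply(table$localities, function(l) country %in% l, logical(1))
  table$species[hit]
}

#' Species totals with proposed additions
#'
#' Bookkeeping for "adding n new species brings the global total to N":
#' additions must be disjoint from the table and carry their own localities.
#'
#' @param table An `occurrence_table`.
#' @param additions Named list: new species name -> character vector of
#'   localities. May be empty.
#' @return List with `table_count`, `grand_total`, and `per_country` (named
#'   integer vector of distinct-species counts over the union).
#' @export
species_totals <- function(table, additions = list()) {
  dup <- intersect(names(additions), table$species)
  if (length(dup)) {
    dk_stop("dk_duplicate_species_error",
            sprintf("additions already in table: %s", paste(dup, collapse = ", ")),
            species = dup)
  }
  all_loc <- c(table$localities, unname(additions))
  all_sp <- c(table$species, names(additions))
  places <- sort(unique(unlist(all_loc)))
  per_country <- stats::setNames(integer(length(places)), places)
  for (i in seq_along(all_sp)) {
    for (p in unique(all_loc[[i]])) per_country[p] <- per_country[p] + 1L
  }
  list(table_count = nrow(table),
       grand_total = nrow(table) + length(additions),
       per_country = per_country)
}

#' Per-decade discovery histogram
#'
#' @param years Named integer vector: species -> year of description.
#' @return Named integer vector: decade start (e.g. `"1950"`) -> count.
#'   Counts partition the input.
#' @export
decade_histogram <- function(years) {
  if (!length(years)) return(stats::setNames(integer(0), character(0)))
  years <- as.integer(years)
  current <- as.integer(format(Sys.Date(), "%Y"))
  bad <- years < 1800L | years > current | is.na(years)
  if (any(bad)) {
    dk_stop("dk_invalid_year_error",
            sprintf("year(s) out of range [1800, %d]: %s", current,
                    paste(years[bad], collapse = ", ")))
  }
  dec <- (years %/% 10L) * 10L
  tb <- table(dec)
  stats::setNames(as.integer(tb), names(tb))
}
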