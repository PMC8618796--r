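# Taxon-by-character matrices and specimen profiles.
#
# A character_matrix holds the species x character grid of state tokens plus a
# vocabulary describing each character (code, human label, kind). Tokens are
# stored canonicalized; parsing happens once at construction so every
# downstream consumer can assume valid states.

#' Construct a character matrix
#'
#' @param tokens Character matrix of state tokens; rownames are species names,
#'   colnames are character codes.
#' @param vocabulary Optional data frame with columns `code`, `label`, `kind`
#'   (`kind` one of `"assimilation"`, `"growth-condition"`, `"morphology"`).
#'   Defaults to a minimal vocabulary built from the column names.
#' @return An object of class `character_matrix`: list with `species`,
#'   `characters`, `vocabulary`, and canonicalized `tokens`.
#' @export
character_matrix <- function(tokens, vocabulary = NULL) {
  if (!is.matrix(tokens) || !is.character(tokens)) {
    dk_stop("dk_matrix_shape_error", "tokens must be a character matrix")
  }
  species <- rownames(tokens)
  codes <- colnames(tokens)
  if (is.null(species) || is.null(codes)) {
    dk_stop("dk_matrix_shape_error", "tokens must have species rownames and character colnames")
  }
  if (anyDuplicated(species)) {
    dk_stop("dk_matrix_shape_error",
            sprintf("duplicate species names: %s",
                    paste(unique(species[duplicated(species)]), collapse = ", ")))
  }
  if (anyDuplicated(codes)) {
    dk_stop("dk_matrix_shape_error", "duplicate character codes in header")
  }
  if (is.null(vocabulary)) {
    vocabulary <- data.frame(code = codes, label = codes,
                             kind = "assimilation", stringsAsFactors = FALSE)
  }
  stopifnot(all(c("code", "label", "kind") %in% names(vocabulary)))
  if (!setequal(vocabulary$code, codes)) {
    dk_stop("dk_matrix_shape_error", "vocabulary codes do not match matrix columns")
  }
  vocabulary <- vocabulary[match(codes, vocabulary$code), , drop = FALSE]
  rownames(vocabulary) <- NULL
  canon <- tokens
  for (i in seq_along(species)) {
    for (j in seq_along(codes)) {
      canon[i, j] <- tryCatch(
        canonical_token(tokens[i, j]),
        dk_unknown_token_error = function(e) {
          dk_unknown_token(tokens[i, j],
                           where = sprintf("species %s, character %s", species[i], codes[j]))
        })
    }
  }
  structure(list(species = species, characters = codes,
                 vocabulary = vocabulary, tokens = canon),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("character_matrix: %d species x %d characters\n",
              length(x$species), length(x$characters)))
  cat("characters:", paste(x$characters, collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.character_matrix <- function(x) c(length(x$species), length(x$characters))

#' Read a character matrix from TSV
#'
#' Dialect: UTF-8, tab-separated, `#` comment lines, header row of character
#' codes, first column species names. Cell tokens are validated against the
#' state grammar; a bad cell is reported with its species/character location.
#'
#' @param path File path (or connection) to read.
#' @param vocabulary Optional vocabulary data frame (see [character_matrix()]);
#'   typically from [read_vocabulary()].
#' @return A `character_matrix`.
#' @export
read_character_matrix <- function(path, vocabulary = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    dk_stop("dk_matrix_shape_error", "matrix file needs a header and at least one species row")
  }
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  widths <- lengths(cells[-1])
  if (any(widths != length(header))) {
    bad <- which(widths != length(header))[1] + 1L
    dk_stop("dk_matrix_shape_error",
            sprintf("ragged row %d: %d fields, header has %d", bad, widths[bad - 1L], length(header)))
  }
  body <- do.call(rbind, cells[-1])
  tokens <- body[, -1, drop = FALSE]
  rownames(tokens) <- trimws(body[, 1])
  colnames(tokens) <- trimws(header[-1])
  character_matrix(tokens, vocabulary = vocabulary)
}

#' Write a character matrix to TSV
#'
#' Emits canonical tokens in the same dialect [read_character_matrix()] reads;
#' reading the result back reproduces the matrix bit-exactly.
#'
#' @param x A `character_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_character_matrix <- function(x, path) {
  stopifnot(inherits(x, "character_matrix"))
  header <- paste(c("species", x$characters), collapse = "\t")
  rows <- vapply(seq_along(x$species), function(i) {
    paste(c(x$species[i], x$tokens[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read a character vocabulary (code, label, kind) from TSV
#'
#' @param path File path to a three-column TSV with header.
#' @return Data frame with columns `code`, `label`, `kind`.
#' @export
read_vocabulary <- function(path) {
  v <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                         check.names = FALSE, encoding = "UTF-8")
  stopifnot(all(c("code", "label", "kind") %in% names(v)))
  if (anyDuplicated(v$code)) {
    dk_stop("dk_matrix_shape_error", "duplicate codes in vocabulary")
  }
  v
}

dk_require_species <- function(matrix, species) {
  missing <- setdiff(species, matrix$species)
  if (length(missing)) {
    dk_stop("dk_unknown_species_error",
            sprintf("species not in matrix: %s", paste(missing, collapse = ", ")),
            species = missing)
  }
}

#' Characters that distinguish two species
#'
#' A character distinguishes two species when their states share no supported
#' binary outcome (e.g. `{positive}` vs `{negative}`). States that support
#' both outcomes (variable, no-data, mixed alternations) never distinguish,
#' and neither do two positive-class states such as `"+"` vs `"w"` under the
#' default polarity rule.
#'
#' @param matrix A `character_matrix`.
#' @param species_a,species_b Species names present in the matrix.
#' @param polarity Polarity rule passed to [state_supports()].
#' @return Character vector of distinguishing character codes (possibly empty).
#' @export
distinguishing_characters <- function(matrix, species_a, species_b,
                                      polarity = c("default", "strict")) {
  polarity <- match.arg(polarity)
  dk_require_species(matrix, c(species_a, species_b))
  a <- matrix$tokens[species_a, ]
  b <- matrix$tokens[species_b, ]
  keep <- vapply(seq_along(a), function(j) {
    sa <- dk_supports(a[[j]], polarity)
    sb <- dk_supports(b[[j]], polarity)
    !any(sa & sb)  # no common supported outcome
  }, logical(1))
  matrix$characters[keep]
}

#' Construct a specimen profile
#'
#' A specimen profile records the observed test outcomes of one strain for a
#' subset of the character vocabulary. Missing characters simply stay absent;
#' key traversal stalls when it needs one.
#'
#' @param outcomes Named character vector of state tokens, names are character
#'   codes.
#' @param identifier Free-text specimen identifier.
#' @param vocabulary Optional vocabulary data frame; if supplied, all outcome
#'   codes must appear in it.
#' @return An object of class `specimen_profile`.
#' @export
specimen_profile <- function(outcomes, identifier = "specimen", vocabulary = NULL) {
  stopifnot(is.character(outcomes), !is.null(names(outcomes)), all(nzchar(names(outcomes))))
  if (anyDuplicated(names(outcomes))) {
    dk_stop("dk_matrix_shape_error", "duplicate character codes in profile")
  }
  if (!is.null(vocabulary)) {
    bad <- setdiff(names(outcomes), vocabulary$code)
    if (length(bad)) {
      dk_stop("dk_unknown_token_error",
              sprintf("profile codes not in vocabulary: %s", paste(bad, collapse = ", ")))
    }
  }
  canon <- vapply(outcomes, canonical_token, character(1))
  structure(list(identifier = identifier, outcomes = canon),
            class = "specimen_profile")
}

#' Read a specimen profile from TSV
#'
#' Two columns (`character`, `state`) with a header row; an optional comment
#' line `# id: <name>` supplies the identifier.
#'
#' @param path File path.
#' @param vocabulary Optional vocabulary for code validation.
#' @return A `specimen_profile`.
#' @export
read_specimen_profile <- function(path, vocabulary = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  id_line <- grep("^#\\s*id:", lines, value = TRUE)
  id <- if (length(id_line)) trimws(sub("^#\\s*id:", "", id_line[1])) else
    sub("\\.[^.]*$", "", basename(path))
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (identical(tolower(trimws(parts[[1]][1])), "character")) parts <- parts[-1]
  outcomes <- vapply(parts, function(p) trimws(p[2]), character(1))
  names(outcomes) <- vapply(parts, function(p) trimws(p[1]), character(1))
  specimen_profile(outcomes, identifier = id, vocabulary = vocabulary)
}

#' @export
print.specimen_profile <- function(x, ...) {
  cat(sprintf("specimen_profile '%s': %d observed characters\n",
              x$identifier, length(x$outcomes)))
  invisible(x)
}

#' Extract one species' row as a named token vector
#'
#' @param matrix A `character_matrix`.
#' @param species A species name.
#' @return Named character vector of canonical tokens.
#' @export
matrix_row <- function(matrix, species) {
  dk_require_species(matrix, species)
  r <- matrix$tokens[species, ]
  stats::setNames(as.character(r), matrix$characters)
}
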