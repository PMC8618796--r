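# Character-state algebra for phenotypic test outcomes.
#
# A cell of a taxonomic character matrix records the outcome of one growth or
# assimilation test for one species, using the compact token vocabulary common
# in yeast taxonomy: "+" strong positive, "-" negative, "w" weak, "l" latent
# (delayed) positive, "s" slow positive, "v" strain-variable, "n" no data.
# Tokens may be joined by "/" or "," into an alternation ("+/w": some strains
# strong, some weak). Downstream key logic only ever asks a binary question --
# does this state support a positive (or negative) reading? -- so the algebra
# reduces every state to the set of binary outcomes it supports.

DK_ATOM_TOKEN <- c(
  positive = "+", weak = "w", latent = "l", slow = "s",
  variable = "v", negative = "-", `no-data` = "n"
)
DK_TOKEN_ATOM <- stats::setNames(names(DK_ATOM_TOKEN), unname(DK_ATOM_TOKEN))

# canonical serialization order for alternation atoms
DK_CANON_ORDER <- c("positive", "weak", "latent", "slow", "variable", "negative")

# All Unicode dash-like glyphs that print sources use for "negative".
# U+2012 figure dash, U+2013 en dash, U+2014 em dash, U+2212 minus sign,
# U+2010 hyphen, U+2011 non-breaking hyphen, U+2015 horizontal bar.
dk_normalize_dashes <- function(x) {
  gsub("[‐‑‒–—―−]", "-", x)
}

#' Parse a character-state token
#'
#' Turns one matrix-cell token (e.g. `"+"`, `"w"`, `"n"`, `"+/w"`, `"+,-"`)
#' into a `character_state`: the non-empty set of atomic outcomes the token
#' denotes plus the raw source text. `/` and `,` both separate alternation
#' atoms; all Unicode dash glyphs normalize to the ASCII negative sign.
#'
#' @param token Character scalar, the source token.
#' @return An object of class `character_state` with elements `atoms`
#'   (character vector in canonical order) and `raw_token`.
#' @examples
#' parse_state_token("+")$atoms
#' parse_state_token("w/+")$atoms
#' @export
parse_state_token <- function(token) {
  if (!is.character(token) || length(token) != 1L || is.na(token)) {
    dk_stop("dk_unknown_token_error", "token must be a single character string")
  }
  raw <- trimws(token)
  if (!nzchar(raw)) dk_unknown_token(token)
  norm <- dk_normalize_dashes(raw)
  parts <- strsplit(norm, "[/,]", fixed = FALSE)[[1]]
  parts <- trimws(parts)
  if (length(parts) == 0L || any(!nzchar(parts))) dk_unknown_token(token)
  bad <- setdiff(parts, names(DK_TOKEN_ATOM))
  if (length(bad)) dk_unknown_token(token)
  atoms <- unique(unname(DK_TOKEN_ATOM[parts]))
  if ("no-data" %in% atoms && length(atoms) > 1L) {
    dk_stop("dk_unknown_token_error",
            sprintf("\"n\" (no data) cannot combine with other atoms: %s", raw),
            token = token)
  }
  atoms <- if (identical(atoms, "no-data")) atoms else
    DK_CANON_ORDER[DK_CANON_ORDER %in% atoms]
  structure(list(atoms = atoms, raw_token = raw), class = "character_state")
}

#' Canonical serialization of a state
#'
#' Atoms are ordered positive < weak < latent < slow < variable < negative and
#' joined with `/`; `"n"` serializes alone. Parsing a canonical token and
#' re-serializing it is the identity.
#'
#' @param state A `character_state`, or a raw token string (parsed first).
#' @return Character scalar, the canonical token.
#' @export
canonical_token <- function(state) {
  if (is.character(state)) state <- parse_state_token(state)
  paste(unname(DK_ATOM_TOKEN[state$atoms]), collapse = "/")
}

#' @export
format.character_state <- function(x, ...) {
  sprintf("<state %s = {%s}>", canonical_token(x), paste(x$atoms, collapse = ", "))
}

#' @export
print.character_state <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# token -> c(pos = TRUE/FALSE, neg = TRUE/FALSE) support table, memoised since
# a 38 x 22 matrix reuses a handful of distinct tokens thousands of times.
.dk_support_cache <- new.env(parent = emptyenv())

dk_supports <- function(token, polarity = c("default", "strict")) {
  polarity <- match.arg(polarity)
  key <- paste0(polarity, "\r", token)
  hit <- .dk_support_cache[[key]]
  if (!is.null(hit)) return(hit)
  atoms <- if (inherits(token, "character_state")) token$atoms else
    parse_state_token(token)$atoms
  pos_class <- c("positive", "weak", "latent", "slow", "variable", "no-data")
  neg_class <- c("negative", "variable", "no-data")
  if (polarity == "strict") neg_class <- c(neg_class, "weak")
  out <- c(positive = any(atoms %in% pos_class),
           negative = any(atoms %in% neg_class))
  if (is.character(token)) .dk_support_cache[[key]] <- out
  out
}

#' Does a state support a binary outcome?
#'
#' The bridge between matrix states and yes/no key leads. Under the default
#' polarity rule, weak/latent/slow count as positive (taxonomic descriptions
#' treat delayed or weak growth as assimilation); `v` (variable) and `n`
#' (no data) support both outcomes; an alternation supports an outcome if any
#' of its atoms does. The `"strict"` polarity additionally lets weak support
#' the negative outcome, flagging borderline reactions.
#'
#' @param state A `character_state` or raw token string.
#' @param outcome `"positive"` or `"negative"`.
#' @param polarity `"default"` or `"strict"`.
#' @return Logical scalar.
#' @examples
#' state_supports("v", "negative")
#' state_supports("w", "negative")            # FALSE under default polarity
#' state_supports("w", "negative", "strict")  # TRUE
#' @export
state_supports <- function(state, outcome = c("positive", "negative"),
                           polarity = c("default", "strict")) {
  outcome <- match.arg(outcome)
  unname(dk_supports(state, match.arg(polarity))[outcome])
}
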