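# Dichotomous key model.
#
# A key is a rooted binary tree of numbered couplets. Each couplet carries two
# leads labeled a and b; both assert opposite binary outcomes of the same
# character, and each points either at another couplet or at a species leaf
# (a character vector -- usually one name, more for multi-species leaves from
# the builder). The printed back-reference "(k)" after a couplet number is
# kept as metadata only: lead targets are authoritative and validate_structure
# reports any disagreement.

dk_lead <- function(label, character, outcome, target) {
  stopifnot(label %in% c("a", "b"), outcome %in% c("positive", "negative"))
  type <- if (is.numeric(target)) "couplet" else "species"
  list(label = label, character = character, outcome = outcome,
       target_type = type,
       target = if (type == "couplet") as.integer(target) else as.character(target))
}

dk_couplet <- function(number, leads, parent_annotation = NA_integer_) {
  list(number = as.integer(number),
       parent_annotation = if (is.na(parent_annotation)) NA_integer_ else as.integer(parent_annotation),
       leads = leads)
}

#' Construct a dichotomous key
#'
#' Verifies the structural invariants: exactly two leads per couplet labeled
#' `a`/`b` asserting opposite outcomes of one character; every non-root
#' couplet targeted by exactly one lead; the couplet graph acyclic with all
#' couplets reachable from the root.
#'
#' @param couplets A list of couplet records (as built by [parse_key()] or the
#'   key builder).
#' @param root Root couplet number (default: the lowest-numbered couplet that
#'   no lead targets).
#' @return An object of class `dichotomous_key`.
#' @export
dichotomous_key <- function(couplets, root = NULL) {
  if (!length(couplets)) dk_stop("dk_key_schema_error", "key has no couplets")
  numbers <- vapply(couplets, function(cp) cp$number, integer(1))
  if (anyDuplicated(numbers)) {
    dk_stop("dk_structure_error", "duplicate couplet numbers")
  }
  names(couplets) <- as.character(numbers)
  for (cp in couplets) {
    if (length(cp$leads) != 2L) {
      dk_stop("dk_key_schema_error",
              sprintf("couplet %d must have exactly two leads", cp$number))
    }
    labs <- vapply(cp$leads, `[[`, character(1), "label")
    if (!setequal(labs, c("a", "b"))) {
      dk_stop("dk_key_schema_error",
              sprintf("couplet %d leads must be labeled a and b", cp$number))
    }
    chars <- vapply(cp$leads, `[[`, character(1), "character")
    outs <- vapply(cp$leads, `[[`, character(1), "outcome")
    if (chars[1] != chars[2] || outs[1] == outs[2]) {
      dk_stop("dk_key_schema_error",
              sprintf("couplet %d leads must assert opposite outcomes of one character", cp$number))
    }
  }
  # reference structure
  targets <- integer(0)
  for (cp in couplets) for (ld in cp$leads) {
    if (ld$target_type == "couplet") {
      if (!as.character(ld$target) %in% names(couplets)) {
        dk_stop("dk_structure_error",
                sprintf("couplet %d references missing couplet %d", cp$number, ld$target))
      }
      targets <- c(targets, ld$target)
    }
  }
  dup <- unique(targets[duplicated(targets)])
  if (length(dup)) {
    dk_stop("dk_structure_error",
            sprintf("couplet(s) referenced by more than one lead: %s",
                    paste(dup, collapse = ", ")))
  }
  roots <- setdiff(numbers, targets)
  if (is.null(root)) {
    if (length(roots) != 1L) {
      dk_stop("dk_structure_error",
              sprintf("key must have exactly one root couplet, found: %s",
                      paste(sort(roots), collapse = ", ")))
    }
    root <- roots
  } else if (!root %in% numbers) {
    dk_stop("dk_structure_error", sprintf("root couplet %d not present", root))
  }
  key <- structure(list(couplets = couplets, root = as.integer(root)),
                   class = "dichotomous_key")
  # reachability (single-parent + unique root already imply acyclicity,
  # but an unreachable cyclic component is still possible)
  seen <- dk_reach(key, key$root)
  if (length(seen) != length(numbers)) {
    dk_stop("dk_structure_error",
            sprintf("couplet(s) unreachable from root: %s",
                    paste(setdiff(numbers, seen), collapse = ", ")))
  }
  key
}

dk_reach <- function(key, from) {
  seen <- integer(0)
  stack <- from
  while (length(stack)) {
    n <- stack[[1]]; stack <- stack[-1]
    if (n %in% seen) next
    seen <- c(seen, n)
    for (ld in key$couplets[[as.character(n)]]$leads) {
      if (ld$target_type == "couplet") stack <- c(stack, ld$target)
    }
  }
  seen
}

#' All species leaves of a key
#'
#' @param key A `dichotomous_key`.
#' @return Character vector of species names (unique, in traversal order).
#' @export
key_species <- function(key) {
  out <- character(0)
  for (n in dk_reach(key, key$root)) {
    for (ld in key$couplets[[as.character(n)]]$leads) {
      if (ld$target_type == "species") out <- c(out, ld$target)
    }
  }
  unique(out)
}

#' @export
print.dichotomous_key <- function(x, ...) {
  cat(sprintf("dichotomous_key: %d couplets, %d leaves, root at couplet %d\n",
              length(x$couplets), dk_leaf_count(x), x$root))
  invisible(x)
}

dk_leaf_count <- function(key) {
  sum(vapply(key$couplets, function(cp) {
    sum(vapply(cp$leads, function(ld) ld$target_type == "species", logical(1)))
  }, integer(1)))
}

#' Parse a key from its JSON representation
#'
#' The key file is a single JSON document: a `couplets` array whose entries
#' carry `number`, optional `parent` (the printed back-reference), and two
#' `leads` objects `{label, character, outcome, target}` where `target` is
#' either `{"couplet": n}` or `{"species": name-or-names}`.
#'
#' @param source A file path, or a JSON string (detected by a leading `{`).
#' @return A validated `dichotomous_key`.
#' @export
parse_key <- function(source) {
  txt <- if (length(source) == 1L && !grepl("^\\s*\\{", source)) {
    paste(readLines(source, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  } else paste(source, collapse = "\n")
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e) dk_stop("dk_key_schema_error",
                                              paste("invalid JSON:", conditionMessage(e))))
  if (is.null(doc$couplets)) dk_stop("dk_key_schema_error", "key document lacks 'couplets'")
  couplets <- lapply(doc$couplets, function(cp) {
    if (is.null(cp$number) || is.null(cp$leads) || length(cp$leads) != 2L) {
      dk_stop("dk_key_schema_error", "each couplet needs 'number' and two 'leads'")
    }
    leads <- lapply(cp$leads, function(ld) {
      if (is.null(ld$label) || is.null(ld$character) || is.null(ld$outcome) || is.null(ld$target)) {
        dk_stop("dk_key_schema_error", "each lead needs label, character, outcome, target")
      }
      tgt <- ld$target
      if (!is.null(tgt$couplet)) {
        dk_lead(ld$label, ld$character, ld$outcome, as.integer(tgt$couplet))
      } else if (!is.null(tgt$species)) {
        dk_lead(ld$label, ld$character, ld$outcome, unlist(tgt$species, use.names = FALSE))
      } else {
        dk_stop("dk_key_schema_error", "lead target must name a couplet or species")
      }
    })
    parent <- if (is.null(cp$parent)) NA_integer_ else as.integer(cp$parent)
    dk_couplet(cp$number, leads, parent)
  })
  dichotomous_key(couplets)
}

#' Serialize a key to JSON
#'
#' Round-trips through [parse_key()]: structure, couplet numbering, and
#' printed parent annotations are preserved verbatim.
#'
#' @param key A `dichotomous_key`.
#' @param path Optional file path; if supplied the JSON is written there.
#' @return The JSON text (invisibly when `path` is given).
#' @export
serialize_key <- function(key, path = NULL) {
  stopifnot(inherits(key, "dichotomous_key"))
  couplets <- lapply(key$couplets, function(cp) {
    rec <- list(number = cp$number)
    if (!is.na(cp$parent_annotation)) rec$parent <- cp$parent_annotation
    rec$leads <- lapply(cp$leads, function(ld) {
      tgt <- if (ld$target_type == "couplet") list(couplet = ld$target) else
        list(species = as.list(ld$target))
      list(label = ld$label, character = ld$character,
           outcome = ld$outcome, target = tgt)
    })
    rec
  })
  doc <- list(schema = "dichokey/key/v1",
              root = key$root,
              couplets = unname(couplets))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' Check key structure and printed parent annotations
#'
#' Report-only companion to the hard validation in [dichotomous_key()]:
#' re-runs the graph checks and, additionally, compares each couplet's printed
#' parent annotation ("(k)") with the actual parent implied by lead targets.
#'
#' @param key A `dichotomous_key`.
#' @return A list with `violations` (character vector) and
#'   `annotation_discrepancies` (data frame: couplet, printed, actual).
#' @export
validate_structure <- function(key) {
  violations <- character(0)
  numbers <- vapply(key$couplets, `[[`, integer(1), "number")
  seen <- dk_reach(key, key$root)
  unreachable <- setdiff(numbers, seen)
  if (length(unreachable)) {
    violations <- c(violations, sprintf("unreachable couplet %d", unreachable))
  }
  # actual parents from lead targets
  parent_of <- integer(0)
  for (cp in key$couplets) for (ld in cp$leads) {
    if (ld$target_type == "couplet") parent_of[as.character(ld$target)] <- cp$number
  }
  disc <- data.frame(couplet = integer(0), printed = integer(0), actual = integer(0))
  for (cp in key$couplets) {
    if (is.na(cp$parent_annotation) || cp$number == key$root) next
    actual <- parent_of[[as.character(cp$number)]]
    if (!identical(actual, cp$parent_annotation)) {
      disc <- rbind(disc, data.frame(couplet = cp$number,
                                     printed = cp$parent_annotation,
                                     actual = actual))
    }
  }
  list(violations = violations, annotation_discrepancies = disc)
}

dk_row_token <- function(row, code) {
  if (inherits(row, "specimen_profile")) row <- row$outcomes
  if (!code %in% names(row)) return(NA_character_)
  tok <- row[[code]]
  if (is.null(tok) || is.na(tok)) NA_character_ else tok
}

#' Species leaves reachable from a state row
#'
#' Exhaustive uncertainty-aware traversal: starting at `from`, a lead is
#' followable iff the row's state for its character supports the asserted
#' outcome (missing characters are treated as no-data, hence follow both
#' leads). Returns the union of species leaves over all followable paths.
#'
#' @param key A `dichotomous_key`.
#' @param row Named character vector of state tokens (character code ->
#'   token), e.g. from [matrix_row()], or a `specimen_profile`.
#' @param polarity Polarity rule for [state_supports()].
#' @param from Couplet number to start from (default the root).
#' @return Character vector of species names.
#' @export
reachable_leaves <- function(key, row, polarity = c("default", "strict"),
                             from = key$root) {
  polarity <- match.arg(polarity)
  if (inherits(row, "specimen_profile")) row <- row$outcomes
  walk <- function(n) {
    out <- character(0)
    for (ld in key$couplets[[as.character(n)]]$leads) {
      tok <- dk_row_token(row, ld$character)
      if (is.na(tok)) tok <- "n"
      if (state_supports(tok, ld$outcome, polarity)) {
        out <- c(out, if (ld$target_type == "species") ld$target else walk(ld$target))
      }
    }
    out
  }
  unique(walk(from))
}

#' Identify a specimen by key traversal
#'
#' Walks the key from the root. At each couplet the specimen's observed state
#' decides the lead. Three terminal statuses:
#' \describe{
#'   \item{identified}{a unique walk reached a species leaf;}
#'   \item{ambiguous}{the specimen supports both leads somewhere (variable or
#'     no-data observation) -- the walk forks and the frontier of reachable
#'     species is reported;}
#'   \item{stalled}{the couplet's character is absent from the profile -- the
#'     user must run that test.}
#' }
#'
#' @param key A `dichotomous_key`.
#' @param specimen A `specimen_profile` (or named token vector).
#' @param polarity Polarity rule for [state_supports()].
#' @return An `identification_result`: list with `status`, `species`
#'   (character vector; length one when identified), `path` (data frame of
#'   couplet numbers and lead labels), and `stalled_at` (couplet number or NA).
#' @export
identify_specimen <- function(key, specimen, polarity = c("default", "strict")) {
  polarity <- match.arg(polarity)
  row <- if (inherits(specimen, "specimen_profile")) specimen$outcomes else specimen
  path <- data.frame(couplet = integer(0), lead = character(0))
  cur <- key$root
  repeat {
    cp <- key$couplets[[as.character(cur)]]
    code <- cp$leads[[1]]$character
    tok <- dk_row_token(row, code)
    if (is.na(tok)) {
      return(structure(list(status = "stalled", species = character(0),
                            path = path, stalled_at = cur),
                       class = "identification_result"))
    }
    ok <- vapply(cp$leads, function(ld) state_supports(tok, ld$outcome, polarity),
                 logical(1))
    if (all(ok)) {
      frontier <- reachable_leaves(key, row, polarity, from = cur)
      return(structure(list(status = "ambiguous", species = frontier,
                            path = path, stalled_at = NA_integer_),
                       class = "identification_result"))
    }
    ld <- cp$leads[[which(ok)]]
    path <- rbind(path, data.frame(couplet = cur, lead = ld$label))
    if (ld$target_type == "species") {
      return(structure(list(status = "identified", species = ld$target,
                            path = path, stalled_at = NA_integer_),
                       class = "identification_result"))
    }
    cur <- ld$target
  }
}

#' @export
print.identification_result <- function(x, ...) {
  cat("identification:", x$status, "\n")
  if (length(x$species)) cat("  species:", paste(x$species, collapse = ", "), "\n")
  if (nrow(x$path)) {
    cat("  path:", paste0(x$path$couplet, x$path$lead, collapse = " -> "), "\n")
  }
  if (!is.na(x$stalled_at)) cat("  stalled at couplet", x$stalled_at, "\n")
  invisible(x)
}
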