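# Key-versus-matrix validation.
#
# Consistency is existential: a species passes when SOME resolution of its
# matrix row (variable and no-data states may go either way) walks the key to
# its own leaf. That matches how printed keys treat strain-variable taxa: the
# key separates them by other, definite characters downstream.

dk_normalize_name <- function(x) {
  x <- gsub("\\s+", " ", trimws(x))
  # abbreviate the genus word: "Wickerhamomyces lannaensis" -> "W. lannaensis"
  sub("^([A-Z])[A-Za-z]+\\s", "\\1. ", x)
}

# root-to-leaf lead sequences for every species leaf
dk_leaf_paths <- function(key) {
  paths <- list()
  walk <- function(n, trail) {
    cp <- key$couplets[[as.character(n)]]
    for (ld in cp$leads) {
      step <- list(couplet = cp$number, lead = ld$label,
                   character = ld$character, outcome = ld$outcome)
      if (ld$target_type == "species") {
        for (sp in ld$target) {
          paths[[length(paths) + 1L]] <<- list(species = sp, steps = c(trail, list(step)))
        }
      } else {
        walk(ld$target, c(trail, list(step)))
      }
    }
  }
  walk(key$root, list())
  paths
}

#' Check a key against a character matrix
#'
#' For every species present in both the key and the matrix, decides whether
#' the species' own leaf is reachable from its matrix row (existential over
#' resolutions of uncertain states), reports the full reachable leaf set, and
#' -- for failures -- cites the first couplet on the root-to-leaf path where
#' the row contradicts the required lead.
#'
#' Species names are matched exactly after normalizing whitespace and the
#' genus abbreviation ("W." vs. the spelled-out genus).
#'
#' @param key A `dichotomous_key`.
#' @param matrix A `character_matrix`.
#' @param polarity Polarity rule for [state_supports()].
#' @return A `consistency_report`: list with `records` (data frame), the
#'   per-species `reachable` sets, `only_in_key`, `only_in_matrix`, and a
#'   `summary` of counts.
#' @export
check_consistency <- function(key, matrix, polarity = c("default", "strict")) {
  polarity <- match.arg(polarity)
  leaf_sp <- key_species(key)
  key_norm <- dk_normalize_name(leaf_sp)
  mat_norm <- dk_normalize_name(matrix$species)
  if (!length(intersect(key_norm, mat_norm))) {
    dk_stop("dk_name_mismatch_error",
            "no species shared between key and matrix after name normalization",
            only_in_key = leaf_sp, only_in_matrix = matrix$species)
  }
  shared <- intersect(mat_norm, key_norm)
  only_in_key <- leaf_sp[!key_norm %in% mat_norm]
  only_in_matrix <- matrix$species[!mat_norm %in% key_norm]

  paths <- dk_leaf_paths(key)
  path_names <- dk_normalize_name(vapply(paths, `[[`, character(1), "species"))

  recs <- list()
  reachable_sets <- list()
  for (nm in shared) {
    sp_mat <- matrix$species[match(nm, mat_norm)]
    row <- matrix_row(matrix, sp_mat)
    reach <- reachable_leaves(key, row, polarity)
    reachable_sets[[sp_mat]] <- reach
    own_paths <- paths[path_names == nm]
    ok <- FALSE
    witness <- NA_character_
    conflict <- data.frame(couplet = NA_integer_, character = NA_character_,
                           state = NA_character_, asserted = NA_character_)
    for (p in own_paths) {
      supported <- vapply(p$steps, function(st) {
        state_supports(row[[st$character]] %||% "n", st$outcome, polarity)
      }, logical(1))
      if (all(supported)) {
        ok <- TRUE
        witness <- paste0(vapply(p$steps, `[[`, integer(1), "couplet"),
                          vapply(p$steps, `[[`, character(1), "lead"),
                          collapse = ",")
        break
      } else if (is.na(conflict$couplet)) {
        st <- p$steps[[which(!supported)[1]]]
        conflict <- data.frame(couplet = st$couplet, character = st$character,
                               state = row[[st$character]] %||% "n",
                               asserted = st$outcome)
      }
    }
    recs[[sp_mat]] <- data.frame(
      species = sp_mat, own_leaf_reachable = ok, n_reachable = length(reach),
      witness_path = witness, conflict_couplet = conflict$couplet,
      conflict_character = conflict$character, conflict_state = conflict$state,
      conflict_asserted = conflict$asserted, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, unname(recs))
  rownames(records) <- NULL
  structure(list(
    records = records,
    reachable = reachable_sets,
    only_in_key = only_in_key,
    only_in_matrix = only_in_matrix,
    summary = list(n_checked = nrow(records),
                   n_consistent = sum(records$own_leaf_reachable),
                   n_only_in_key = length(only_in_key),
                   n_only_in_matrix = length(only_in_matrix))),
    class = "consistency_report")
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' @export
print.consistency_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("consistency_report: %d/%d species reach their own leaf\n",
              s$n_consistent, s$n_checked))
  bad <- x$records[!x$records$own_leaf_reachable, , drop = FALSE]
  if (nrow(bad)) {
    for (i in seq_len(nrow(bad))) {
      cat(sprintf("  %s: blocked at couplet %d (%s = %s, lead asserts %s)\n",
                  bad$species[i], bad$conflict_couplet[i], bad$conflict_character[i],
                  bad$conflict_state[i], bad$conflict_asserted[i]))
    }
  }
  invisible(x)
}

#' Which matrix species can reach each key leaf?
#'
#' Runs [reachable_leaves()] for every matrix row and inverts the relation.
#' Under uncertainty a species may reach several leaves and a leaf may be
#' reached by several species; the multiset sizes of the forward and inverted
#' maps always agree (conservation).
#'
#' @param key A `dichotomous_key`.
#' @param matrix A `character_matrix`.
#' @param polarity Polarity rule.
#' @return Named list: leaf species -> character vector of matrix species that
#'   can reach that leaf.
#' @export
ambiguity_report <- function(key, matrix, polarity = c("default", "strict")) {
  polarity <- match.arg(polarity)
  leaves <- key_species(key)
  inv <- stats::setNames(vector("list", length(leaves)), leaves)
  for (sp in matrix$species) {
    reach <- reachable_leaves(key, matrix_row(matrix, sp), polarity)
    for (lf in reach) inv[[lf]] <- c(inv[[lf]], sp)
  }
  inv
}

#' Structural metrics of a key
#'
#' Depth of a leaf is the number of couplets on its root-to-leaf path.
#'
#' @param key A `dichotomous_key`.
#' @return A `key_metrics` list: `couplet_count`, `leaf_count`, `max_depth`,
#'   `mean_depth`, `characters_used`.
#' @export
key_metrics <- function(key) {
  paths <- dk_leaf_paths(key)
  # one depth per leaf *position* (multi-species leaves count once)
  pos <- vapply(paths, function(p) {
    st <- p$steps[[length(p$steps)]]
    paste0(st$couplet, st$lead)
  }, character(1))
  depths <- vapply(paths, function(p) length(p$steps), integer(1))
  depths <- depths[!duplicated(pos)]
  chars <- unique(unlist(lapply(key$couplets, function(cp) cp$leads[[1]]$character)))
  structure(list(couplet_count = length(key$couplets),
                 leaf_count = dk_leaf_count(key),
                 max_depth = max(depths),
                 mean_depth = mean(depths),
                 characters_used = sort(chars)),
            class = "key_metrics")
}

#' @export
print.key_metrics <- function(x, ...) {
  cat(sprintf("key_metrics: %d couplets, %d leaves, depth max %d / mean %.2f\n",
              x$couplet_count, x$leaf_count, x$max_depth, x$mean_depth))
  cat("  characters used:", paste(x$characters_used, collapse = " "), "\n")
  invisible(x)
}
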