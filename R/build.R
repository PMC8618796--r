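# Greedy construction of a dichotomous key from a character matrix.
#
# At each node the builder scores every character by the expected
# log-reduction in taxon count of the induced split, penalizing characters
# whose uncertain states (variable, alternation, no-data) force taxa onto
# both sides. Optimal (minimum expected depth) key construction is NP-hard;
# greedy selection with a deterministic tie-break is the standard practical
# compromise and is what printed keys approximate by hand.

#' Builder configuration
#'
#' @param scoring `"information-gain"` (expected natural-log reduction in
#'   taxon count) or `"worst-case-balance"` (minimize the larger side).
#' @param penalty_uncertain Penalty per taxon duplicated onto both sides by a
#'   variable or alternation state (default 0.5).
#' @param penalty_nodata Penalty per taxon duplicated by a no-data state
#'   (default 0.5).
#' @param tie_break Only `"column-order"`: ties go to the earlier character in
#'   the vocabulary.
#' @param max_depth Optional cap on couplets along any path.
#' @param allow_multi_species_leaves If `TRUE` (default), an unsplittable
#'   taxon set becomes a multi-species leaf; if `FALSE` it raises an
#'   indistinguishable-taxa error.
#' @return A `builder_config` list.
#' @export
builder_config <- function(scoring = c("information-gain", "worst-case-balance"),
                           penalty_uncertain = 0.5, penalty_nodata = 0.5,
                           tie_break = "column-order", max_depth = NULL,
                           allow_multi_species_leaves = TRUE) {
  stopifnot(penalty_uncertain >= 0, penalty_nodata >= 0,
            identical(tie_break, "column-order"))
  structure(list(scoring = match.arg(scoring),
                 penalty_uncertain = penalty_uncertain,
                 penalty_nodata = penalty_nodata,
                 tie_break = tie_break, max_depth = max_depth,
                 allow_multi_species_leaves = allow_multi_species_leaves),
            class = "builder_config")
}

#' Build a dichotomous key from a character matrix
#'
#' Recursive greedy partition. For a candidate character, taxa supporting only
#' the positive outcome go to lead a, only the negative to lead b, and taxa
#' supporting both (variable, no-data, mixed alternations) are duplicated onto
#' BOTH sides. A character is admissible only if both sides are strictly
#' smaller than the current set. Lead a always carries the positive outcome,
#' following printed-key convention. Couplets are numbered in preorder
#' (root = 1, then the a-subtree, then the b-subtree), so the same matrix and
#' config always yield the identical key.
#'
#' @param matrix A `character_matrix` with at least two species.
#' @param config A [builder_config()].
#' @param polarity Polarity rule for [state_supports()].
#' @return A list with `key` (a `dichotomous_key`) and `log` (a data frame of
#'   per-couplet split decisions: character, score, side sizes, duplicates).
#' @export
build_key <- function(matrix, config = builder_config(),
                      polarity = c("default", "strict")) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(matrix, "character_matrix"))
  if (length(matrix$species) < 2L) {
    dk_stop("dk_key_schema_error", "need at least two species to build a key")
  }
  codes <- matrix$characters
  # precompute support tables: species x character, logical
  pos <- apply(matrix$tokens, c(1, 2), function(t) state_supports(t, "positive", polarity))
  neg <- apply(matrix$tokens, c(1, 2), function(t) state_supports(t, "negative", polarity))

  env <- new.env()
  env$counter <- 0L
  env$couplets <- list()
  env$log <- list()

  score_split <- function(sp, code) {
    p <- pos[sp, code]; n <- neg[sp, code]
    a_only <- sp[p & !n]; b_only <- sp[!p & n]; both <- sp[p & n]
    nA <- length(a_only) + length(both)
    nB <- length(b_only) + length(both)
    total <- length(sp)
    if (nA == 0L || nB == 0L || nA >= total || nB >= total) {
      return(list(score = -Inf))
    }
    pen <- 0
    if (length(both)) {
      nodata <- matrix$tokens[both, code] == "n"
      pen <- config$penalty_nodata * sum(nodata) +
        config$penalty_uncertain * sum(!nodata)
    }
    base <- if (config$scoring == "information-gain") {
      wA <- nA / (nA + nB); wB <- nB / (nA + nB)
      log(total) - (wA * log(nA) + wB * log(nB))
    } else {
      -max(nA, nB) / total
    }
    list(score = base - pen, a = c(a_only, both), b = c(b_only, both),
         nA = nA, nB = nB, n_both = length(both))
  }

  build <- function(sp, depth) {
    if (length(sp) == 1L) return(sp)
    at_cap <- !is.null(config$max_depth) && depth >= config$max_depth
    best <- NULL; best_code <- NULL
    if (!at_cap) {
      for (code in codes) {  # column order => deterministic tie-break
        cand <- score_split(sp, code)
        if (is.finite(cand$score) && (is.null(best) || cand$score > best$score)) {
          best <- cand; best_code <- code
        }
      }
    }
    if (is.null(best)) {
      if (!config$allow_multi_species_leaves) {
        dk_stop("dk_indistinguishable_taxa_error",
                sprintf("cannot separate taxa: %s", paste(sp, collapse = ", ")),
                taxa = sp)
      }
      return(sp)  # multi-species leaf
    }
    env$counter <- env$counter + 1L
    num <- env$counter
    env$log[[length(env$log) + 1L]] <- data.frame(
      couplet = num, character = best_code, score = best$score,
      n_taxa = length(sp), n_a = best$nA, n_b = best$nB,
      n_duplicated = best$n_both, stringsAsFactors = FALSE)
    a_target <- build(best$a, depth + 1L)
    b_target <- build(best$b, depth + 1L)
    env$couplets[[as.character(num)]] <- dk_couplet(
      num,
      list(dk_lead("a", best_code, "positive", a_target),
           dk_lead("b", best_code, "negative", b_target)))
    num
  }

  root <- build(matrix$species, 0L)
  if (is.character(root)) {
    dk_stop("dk_indistinguishable_taxa_error",
            sprintf("no character splits the matrix at all: %s",
                    paste(root, collapse = ", ")), taxa = root)
  }
  key <- dichotomous_key(unname(env$couplets))
  log <- do.call(rbind, env$log)
  list(key = key, log = log)
}

#' Compare two keys over the same species universe
#'
#' @param key_a,key_b Valid `dichotomous_key` objects whose leaf species sets
#'   are equal (after name normalization).
#' @return A `key_comparison` list: both metric sets, their deltas, the
#'   Jaccard overlap of characters used, and per-species depth differences.
#' @export
compare_keys <- function(key_a, key_b) {
  sa <- key_species(key_a); sb <- key_species(key_b)
  na <- dk_normalize_name(sa); nb <- dk_normalize_name(sb)
  if (!setequal(na, nb)) {
    dk_stop("dk_universe_mismatch_error",
            sprintf("species universes differ (only in A: %s; only in B: %s)",
                    paste(sa[!na %in% nb], collapse = ", "),
                    paste(sb[!nb %in% na], collapse = ", ")),
            only_in_a = sa[!na %in% nb], only_in_b = sb[!nb %in% na])
  }
  ma <- key_metrics(key_a); mb <- key_metrics(key_b)
  depth_of <- function(key) {
    paths <- dk_leaf_paths(key)
    d <- vapply(paths, function(p) length(p$steps), integer(1))
    nm <- dk_normalize_name(vapply(paths, `[[`, character(1), "species"))
    tapply(d, nm, min)  # a species duplicated into several leaves: best depth
  }
  da <- depth_of(key_a); db <- depth_of(key_b)
  common <- sort(intersect(names(da), names(db)))
  jac <- length(intersect(ma$characters_used, mb$characters_used)) /
    length(union(ma$characters_used, mb$characters_used))
  structure(list(
    metrics_a = ma, metrics_b = mb,
    delta = list(couplet_count = ma$couplet_count - mb$couplet_count,
                 max_depth = ma$max_depth - mb$max_depth,
                 mean_depth = ma$mean_depth - mb$mean_depth),
    character_jaccard = jac,
    species_depths = data.frame(species = common,
                                depth_a = as.integer(da[common]),
                                depth_b = as.integer(db[common]),
                                delta = as.integer(da[common] - db[common]))),
    class = "key_comparison")
}

#' @export
print.key_comparison <- function(x, ...) {
  cat(sprintf("key_comparison: %d vs %d couplets; character Jaccard %.2f\n",
              x$metrics_a$couplet_count, x$metrics_b$couplet_count,
              x$character_jaccard))
  cat(sprintf("  depth (max/mean): %d/%.2f vs %d/%.2f\n",
              x$metrics_a$max_depth, x$metrics_a$mean_depth,
              x$metrics_b$max_depth, x$metrics_b$mean_depth))
  invisible(x)
}
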