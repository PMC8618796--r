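# Shared toy builders and an independent brute-force traversal oracle.

toy_matrix <- function(tokens_by_row, codes = NULL) {
  # tokens_by_row: named list species -> character vector of tokens
  toks <- do.call(rbind, tokens_by_row)
  rownames(toks) <- names(tokens_by_row)
  colnames(toks) <- codes %||% sprintf("c%d", seq_len(ncol(toks)))
  character_matrix(toks)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-couplet key: couplet 1 on `code`, a -> sp_pos, b -> sp_neg
toy_key_1 <- function(code = "c1", sp_pos = "SpX", sp_neg = "SpY") {
  parse_key(sprintf('{
    "couplets": [
      {"number": 1, "leads": [
        {"label": "a", "character": "%s", "outcome": "positive", "target": {"species": "%s"}},
        {"label": "b", "character": "%s", "outcome": "negative", "target": {"species": "%s"}}
      ]}
    ]}', code, sp_pos, code, sp_neg))
}

# Brute-force oracle for reachable_leaves: enumerate every resolution of the
# row into definite +/- outcomes (per supported outcomes of each state) and
# walk the key deterministically for each. Independent re-implementation:
# it never calls reachable_leaves and does its own walking.
brute_force_leaves <- function(key, row, polarity = "default") {
  codes <- unique(unlist(lapply(key$couplets, function(cp) cp$leads[[1]]$character)))
  options_per_code <- lapply(codes, function(code) {
    tok <- if (code %in% names(row)) row[[code]] else "n"
    opts <- c("positive", "negative")
    opts[c(state_supports(tok, "positive", polarity),
           state_supports(tok, "negative", polarity))]
  })
  names(options_per_code) <- codes
  grid <- expand.grid(options_per_code, stringsAsFactors = FALSE)
  walk_one <- function(assignment) {
    cur <- key$root
    repeat {
      cp <- key$couplets[[as.character(cur)]]
      code <- cp$leads[[1]]$character
      want <- assignment[[code]]
      ld <- Filter(function(l) l$outcome == want, cp$leads)[[1]]
      if (ld$target_type == "species") return(ld$target)
      cur <- ld$target
    }
  }
  sort(unique(unlist(lapply(seq_len(nrow(grid)), function(i) {
    walk_one(as.list(grid[i, , drop = FALSE]))
  }))))
}
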