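#' Family-by-character matrix of nest states
#'
#' The central tabular container: one record per family, with a (possibly
#' polymorphic) state set for each of the three nest characters, a
#' missing-data reason, and a passerine flag. Families that are brood
#' parasites, mound builders, or lack data cannot be characterized: their
#' reason is not `"none"` and all three state sets must be empty; every
#' other record must carry at least one state per character.
#'
#' @param records A data frame with columns `family` (unique labels),
#'   `passerine` (logical), `missing_reason` (one of `none`,
#'   `brood_parasite`, `mound_builder`, `no_data`) and list-columns
#'   `structure`, `site`, `attachment` of state-label vectors.
#' @param variant `"all"` or `"effective"` (which state-coding rule produced
#'   the sets).
#' @return An object of class `character_matrix`.
#' @export
character_matrix <- function(records, variant = c("all", "effective")) {
  variant <- match.arg(variant)
  needed <- c("family", "passerine", "missing_reason", nest_characters())
  if (!all(needed %in% names(records)))
    stop_nestevo(paste("records must have columns:", paste(needed, collapse = ", ")),
                 "nestevo_input_error")
  records <- as.data.frame(records)[, needed]
  if (anyDuplicated(records$family))
    stop_nestevo("duplicate family records", "nestevo_duplicate_record")
  if (!all(records$missing_reason %in% missing_reasons()))
    stop_nestevo("invalid missing_reason", "nestevo_vocabulary_error")
  vocab <- nest_state_vocabulary()
  for (ch in nest_characters()) {
    col <- records[[ch]]
    if (!is.list(col)) col <- as.list(col)
    col <- lapply(col, function(s) {
      s <- as.character(s[!is.na(s)])
      s[nzchar(s)]
    })
    bad <- !vapply(col, function(s) all(s %in% vocab[[ch]]), logical(1))
    if (any(bad))
      stop_nestevo(sprintf("unknown %s state(s) for family '%s'", ch,
                           records$family[which(bad)[1]]),
                   "nestevo_vocabulary_error")
    records[[ch]] <- col
  }
  n_states <- vapply(nest_characters(), function(ch)
    as.numeric(lengths(records[[ch]])), numeric(nrow(records)))
  if (!is.matrix(n_states))
    n_states <- matrix(n_states, nrow = nrow(records),
                       ncol = length(nest_characters()))
  is_missing <- records$missing_reason != "none"
  if (any(is_missing & rowSums(n_states) > 0))
    stop_nestevo("families with a missing_reason must have empty state cells",
                 "nestevo_vocabulary_error")
  if (any(!is_missing & apply(n_states, 1, min) == 0))
    stop_nestevo("non-missing families need >= 1 state for every character",
                 "nestevo_invariant_error")
  structure(list(records = records, variant = variant),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  n <- nrow(x$records)
  cat(sprintf("character_matrix ('%s' variant): %d families (%d missing, %d passerine)\n",
              x$variant, n, sum(x$records$missing_reason != "none"),
              sum(x$records$passerine)))
  invisible(x)
}

#' @export
`==.character_matrix` <- function(e1, e2) {
  isTRUE(all.equal(e1$variant, e2$variant)) &&
    isTRUE(all.equal(e1$records, e2$records, check.attributes = FALSE))
}

#' Read / write a character matrix in the package CSV dialect
#'
#' The dialect is UTF-8 CSV with header
#' `family,passerine,missing_reason,structure,site,attachment`; multiple
#' states within a cell are separated by `|`; an empty cell means no data
#' (only allowed, and then required, when `missing_reason` is not `"none"`).
#'
#' @param path File path.
#' @param variant Variant tag for the matrix read (`"all"` or `"effective"`).
#' @return `read_character_matrix()` returns a `character_matrix`;
#'   `write_character_matrix()` invisibly returns `path`. The round trip
#'   `read(write(m))` reproduces `m`.
#' @export
read_character_matrix <- function(path, variant = c("all", "effective")) {
  variant <- match.arg(variant)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(df) == 0L) {
    rec <- data.frame(family = character(0), passerine = logical(0),
                      missing_reason = character(0))
    rec$structure <- list(); rec$site <- list(); rec$attachment <- list()
    return(character_matrix(rec, variant))
  }
  rec <- data.frame(family = df$family,
                    passerine = as.logical(df$passerine),
                    missing_reason = df$missing_reason,
                    stringsAsFactors = FALSE)
  for (ch in nest_characters())
    rec[[ch]] <- lapply(strsplit(df[[ch]], "|", fixed = TRUE),
                        function(s) s[nzchar(s)])
  character_matrix(rec, variant)
}

#' @rdname read_character_matrix
#' @param matrix A `character_matrix`.
#' @export
write_character_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "character_matrix"))
  rec <- matrix$records
  df <- data.frame(family = rec$family, passerine = rec$passerine,
                   missing_reason = rec$missing_reason,
                   stringsAsFactors = FALSE)
  for (ch in nest_characters())
    df[[ch]] <- vapply(rec[[ch]], paste, character(1), collapse = "|")
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' State sets of one character, as a named list
#'
#' @param matrix A `character_matrix`.
#' @param character One of `"structure"`, `"site"`, `"attachment"`.
#' @param drop_missing Drop families with no data for the character?
#' @return Named list of state-label vectors (missing families have
#'   `character(0)` unless dropped).
#' @export
state_sets <- function(matrix, character, drop_missing = FALSE) {
  stopifnot(inherits(matrix, "character_matrix"))
  check_character_name(character)
  out <- setNames(matrix$records[[character]], matrix$records$family)
  if (drop_missing) out <- out[lengths(out) > 0L]
  out
}

#' Derive the "effective" state set of a family from species-level records
#'
#' A state is *effective* when it is used by strictly more than
#' `threshold` (default 10%) of the species sampled for the family. Families
#' with at most `cap` species with data use all of them; larger families are
#' down-sampled to `cap` species spread approximately evenly across genera
#' (seeded round-robin over lexicographically sorted genera, species shuffled
#' within genus). The default `cap` of 50 is close to the mean number of
#' species per family (10,978 species / 242 families = 45).
#'
#' @param species_table Data frame with columns `species`, `genus` and
#'   `states` (character vector per species, either a list-column or
#'   `|`-separated strings). Species with no states are ignored.
#' @param threshold Effective-state fraction threshold in (0, 1).
#' @param cap Maximum number of species sampled per family.
#' @param seed Optional integer seed for the within-genus shuffle.
#' @return Character vector of effective states, ordered by decreasing
#'   species frequency; empty (with a warning) for an empty table.
#' @export
derive_effective_states <- function(species_table, threshold = 0.10, cap = 50L,
                                    seed = NULL) {
  if (!(threshold > 0 && threshold < 1))
    stop_nestevo("threshold must be in (0,1)", "nestevo_invalid_parameter")
  st <- as.data.frame(species_table)
  if (!is.list(st$states))
    st$states <- lapply(strsplit(as.character(st$states), "|", fixed = TRUE),
                        function(s) s[nzchar(s)])
  st <- st[lengths(st$states) > 0L, , drop = FALSE]
  if (nrow(st) == 0L) {
    warning("no species with state data; returning an empty state set")
    return(character(0))
  }
  if (nrow(st) > cap) {
    # round-robin across genera: sort genera, shuffle species within genus
    # (seeded), then take one species per genus per round until `cap`
    st <- with_seed(seed, {
      by_genus <- split(seq_len(nrow(st)), st$genus)
      by_genus <- by_genus[order(names(by_genus))]
      by_genus <- lapply(by_genus, function(ix) {
        ix <- ix[order(st$species[ix])]
        if (length(ix) > 1L) ix[sample.int(length(ix))] else ix
      })
      take <- integer(0)
      round <- 1L
      while (length(take) < cap) {
        avail <- unlist(lapply(by_genus, function(ix)
          if (length(ix) >= round) ix[round] else NULL))
        if (!length(avail)) break
        room <- cap - length(take)
        take <- c(take, avail[seq_len(min(room, length(avail)))])
        round <- round + 1L
      }
      st[sort(take), , drop = FALSE]
    })
  }
  n <- nrow(st)
  counts <- sort(table(unlist(lapply(st$states, unique))), decreasing = TRUE)
  eff <- names(counts)[counts / n > threshold]
  eff
}

#' Recode a multi-state character as binary
#'
#' Families whose state set is contained in `focal_states` (the ancestral
#' category) get `ancestral_label`; families whose set contains any state
#' outside it get `derived_label` — so a family polymorphic across the two
#' categories is coded as the later-derived state. Missing families stay
#' missing (`NA`).
#'
#' @param matrix A `character_matrix`.
#' @param character The character to recode.
#' @param focal_states Non-empty subset of the character's vocabulary
#'   defining the ancestral category.
#' @param derived_label,ancestral_label Labels for the two categories.
#' @return Named character vector family -> label (`NA` = missing).
#' @export
binary_recode <- function(matrix, character, focal_states, derived_label,
                          ancestral_label) {
  stopifnot(inherits(matrix, "character_matrix"))
  check_character_name(character)
  vocab <- nest_state_vocabulary()[[character]]
  if (length(focal_states) == 0L)
    stop_nestevo("focal_states must be non-empty", "nestevo_invalid_parameter")
  if (!all(focal_states %in% vocab))
    stop_nestevo("focal_states outside the character vocabulary",
                 "nestevo_vocabulary_error")
  sets <- state_sets(matrix, character)
  out <- vapply(sets, function(s) {
    if (length(s) == 0L) return(NA_character_)
    if (any(!s %in% focal_states)) derived_label else ancestral_label
  }, character(1))
  out
}

#' The three standard binary recodings of nest characters
#'
#' Named presets for the correlated-evolution case studies: scrape vs
#' non-scrape structure against ground vs non-ground site; cup vs non-cup
#' structure against non-tree-vegetation vs other sites; and cup/domed vs
#' other structures against basal vs non-basal attachment. In each preset,
#' trait A is the putative driver and trait B the putative follower, and the
#' derived category is coded 1.
#'
#' @return Named list of presets; each has `name`, `a` and `b`, where `a` and
#'   `b` give the `character`, `focal_states` (ancestral category) and the
#'   two labels for [binary_recode()].
#' @export
nest_recode_presets <- function() {
  vocab <- nest_state_vocabulary()
  list(
    scrape_x_ground = list(
      name = "scrape_x_ground",
      a = list(character = "structure", focal_states = "scrape",
               derived_label = "non-scrape", ancestral_label = "scrape"),
      b = list(character = "site", focal_states = "ground",
               derived_label = "non-ground", ancestral_label = "ground")),
    cup_x_nontree_vegetation = list(
      name = "cup_x_nontree_vegetation",
      a = list(character = "structure",
               focal_states = setdiff(vocab$structure, "cup"),
               derived_label = "cup", ancestral_label = "non-cup"),
      b = list(character = "site",
               focal_states = setdiff(vocab$site, "non-tree vegetation"),
               derived_label = "non-tree vegetation",
               ancestral_label = "other site")),
    cup_dome_x_nonbasal = list(
      name = "cup_dome_x_nonbasal",
      a = list(character = "structure",
               focal_states = setdiff(vocab$structure,
                                      c("cup", "simple dome", "dome with tunnel")),
               derived_label = "cup/domed", ancestral_label = "other structure"),
      b = list(character = "attachment", focal_states = "basal",
               derived_label = "non-basal", ancestral_label = "basal"))
  )
}

#' Per-state frequencies of a character across families
#'
#' For every state of the character: the proportion of families whose state
#' set is exactly that state (*exclusive*) and the proportion whose set
#' contains it (*inclusive*). Proportions are over families with data for the
#' character by default; `denominator = "all"` uses every family.
#'
#' @param matrix A `character_matrix`.
#' @param character The character to summarize.
#' @param denominator `"with_data"` (default) or `"all"`.
#' @return Data frame with columns `state`, `n_exclusive`, `n_inclusive`,
#'   `p_exclusive`, `p_inclusive`; empty (with a warning) when no family has
#'   data.
#' @export
state_frequencies <- function(matrix, character,
                              denominator = c("with_data", "all")) {
  stopifnot(inherits(matrix, "character_matrix"))
  check_character_name(character)
  denominator <- match.arg(denominator)
  vocab <- nest_state_vocabulary()[[character]]
  sets <- state_sets(matrix, character)
  with_data <- sets[lengths(sets) > 0L]
  if (!length(with_data)) {
    warning(sprintf("no family has data for '%s'", character))
    return(data.frame(state = character(0), n_exclusive = integer(0),
                      n_inclusive = integer(0), p_exclusive = numeric(0),
                      p_inclusive = numeric(0)))
  }
  denom <- if (denominator == "all") length(sets) else length(with_data)
  n_ex <- vapply(vocab, function(s)
    as.numeric(sum(vapply(with_data, function(set) identical(set, s), logical(1)))),
    numeric(1))
  n_in <- vapply(vocab, function(s)
    as.numeric(sum(vapply(with_data, function(set) s %in% set, logical(1)))),
    numeric(1))
  data.frame(state = vocab, n_exclusive = n_ex, n_inclusive = n_in,
             p_exclusive = n_ex / denom, p_inclusive = n_in / denom,
             row.names = NULL)
}
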