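#' State vocabularies for the three nest characters
#'
#' The fixed coding scheme for avian nests: seven structure types, seven site
#' types, and four attachment approaches. These vocabularies validate every
#' character matrix read or built by the package.
#'
#' @return A named list with elements `structure`, `site` and `attachment`,
#'   each an ordered character vector of state labels.
#' @examples
#' nest_state_vocabulary()$attachment
#' @export
nest_state_vocabulary <- function() {
  list(
    structure = c("scrape", "platform", "cup", "simple dome",
                  "dome with tunnel", "primary cavity", "secondary cavity"),
    site = c("ground", "tree", "non-tree vegetation", "cliff/bank",
             "underground", "water bodies", "termite/ant nests"),
    attachment = c("basal", "lateral", "horizontally forked", "pensile")
  )
}

#' @rdname nest_state_vocabulary
#' @param path File to write the vocabulary to, as JSON (for validation by
#'   external tools).
#' @export
write_nest_vocabulary <- function(path) {
  jsonlite::write_json(nest_state_vocabulary(), path, pretty = TRUE)
  invisible(path)
}

nest_characters <- function() names(nest_state_vocabulary())

missing_reasons <- function() c("none", "brood_parasite", "mound_builder", "no_data")

check_character_name <- function(character) {
  if (!character %in% nest_characters())
    stop_nestevo(sprintf("unknown character '%s'", character), "nestevo_vocabulary_error")
  character
}
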