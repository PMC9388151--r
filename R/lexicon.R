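#' Create an ingredient-name lexicon
#'
#' Maps normalized free-text ingredient names to environmental-database
#' food categories.  `entries` are exact synonym matches; `fallbacks` map
#' broad class keywords (e.g. "vegetable", "fruit") to aggregate
#' categories such as "other vegetables" and are tried, longest keyword
#' first, when no exact synonym matches.
#'
#' @param entries `data.frame` with columns `synonym`, `category_id`.
#' @param fallbacks Optional `data.frame` with columns `keyword`,
#'   `category_id`.
#' @return An object of class `lexicon`.
#' @export
lexicon <- function(entries, fallbacks = NULL) {
  entries <- as.data.frame(entries)
  stopifnot(all(c("synonym", "category_id") %in% names(entries)))
  entries$synonym <- vapply(entries$synonym,
                            function(s) normalize_name(s)$name, character(1))
  entries <- entries[nzchar(entries$synonym), ]
  entries <- entries[!duplicated(entries$synonym), ]
  if (!is.null(fallbacks)) {
    fallbacks <- as.data.frame(fallbacks)
    stopifnot(all(c("keyword", "category_id") %in% names(fallbacks)))
    fallbacks$keyword <- tolower(trimws(fallbacks$keyword))
    fallbacks <- fallbacks[order(-nchar(fallbacks$keyword)), ]
  }
  structure(list(entries = entries, fallbacks = fallbacks), class = "lexicon")
}

#' Read a lexicon from CSV resources
#' @param path CSV with columns `synonym`, `category_id`.
#' @param fallback_path Optional CSV with columns `keyword`, `category_id`.
#' @return A [lexicon()].
#' @export
read_lexicon <- function(path, fallback_path = NULL) {
  entries <- read.csv(path, stringsAsFactors = FALSE)
  fallbacks <- if (!is.null(fallback_path))
    read.csv(fallback_path, stringsAsFactors = FALSE)
  lexicon(entries, fallbacks)
}

#' The starter lexicon shipped with the package
#'
#' Covers the synthetic category set (identity names plus common label
#' synonyms) and aggregate fallbacks; user-extensible by editing copies of
#' the CSV resources.
#' @return A [lexicon()].
#' @export
default_lexicon <- function() {
  read_lexicon(
    system.file("extdata", "lexicon.csv", package = "foodprint"),
    system.file("extdata", "lexicon_fallbacks.csv", package = "foodprint"))
}

#' Normalize a free-text ingredient name
#'
#' Lowercases, strips percent annotations, digits and punctuation, removes
#' parenthetical sub-ingredient lists (returned separately), and detects
#' and removes an "organic" token.
#'
#' @param raw Free-text name, e.g. `"Organic Tomatoes (32%)"`.
#' @return List with `name` (normalized), `organic` (logical) and
#'   `sub_names` (normalized parenthetical sub-ingredients, if any).
#' @export
normalize_name <- function(raw) {
  if (is.null(raw) || is.na(raw)) raw <- ""
  x <- tolower(as.character(raw))
  subs <- regmatches(x, gregexpr("\\(([^)]*)\\)", x))[[1]]
  sub_names <- character()
  if (length(subs)) {
    inner <- gsub("[()]", "", subs)
    parts <- trimws(unlist(strsplit(inner, ",", fixed = TRUE)))
    sub_names <- vapply(parts[nzchar(parts)],
                        function(p) normalize_name(p)$name, character(1),
                        USE.NAMES = FALSE)
    sub_names <- sub_names[nzchar(sub_names)]
  }
  x <- gsub("\\([^)]*\\)", " ", x)        # drop parenthetical sub-lists
  x <- gsub("[0-9]+([.][0-9]+)?\\s*%?", " ", x)  # percent annotations
  x <- gsub("[^a-z ]", " ", x)
  organic <- grepl("\\borganic\\b", x)
  x <- gsub("\\borganic\\b", " ", x)
  x <- gsub("\\s+", " ", trimws(x))
  list(name = x, organic = organic, sub_names = sub_names)
}

map_name <- function(name, lex) {
  if (!nzchar(name)) return(NA_character_)
  hit <- match(name, lex$entries$synonym)
  if (!is.na(hit)) return(lex$entries$category_id[hit])
  if (!is.null(lex$fallbacks) && nrow(lex$fallbacks)) {
    for (i in seq_len(nrow(lex$fallbacks))) {
      if (grepl(lex$fallbacks$keyword[i], name, fixed = TRUE))
        return(lex$fallbacks$category_id[i])
    }
  }
  NA_character_
}

#' Map one ingredient to a food category
#'
#' Exact synonym match on the normalized name is preferred; otherwise the
#' longest matching aggregate-fallback keyword; otherwise unmapped (`NA`).
#' Compound ingredients are flattened: the parent name is mapped and the
#' parenthetical sub-ingredients are ignored unless the parent is
#' unmapped, in which case the first mappable sub-ingredient is used.
#'
#' @param entry An [ingredient_entry()] or a character name.
#' @param lex A [lexicon()].
#' @return List with `category_id` (or `NA`) and `organic` flag.
#' @export
map_ingredient <- function(entry, lex) {
  name <- if (inherits(entry, "ingredient_entry")) entry$name else entry
  norm <- normalize_name(name)
  cid <- map_name(norm$name, lex)
  if (is.na(cid) && length(norm$sub_names)) {
    for (s in norm$sub_names) {
      cid <- map_name(s, lex)
      if (!is.na(cid)) break
    }
  }
  organic <- norm$organic ||
    (inherits(entry, "ingredient_entry") && isTRUE(entry$organic))
  list(category_id = cid, organic = organic)
}

#' Assign food categories to every ingredient of a corpus
#'
#' Deterministic, case- and whitespace-insensitive; mapping a corpus twice
#' yields identical assignments.  Existing `category_id` values are
#' overwritten.
#'
#' @param products List of [product_record()] objects.
#' @param lex A [lexicon()]; defaults to the shipped starter lexicon.
#' @return The corpus with `category_id` and `organic` filled in.
#' @export
map_products <- function(products, lex = default_lexicon()) {
  lapply(products, function(p) {
    p$ingredients <- lapply(p$ingredients, function(ig) {
      m <- map_ingredient(ig, lex)
      ig$category_id <- m$category_id
      ig$organic <- m$organic
      ig
    })
    p
  })
}
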