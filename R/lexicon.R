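#' Build an animal-name lexicon
#'
#' The lexicon drives token normalization: mapping raw spoken forms (plurals,
#' multiword names) onto canonical singular animal names, and deciding which
#' tokens are animal names at all. Name lookups are entirely local, so runs
#' are reproducible with no network dependency.
#'
#' @param canonical Character vector of canonical singular names (may contain
#'   spaces for multiword names such as `"mountain lion"`).
#' @param plural_map Named character vector mapping an irregular plural form to
#'   its canonical name (e.g. `c(hippopotami = "hippopotamus", oxen = "ox")`).
#'   Regular plurals are handled by suffix stemming and need not be listed.
#' @return An object of class `vf_lexicon`.
#' @export
vf_lexicon <- function(canonical, plural_map = character()) {
  canonical <- unique(tolower(trimws(canonical)))
  canonical <- canonical[nzchar(canonical)]
  plural_map <- vapply(plural_map, tolower, "")
  if (length(plural_map) > 0L) {
    names(plural_map) <- tolower(names(plural_map))
    bad <- setdiff(unname(plural_map), canonical)
    if (length(bad) > 0L) {
      stop_vf("plural_map value(s) not canonical names: ",
              paste(bad, collapse = ", "), class = "validation")
    }
  }
  multiword <- canonical[grepl(" ", canonical, fixed = TRUE)]
  structure(
    list(canonical = canonical,
         plural_map = plural_map,
         multiword = multiword,
         max_words = max(1L, lengths(strsplit(multiword, " ", fixed = TRUE)))),
    class = "vf_lexicon"
  )
}

#' @export
print.vf_lexicon <- function(x, ...) {
  cat("<vf_lexicon> ", length(x$canonical), " canonical names (",
      length(x$multiword), " multiword, ", length(x$plural_map),
      " irregular plurals)\n", sep = "")
  invisible(x)
}

#' Read / write a lexicon TSV
#'
#' The TSV has a `name` column of canonical singular names and an optional
#' `plural` column listing an irregular plural form for that name (empty for
#' regularly inflected names).
#'
#' @param path Path to the lexicon TSV.
#' @return `load_lexicon()` returns a [vf_lexicon()] object.
#' @export
load_lexicon <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_cols(df, "name", "lexicon file")
  plural_map <- character()
  if ("plural" %in% names(df)) {
    has <- !is.na(df$plural) & nzchar(df$plural)
    plural_map <- stats::setNames(tolower(df$name[has]), tolower(df$plural[has]))
  }
  vf_lexicon(df$name, plural_map)
}

#' @rdname load_lexicon
#' @param lexicon A [vf_lexicon()] object.
#' @export
write_lexicon <- function(lexicon, path) {
  inv <- character(length(lexicon$canonical))
  names(inv) <- lexicon$canonical
  if (length(lexicon$plural_map) > 0L) {
    inv[unname(lexicon$plural_map)] <- names(lexicon$plural_map)
  }
  readr::write_tsv(
    tibble::tibble(name = lexicon$canonical,
                   plural = unname(inv[lexicon$canonical])),
    path, na = ""
  )
  invisible(lexicon)
}

# conservative suffix stemmer: a rule fires only when the stemmed form is a
# known canonical name, so names like "moose" survive untouched
stem_candidates <- function(word) {
  out <- character()
  if (grepl("ies$", word)) out <- c(out, sub("ies$", "y", word))
  if (grepl("es$", word)) out <- c(out, sub("es$", "", word))
  if (grepl("s$", word)) out <- c(out, sub("s$", "", word))
  out
}

#' Normalize raw tokens to a canonical animal name
#'
#' Lookup order: multiword match on the joined tokens (with the final word
#' de-pluralized if needed), then the irregular-plural map, then conservative
#' suffix stemming (`-ies`, `-es`, `-s`, applied only when the stem is in the
#' lexicon), then exact lookup. Anything that resolves to no canonical name is
#' a non-animal token.
#'
#' @param raw_tokens Character vector of one or more lower-cased raw tokens
#'   forming a single candidate name (length > 1 for a multiword candidate).
#' @param lexicon A [vf_lexicon()].
#' @return The canonical singular name, or `NA_character_` for a non-animal.
#' @examples
#' lex <- vf_lexicon(c("pig", "ox", "mountain lion"), c(oxen = "ox"))
#' normalize_name("pigs", lex)
#' normalize_name(c("mountain", "lions"), lex)
#' @export
normalize_name <- function(raw_tokens, lexicon) {
  raw_tokens <- tolower(raw_tokens)
  if (length(raw_tokens) > 1L) {
    joined <- paste(raw_tokens, collapse = " ")
    if (joined %in% lexicon$multiword) return(joined)
    last <- raw_tokens[length(raw_tokens)]
    for (cand in stem_candidates(last)) {
      j <- paste(c(raw_tokens[-length(raw_tokens)], cand), collapse = " ")
      if (j %in% lexicon$multiword) return(j)
    }
    return(NA_character_)
  }
  word <- raw_tokens
  if (word %in% names(lexicon$plural_map)) {
    return(unname(lexicon$plural_map[[word]]))
  }
  for (cand in stem_candidates(word)) {
    if (cand %in% lexicon$canonical) return(cand)
  }
  if (word %in% lexicon$canonical) return(word)
  NA_character_
}

#' Classify and merge tokens of a response
#'
#' Tags every token as `animal` or `non_animal` and merges runs of consecutive
#' participant tokens that form one multiword animal name (longest match
#' first) into a single token whose onset is the first word's onset and whose
#' duration is the sum of the constituents. Examiner tokens are always
#' non-animal. Token order and the onsets of unmerged tokens are untouched.
#'
#' @param tokens A token tibble (see [read_ctm()]), one or many subjects.
#' @param lexicon A [vf_lexicon()].
#' @return The token tibble with `token_class` and `name` (canonical name, NA
#'   for non-animals) columns added; multiword names occupy one row.
#' @export
classify_tokens <- function(tokens, lexicon) {
  assert_cols(tokens, c("subject_id", "word", "onset", "duration", "speaker"),
              "token table")
  tokens |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(~ classify_one(.x, lexicon)) |>
    dplyr::ungroup()
}

classify_one <- function(tok, lexicon) {
  n <- nrow(tok)
  out <- vector("list", n)
  i <- 1L
  k <- 0L
  while (i <= n) {
    row <- tok[i, ]
    if (row$speaker == "examiner") {
      row$token_class <- "non_animal"; row$name <- NA_character_
      k <- k + 1L; out[[k]] <- row; i <- i + 1L
      next
    }
    matched <- FALSE
    # longest multiword window of consecutive participant tokens first
    wmax <- min(lexicon$max_words, n - i + 1L)
    for (w in if (wmax >= 2L) seq(wmax, 2L) else integer()) {
      window <- tok[i:(i + w - 1L), ]
      if (any(window$speaker != "participant")) next
      name <- normalize_name(window$word, lexicon)
      if (!is.na(name)) {
        merged <- window[1L, ]
        merged$word <- paste(window$word, collapse = " ")
        merged$duration <- sum(window$duration)
        merged$token_class <- "animal"
        merged$name <- name
        k <- k + 1L; out[[k]] <- merged
        i <- i + w
        matched <- TRUE
        break
      }
    }
    if (matched) next
    name <- normalize_name(row$word, lexicon)
    row$token_class <- if (is.na(name)) "non_animal" else "animal"
    row$name <- name
    k <- k + 1L; out[[k]] <- row; i <- i + 1L
  }
  dplyr::bind_rows(out[seq_len(k)])
}

#' Build or load a semantic subcategory table
#'
#' A subcategory table assigns each canonical animal name to between one and
#' four semantic subcategories (e.g. pets, birds, African animals). Two names
#' are table-similar when their subcategory sets intersect; this is the
#' rule-based alternative to embedding similarity for cluster/switch
#' segmentation.
#'
#' @param assignments A data frame with columns `name` and `subcategory`, one
#'   row per name-subcategory pair.
#' @return An object of class `vf_category_table`.
#' @export
as_category_table <- function(assignments) {
  assert_cols(assignments, c("name", "subcategory"), "category table")
  if (nrow(assignments) == 0L) {
    stop_vf("category table is empty", class = "validation")
  }
  assignments <- dplyr::distinct(
    dplyr::mutate(assignments,
                  name = tolower(.data$name),
                  subcategory = tolower(.data$subcategory))
  )
  sets <- split(assignments$subcategory, assignments$name)
  too_many <- names(sets)[lengths(sets) > 4L]
  if (length(too_many) > 0L) {
    stop_vf("name(s) assigned to more than 4 subcategories: ",
            paste(too_many, collapse = ", "), class = "validation")
  }
  structure(
    list(assignments = sets,
         subcategories = sort(unique(assignments$subcategory))),
    class = "vf_category_table"
  )
}

#' @rdname as_category_table
#' @param path Path to a TSV with columns `name`, `subcategory`.
#' @export
load_category_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  as_category_table(df)
}

#' @rdname as_category_table
#' @param table A `vf_category_table`.
#' @export
write_category_table <- function(table, path) {
  df <- tibble::tibble(
    name = rep(names(table$assignments), lengths(table$assignments)),
    subcategory = unlist(table$assignments, use.names = FALSE)
  )
  readr::write_tsv(df, path)
  invisible(table)
}

#' @export
print.vf_category_table <- function(x, ...) {
  cat("<vf_category_table> ", length(x$assignments), " names in ",
      length(x$subcategories), " subcategories\n", sep = "")
  invisible(x)
}

#' Subcategory lookup
#'
#' @param name A canonical animal name.
#' @param table A [as_category_table()] object.
#' @return Character vector of subcategory labels (length 0 if unknown).
#' @export
subcategories_of <- function(name, table) {
  table$assignments[[tolower(name)]] %||% character()
}
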