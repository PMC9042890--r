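#' Read a molecular interaction map from files
#'
#' Loads a map from an element file and an interaction file in either of two
#' documented dialects:
#'
#' * **json** — two UTF-8 JSON files. The element file is an array of objects
#'   `{"id", "name", "type", "submaps": [...], "xrefs": {...}}` (only `id` is
#'   required); the interaction file is an array of objects
#'   `{"source", "sign", "target", "class"}` with `sign` being `-1` or `1`.
#'   This schema is a documented stand-in for map-server exports; an adapter
#'   for a specific server dump can be layered on top without touching the
#'   loader.
#' * **tsv** — tab-separated files with a header row; lines starting with
#'   `#` are ignored. Element columns: `id`, `name`, `bio_type`, `submaps`
#'   (`;`-separated list, may be empty). Interaction columns: `source`,
#'   `sign`, `target`, `class`.
#'
#' Loading is row-order independent: any permutation of input rows produces
#' an identical graph (and an identical canonical serialization via
#' [write_mim()]). Dangling endpoint ids, signs outside `{-1, +1}`, duplicate
#' element ids and self-loops are load errors naming the offender.
#'
#' @param elements_path,interactions_path File paths.
#' @param format `"json"` or `"tsv"`.
#' @param quiet Passed to [mim_graph()].
#' @return A [mim_graph].
#' @seealso [write_mim()] for the canonical writer.
#' @export
read_mim <- function(elements_path, interactions_path,
                     format = c("json", "tsv"), quiet = FALSE) {
  format <- match.arg(format)
  for (p in c(elements_path, interactions_path)) {
    if (!file.exists(p)) {
      stop_twodea(sprintf("file not found: %s", p),
                  class = "twodea_load_error")
    }
  }
  if (format == "json") {
    el <- jsonlite::fromJSON(elements_path, simplifyDataFrame = FALSE)
    ia <- jsonlite::fromJSON(interactions_path, simplifyDataFrame = FALSE)
    elements <- tibble(
      id = purrr::map_chr(el, ~ as.character(.x$id %||% NA_character_)),
      name = purrr::map_chr(el, ~ as.character(.x$name %||% .x$id)),
      bio_type = purrr::map_chr(el, ~ as.character(.x$type %||% "other")),
      submaps = purrr::map(el, ~ as.character(unlist(.x$submaps))),
      xrefs = purrr::map(el, "xrefs")
    )
    has_class <- any(purrr::map_lgl(ia, ~ !is.null(.x$class)))
    interactions <- tibble(
      source = purrr::map_chr(ia, ~ as.character(.x$source %||% NA_character_)),
      sign = purrr::map_chr(ia, ~ as.character(.x$sign %||% NA_character_)),
      target = purrr::map_chr(ia, ~ as.character(.x$target %||% NA_character_))
    )
    if (has_class) {
      interactions$iclass <- purrr::map_chr(
        ia, ~ as.character(.x$class %||% "generic"))
    }
  } else {
    elements <- read_tsv_dialect(elements_path)
    interactions <- read_tsv_dialect(interactions_path)
    if ("class" %in% names(interactions)) {
      interactions <- rename(interactions, iclass = "class")
    }
  }
  mim_graph(elements, interactions, quiet = quiet)
}

read_tsv_dialect <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) < 1L) {
    stop_twodea(sprintf("no header row in %s", path),
                class = "twodea_load_error")
  }
  tab <- utils::read.delim(text = lines, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", stringsAsFactors = FALSE)
  as_tibble(tab)
}

#' Write a molecular interaction map in canonical form
#'
#' Serialization is canonical — elements sorted by id, interactions by
#' (source, target, sign) — so two graphs with the same element and edge sets
#' produce byte-identical files, and load/serialize/load round-trips exactly.
#'
#' @param graph A [mim_graph].
#' @param elements_path,interactions_path Output paths.
#' @param format `"json"` or `"tsv"`.
#' @return Invisibly, the two paths.
#' @export
write_mim <- function(graph, elements_path, interactions_path,
                      format = c("json", "tsv")) {
  format <- match.arg(format)
  el <- arrange(graph$elements, .data$id)
  ia <- arrange(graph$interactions, .data$source, .data$target, .data$sign)
  if (format == "json") {
    el_list <- purrr::pmap(el, function(id, name, bio_type, submaps, xrefs) {
      out <- list(id = jsonlite::unbox(id), name = jsonlite::unbox(name),
                  type = jsonlite::unbox(bio_type), submaps = as.list(submaps))
      if (!is.null(xrefs) && length(xrefs)) out$xrefs <- xrefs
      out
    })
    ia_list <- purrr::pmap(ia, function(source, sign, target, iclass) {
      list(source = jsonlite::unbox(source), sign = jsonlite::unbox(sign),
           target = jsonlite::unbox(target), class = jsonlite::unbox(iclass))
    })
    writeLines(jsonlite::toJSON(el_list, pretty = TRUE), elements_path,
               useBytes = TRUE)
    writeLines(jsonlite::toJSON(ia_list, pretty = TRUE), interactions_path,
               useBytes = TRUE)
  } else {
    el_out <- mutate(el,
                     submaps = purrr::map_chr(.data$submaps, paste,
                                              collapse = ";"))
    el_out <- select(el_out, "id", "name", "bio_type", "submaps")
    write_tsv_plain(el_out, elements_path)
    ia_out <- select(ia, "source", "sign", "target", class = "iclass")
    write_tsv_plain(ia_out, interactions_path)
  }
  invisible(c(elements_path, interactions_path))
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
}

#' Match data symbols to graph element ids
#'
#' Exact id matches take priority; remaining symbols are matched
#' case-insensitively on element `name` (gene-symbol case differs between
#' species conventions). Ambiguous case-insensitive name matches are treated
#' as unmatched.
#'
#' @param graph A [mim_graph].
#' @param symbols Character vector.
#' @return Character vector of element ids, `NA` where unmatched.
#' @export
match_symbols <- function(graph, symbols) {
  symbols <- as.character(symbols)
  out <- ifelse(symbols %in% graph$elements$id, symbols, NA_character_)
  todo <- which(is.na(out))
  if (length(todo)) {
    lower_names <- tolower(graph$elements$name)
    for (i in todo) {
      hit <- which(lower_names == tolower(symbols[i]))
      if (length(hit) == 1L) out[i] <- graph$elements$id[hit]
    }
  }
  out
}
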