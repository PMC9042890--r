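#' Read a differential-change data table
#'
#' Parses the tab-delimited upload format: a header row with a `symbol`
#' column followed by `FC_<sample>` / `padj_<sample>` column pairs, one pair
#' per sample, UTF-8, `#` comment lines ignored. Fold changes are signed
#' log2 values; `padj` are multiple-testing-adjusted p-values in `[0, 1]`.
#'
#' @param path File path.
#' @return A long tibble with columns `symbol`, `sample`, `fc`, `adj_p`.
#' @export
read_dce_table <- function(path) {
  if (!file.exists(path)) {
    stop_twodea(sprintf("file not found: %s", path),
                class = "twodea_data_error")
  }
  tab <- read_tsv_dialect(path)
  dce_long(tab, path = path)
}

dce_long <- function(tab, path = "<data>") {
  tab <- as_tibble(tab)
  if (all(c("symbol", "sample", "fc", "adj_p") %in% names(tab))) {
    tab$fc <- as.numeric(tab$fc)
    tab$adj_p <- as.numeric(tab$adj_p)
    return(tab[, c("symbol", "sample", "fc", "adj_p")])
  }
  if (!"symbol" %in% names(tab)) {
    stop_twodea(sprintf("%s: no `symbol` column in data table.", path),
                class = "twodea_data_error")
  }
  fc_cols <- grep("^FC_", names(tab), value = TRUE)
  p_cols <- grep("^padj_", names(tab), value = TRUE)
  samples <- sub("^FC_", "", fc_cols)
  if (!length(samples) || !setequal(samples, sub("^padj_", "", p_cols))) {
    stop_twodea(sprintf(
      "%s: need matching FC_<sample> / padj_<sample> column pairs.", path),
      class = "twodea_data_error")
  }
  out <- purrr::map_dfr(samples, function(s) {
    fc <- suppressWarnings(as.numeric(tab[[paste0("FC_", s)]]))
    pv <- suppressWarnings(as.numeric(tab[[paste0("padj_", s)]]))
    bad <- which(xor(is.na(fc), is.na(pv)))
    if (length(bad)) {
      stop_twodea(sprintf("%s: malformed FC/padj pair for sample '%s' at line %d.",
                          path, s, bad[1] + 1L),
                  class = "twodea_data_error")
    }
    tibble(symbol = as.character(tab$symbol), sample = s, fc = fc, adj_p = pv)
  })
  out[!is.na(out$fc), , drop = FALSE]
}

#' Write a wide differential-change table
#'
#' Inverse of [read_dce_table()]: writes `symbol` plus `FC_<sample>` /
#' `padj_<sample>` pairs, tab-separated.
#' @param data Long tibble (`symbol`, `sample`, `fc`, `adj_p`) or an
#'   already-wide data frame.
#' @param path Output file.
#' @export
write_dce_table <- function(data, path) {
  data <- as_tibble(data)
  if (all(c("symbol", "sample", "fc", "adj_p") %in% names(data))) {
    wide <- tidyr::pivot_wider(data, id_cols = "symbol",
                               names_from = "sample",
                               values_from = c("fc", "adj_p"),
                               names_glue = "{ifelse(.value == 'fc', 'FC', 'padj')}_{sample}")
    ord <- c("symbol",
             unlist(lapply(unique(data$sample),
                           function(s) paste0(c("FC_", "padj_"), s))))
    wide <- wide[, ord]
  } else {
    wide <- data
  }
  write_tsv_plain(wide, path)
  invisible(path)
}

#' Filter differentially changed elements for one sample
#'
#' Applies the significance and effect-size filters (`adj_p < p_threshold`,
#' `|FC| > abs_fc_threshold`) to one sample's rows and matches symbols to
#' graph element ids via [match_symbols()]. Unmatched symbols are reported
#' in the `unmatched` attribute, never silently dropped. Duplicate matches
#' to the same element keep the entry with the smallest adjusted p
#' (ties broken by symbol).
#'
#' The defaults mirror common differential-expression practice: adjusted
#' p < 0.05, no fold-change floor; transcriptomics case work typically adds
#' `abs_fc_threshold = 1` (i.e. |log2 FC| > 1).
#'
#' @param data Long tibble from [read_dce_table()], or a wide data frame in
#'   the same dialect.
#' @param sample Sample label to extract.
#' @param graph A [mim_graph] used for symbol matching.
#' @param p_threshold Keep entries with `adj_p` strictly below this.
#' @param abs_fc_threshold Keep entries with `|fc|` strictly above this.
#' @param bio_type Optional restriction of matched elements to these
#'   biological types.
#' @return A `dce_set`: tibble (`element`, `symbol`, `fc`, `adj_p`) with
#'   attributes `sample`, `p_threshold`, `abs_fc_threshold`, `unmatched`.
#' @export
filter_dces <- function(data, sample, graph, p_threshold = 0.05,
                        abs_fc_threshold = 0, bio_type = NULL) {
  long <- dce_long(data)
  rows <- long[long$sample == sample, , drop = FALSE]
  if (!nrow(rows)) {
    stop_twodea(sprintf("sample '%s' not present in the data table.", sample),
                class = "twodea_data_error")
  }
  rows <- rows[!is.na(rows$adj_p) & rows$adj_p < p_threshold &
                 abs(rows$fc) > abs_fc_threshold, , drop = FALSE]
  rows$element <- match_symbols(graph, rows$symbol)
  if (!is.null(bio_type)) {
    et <- element_type(graph, rows$element)
    rows$element[!is.na(rows$element) & !(et %in% bio_type)] <- NA_character_
  }
  unmatched <- sort(unique(rows$symbol[is.na(rows$element)]))
  rows <- rows[!is.na(rows$element), , drop = FALSE]
  rows <- arrange(rows, .data$element, .data$adj_p, .data$symbol)
  rows <- rows[!duplicated(rows$element), , drop = FALSE]
  out <- rows[, c("element", "symbol", "fc", "adj_p")]
  structure(out,
            class = c("dce_set", class(out)),
            sample = sample,
            p_threshold = p_threshold,
            abs_fc_threshold = abs_fc_threshold,
            unmatched = unmatched)
}

#' Construct a DCE set directly from element ids
#'
#' Convenience constructor for simulated or user-assumed differential
#' changes that are already expressed as graph element ids.
#' @param element Character vector of element ids.
#' @param fc Signed log2 fold changes.
#' @param adj_p Adjusted p-values (defaults to 0 for assumed changes).
#' @param sample Sample label.
#' @return A `dce_set` tibble.
#' @export
dce_set <- function(element, fc, adj_p = rep(0, length(element)),
                    sample = "sample1") {
  if (anyDuplicated(element)) {
    stop_twodea("duplicate element ids in DCE set.",
                class = "twodea_usage_error")
  }
  structure(
    tibble(element = as.character(element), symbol = as.character(element),
           fc = as.numeric(fc), adj_p = as.numeric(adj_p)),
    class = c("dce_set", "tbl_df", "tbl", "data.frame"),
    sample = sample, p_threshold = NA_real_, abs_fc_threshold = NA_real_,
    unmatched = character())
}

#' @export
print.dce_set <- function(x, ...) {
  cat(sprintf("<dce_set> sample '%s': %d element(s), %d unmatched symbol(s)\n",
              attr(x, "sample"), nrow(x), length(attr(x, "unmatched"))))
  NextMethod()
}
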