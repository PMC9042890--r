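#' @importFrom rlang %||% abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange mutate filter select distinct bind_rows group_by
#'   summarise ungroup left_join n rename all_of across
#' @importFrom stats p.adjust rnorm runif setNames
#' @importFrom utils head
NULL

# single source of truth for the element and interaction vocabularies
BIO_TYPES <- c("gene", "protein", "metabolite", "phenotype", "complex",
               "miRNA", "lncRNA", "other")
INTERACTION_CLASSES <- c("transcriptional", "catalytic", "generic")

`%||%` <- rlang::`%||%`

stop_twodea <- function(msg, class = "twodea_error", ...) {
  rlang::abort(msg, class = c(class, "twodea_error"), ...)
}

assert_scalar_chr <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop_twodea(sprintf("`%s` must be a single non-missing string.", what),
                class = "twodea_usage_error")
  }
  invisible(x)
}

# seeded evaluation that never leaks into the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}
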