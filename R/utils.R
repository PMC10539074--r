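#' @useDynLib tadcons, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods as is
#' @importFrom stats setNames
#' @importFrom utils read.table write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Split a species-prefixed identifier
#'
#' Identifiers created by the package are of the form `"<species>|<token>"`.
#'
#' @param x character vector of prefixed ids
#' @return data.frame with columns `species` and `token`
#' @keywords internal
split_prefixed_id <- function(x) {
  pos <- regexpr("|", x, fixed = TRUE)
  bad <- pos < 0L
  if (any(bad)) {
    stop("identifier(s) lack a species prefix: ",
         paste(utils::head(x[bad], 3), collapse = ", "))
  }
  data.frame(species = substr(x, 1L, pos - 1L),
             token = substr(x, pos + 1L, nchar(x)),
             stringsAsFactors = FALSE)
}

species_of <- function(x) split_prefixed_id(x)$species

#' Write a data frame as a TSV file
#'
#' Plain tab-separated output with a header, no quoting, no row names —
#' the on-disk convention used by every table the pipeline emits.
#'
#' @param df data.frame
#' @param path output path
#' @keywords internal
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "", ...)
}

empty_df <- function(...) {
  cols <- list(...)
  structure(data.frame(cols, stringsAsFactors = FALSE),
            names = names(cols))
}
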