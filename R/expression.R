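#' Read a gene expression table
#'
#' Expects genes in rows and samples in columns: the first row holds sample
#' identifiers, the first column gene identifiers, every remaining cell a
#' finite number. The delimiter is explicit, never guessed.
#'
#' @param path Path to a delimited text file.
#' @param delimiter Field delimiter, `"\t"` (default) or `","` etc.
#' @return A tibble whose first column `gene` holds gene ids and whose
#'   remaining columns are samples, in file order. Validated by
#'   [validate_expression()].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_expression(simulate_expression(random_planted_model(3, 0.5, seed = 1)), tf)
#' read_expression(tf)
#' @export
read_expression <- function(path, delimiter = "\t") {
  if (!file.exists(path)) {
    abort(paste0("expression file not found: ", path))
  }
  df <- readr::read_delim(
    path,
    delim = delimiter,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  names(df)[1] <- "gene"
  if (ncol(df) < 3) {
    abort("expression table needs at least 2 sample columns")
  }
  for (j in seq(2, ncol(df))) {
    parsed <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(parsed) | !is.finite(parsed))
    if (length(bad) > 0) {
      abort(paste0(
        "non-numeric or missing value at gene row ", bad[1],
        " (", df$gene[bad[1]], "), sample column '", names(df)[j], "'"
      ))
    }
    df[[j]] <- parsed
  }
  validate_expression(df)
}

#' Write a gene expression table
#'
#' @param data An expression tibble as returned by [read_expression()] or
#'   [simulate_expression()].
#' @param path Output path.
#' @param delimiter Field delimiter, `"\t"` by default.
#' @return `path`, invisibly.
#' @export
write_expression <- function(data, path, delimiter = "\t") {
  data <- validate_expression(data)
  readr::write_delim(data, path, delim = delimiter, progress = FALSE)
  invisible(path)
}

#' Validate an expression tibble
#'
#' Checks the invariants every scoring routine relies on: a `gene` id column
#' with distinct ids, at least two sample columns, and all values finite.
#'
#' @param data A data frame: first column gene ids, remaining columns numeric
#'   samples with distinct names.
#' @return The validated data as a tibble, first column named `gene`.
#' @export
validate_expression <- function(data) {
  data <- as_tibble(data)
  if (ncol(data) < 3) {
    abort("expression table needs a gene column and at least 2 samples")
  }
  names(data)[1] <- "gene"
  data$gene <- as.character(data$gene)
  dup <- data$gene[duplicated(data$gene)]
  if (length(dup) > 0) {
    abort(paste0("duplicate gene id: ", dup[1]))
  }
  sdup <- names(data)[-1][duplicated(names(data)[-1])]
  if (length(sdup) > 0) {
    abort(paste0("duplicate sample id: ", sdup[1]))
  }
  for (j in seq(2, ncol(data))) {
    if (!is.numeric(data[[j]])) {
      abort(paste0("sample column '", names(data)[j], "' is not numeric"))
    }
    bad <- which(!is.finite(data[[j]]))
    if (length(bad) > 0) {
      abort(paste0(
        "non-finite value at gene ", data$gene[bad[1]],
        ", sample '", names(data)[j], "'"
      ))
    }
  }
  data
}

# genes x samples numeric matrix restricted to `genes` (in the given order)
expression_matrix <- function(data, genes = NULL) {
  data <- validate_expression(data)
  genes <- genes %||% data$gene
  miss <- setdiff(genes, data$gene)
  if (length(miss) > 0) {
    abort(paste0("gene not found in expression data: ", miss[1]))
  }
  m <- as.matrix(data[match(genes, data$gene), -1, drop = FALSE])
  rownames(m) <- genes
  m
}
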