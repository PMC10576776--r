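#' Boundary-phenotype table
#'
#' The substrate of all penetrance, expressivity and correlation statistics:
#' one row per scored somite boundary, per embryo side, with the binary code
#' used for scoring cleared embryos (0 = intact, 1 = defected, NA =
#' unscorable). Boundaries up to 30 are conventionally scored; the analysis
#' range (default 11--30) is applied downstream.
#'
#' @param x A data frame with columns `embryo_id`, `side` ("L"/"R"),
#'   `boundary_index` (integer), `phenotype` (0, 1 or NA) and optionally
#'   `condition`.
#' @param condition Condition label used when `x` lacks a `condition` column.
#' @return A data frame of class `boundary_table`.
#' @export
boundary_table <- function(x, condition = "unspecified") {
  stopifnot(is.data.frame(x))
  need <- c("embryo_id", "side", "boundary_index", "phenotype")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("boundary table is missing column(s): ", paste(miss, collapse = ", "))
  x$embryo_id <- as.character(x$embryo_id)
  x$side <- as.character(x$side)
  if (nrow(x)) {
    bad <- !x$side %in% c("L", "R")
    if (any(bad))
      stop("side must be 'L' or 'R' (offending row ", which(bad)[1L], ")")
    ph <- x$phenotype
    bad <- !is.na(ph) & !ph %in% c(0L, 1L)
    if (any(bad))
      stop("phenotype must be 0 (intact), 1 (defected) or NA (row ",
           which(bad)[1L], ")")
    dup <- duplicated(x[, c("embryo_id", "side", "boundary_index")])
    if (any(dup))
      stop("duplicate (embryo_id, side, boundary_index) at row ",
           which(dup)[1L])
  }
  x$boundary_index <- as.integer(x$boundary_index)
  x$phenotype <- as.integer(x$phenotype)
  if (is.null(x$condition))
    x$condition <- rep(as.character(condition), nrow(x))
  x <- x[, c("embryo_id", "side", "boundary_index", "phenotype", "condition")]
  class(x) <- c("boundary_table", "data.frame")
  x
}

#' Read / write a boundary-phenotype table as TSV
#'
#' Tab-separated with header `embryo_id side boundary_index phenotype
#' condition`; phenotype coded 0 = intact, 1 = defected, NA = unscorable.
#'
#' @param path File path.
#' @return `read_boundary_table` returns a [boundary_table()];
#'   `write_boundary_table` returns `path` invisibly.
#' @export
read_boundary_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  boundary_table(x)
}

#' @rdname read_boundary_table
#' @param x A [boundary_table()].
#' @export
write_boundary_table <- function(x, path) {
  stopifnot(inherits(x, "boundary_table"))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.boundary_table <- function(x, ...) {
  cat(sprintf("Boundary-phenotype table: %d rows, %d embryos, conditions: %s\n",
              nrow(x), length(unique(x$embryo_id)),
              paste(unique(x$condition), collapse = ", ")))
  if (nrow(x)) print.data.frame(utils::head(x, 6L))
  invisible(x)
}
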