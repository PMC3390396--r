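#' Read and write the tab-delimited table dialect
#'
#' The package exchanges two plain-text tables: a *cells* table with one row
#' per bivalent (`cell_id`, `genotype`, `bivalent_id`, `sc_length`,
#' `shape_class`, `n_class1`, `n_class2`) and a *foci* table with one row per
#' focus (`cell_id`, `bivalent_id`, `channel`, `position_frac`). Both are
#' tab-delimited with a header row.
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return `read_*` return data frames; `write_*` return `path` invisibly.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_cells_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
write_foci_table <- write_cells_table

#' @rdname table_io
#' @export
read_cells_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname table_io
#' @export
read_foci_table <- read_cells_table

.cells_cols <- c("cell_id", "genotype", "bivalent_id", "sc_length",
                 "shape_class", "n_class1", "n_class2")
.foci_cols <- c("cell_id", "bivalent_id", "channel", "position_frac")

#' Validate cells and foci tables against the schema
#'
#' Checks column names, value domains (positions in `[0, 1]`, SC lengths
#' positive, shape classes in the three-level enum, event counts non-negative
#' integers, channel labels non-empty) and duplicate `(cell_id, bivalent_id)`
#' keys in the cells table. Each violation names the offending column and row.
#'
#' @param cells,foci Data frames or file paths; either may be `NULL` to skip.
#' @return Data frame of issues (`table`, `row`, `problem`); zero rows when
#'   both tables are valid.
#' @export
validate_tables <- function(cells = NULL, foci = NULL) {
  issues <- list()
  add <- function(tab, row, problem)
    issues[[length(issues) + 1L]] <<- data.frame(
      table = tab, row = row, problem = problem, stringsAsFactors = FALSE)
  load_tab <- function(x, nm) {
    if (is.character(x)) {
      if (!file.exists(x)) stop("cannot read ", nm, " table: ", x)
      read.delim(x, stringsAsFactors = FALSE)
    } else x
  }
  if (!is.null(cells)) {
    cells <- load_tab(cells, "cells")
    miss <- setdiff(.cells_cols, names(cells))
    if (length(miss)) {
      add("cells", NA_integer_, paste("missing column:", paste(miss, collapse = ", ")))
    } else {
      bad <- which(!cells$shape_class %in% c("univalent_pair", "rod", "ring"))
      for (i in bad) add("cells", i, paste("unknown shape_class:", cells$shape_class[[i]]))
      bad <- which(!is.finite(cells$sc_length) | cells$sc_length <= 0)
      for (i in bad) add("cells", i, "sc_length must be > 0")
      for (col in c("n_class1", "n_class2")) {
        v <- cells[[col]]
        bad <- which(!is.finite(v) | v < 0 | v != floor(v))
        for (i in bad) add("cells", i, paste(col, "must be a non-negative integer"))
      }
      key <- paste(cells$cell_id, cells$bivalent_id)
      dup <- which(duplicated(key))
      for (i in dup) add("cells", i, "duplicate (cell_id, bivalent_id) key")
    }
  }
  if (!is.null(foci)) {
    foci <- load_tab(foci, "foci")
    miss <- setdiff(.foci_cols, names(foci))
    if (length(miss)) {
      add("foci", NA_integer_, paste("missing column:", paste(miss, collapse = ", ")))
    } else {
      bad <- which(!is.finite(foci$position_frac) |
                     foci$position_frac < 0 | foci$position_frac > 1)
      for (i in bad) add("foci", i, "position_frac outside [0, 1]")
      bad <- which(!nzchar(as.character(foci$channel)) | is.na(foci$channel))
      for (i in bad) add("foci", i, "empty channel label")
    }
  }
  if (length(issues) == 0L)
    return(data.frame(table = character(0), row = integer(0),
                      problem = character(0), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}
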