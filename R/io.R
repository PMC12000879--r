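#' Read and write the tabular screen formats
#'
#' All tables are plain delimited text; the delimiter is chosen from the file
#' extension (`.csv` = comma, anything else = tab). Writing then reading a
#' table reproduces it exactly (round-trip), which the test suite asserts.
#'
#' @param path File path ending in `.tsv`, `.txt` or `.csv`.
#' @name ern_io
NULL

delim_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

read_table_auto <- function(path, col_types) {
  readr::read_delim(path, delim = delim_for(path), col_types = col_types,
                    progress = FALSE, show_col_types = FALSE)
}

write_table_auto <- function(x, path) {
  readr::write_delim(x, path, delim = delim_for(path), na = "NA")
  invisible(path)
}

#' @rdname ern_io
#' @export
read_gene_library <- function(path) {
  x <- read_table_auto(path, readr::cols(
    gene_id = readr::col_character(),
    functional_class = readr::col_character(),
    has_paralogue = readr::col_logical(),
    paralogue_partner = readr::col_character(),
    is_negative_control = readr::col_logical(),
    .default = readr::col_double()
  ))
  validate_library(x)
}

#' @rdname ern_io
#' @param library,layout,screen Tables as produced by [build_default_library()],
#'   [layout_plates()] and [simulate_screen()].
#' @export
write_gene_library <- function(library, path) write_table_auto(library, path)

#' @rdname ern_io
#' @export
read_plate_layout <- function(path) {
  x <- read_table_auto(path, readr::cols(
    plate_id = readr::col_character(),
    well = readr::col_character(),
    gene_id = readr::col_character(),
    is_control = readr::col_logical()
  ))
  validate_layout(x)
}

#' @rdname ern_io
#' @export
write_plate_layout <- function(layout, path) write_table_auto(layout, path)

#' @rdname ern_io
#' @export
read_screen_table <- function(path) {
  x <- read_table_auto(path, readr::cols(
    plate_id = readr::col_character(),
    well = readr::col_character(),
    gene_id = readr::col_character(),
    condition = readr::col_character(),
    replicate = readr::col_integer(),
    cell_count = readr::col_double()
  ))
  validate_screen(x)
}

#' @rdname ern_io
#' @export
write_screen_table <- function(screen, path) write_table_auto(screen, path)
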