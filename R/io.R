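#' Default column map for reporter-table exports
#'
#' Maps the pipeline's logical column roles onto the column names of a
#' search-engine peptide export. Renaming columns in a different export
#' dialect is a configuration concern: pass a modified map to
#' [read_reporter_table()].
#'
#' @return A named list with entries `accession`, `sequence`, `positions`
#'   and `contaminant`.
#' @export
default_column_map <- function() {
  list(
    accession   = "Accession",
    sequence    = "Sequence",
    positions   = "Positions in Proteins",
    contaminant = "Contaminant"
  )
}

# truthy contaminant flags seen in common exports
parse_contaminant <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  x <- trimws(tolower(as.character(x)))
  !is.na(x) & x %in% c("true", "t", "yes", "y", "+", "1", "x")
}

# extract sorted unique 1-based integer positions from e.g. "C139; C145"
parse_positions <- function(x) {
  stringr::str_extract_all(x, "[0-9]+") |>
    lapply(function(p) sort(unique(as.integer(p))))
}

make_site_key <- function(accession, positions) {
  paste0(accession, ":",
         vapply(positions, function(p) paste0("Cys", p, collapse = ","), ""))
}

#' Read a Cys-peptide reporter-intensity table
#'
#' Reads a tab-separated peptide-level export (one row per Cys peptide or
#' PSM, one intensity column per reporter channel), applies the contaminant
#' and non-Cys filters, and aggregates rows that quantify the same Cys site
#' set by summing intensities channel-wise. The quantified unit downstream is
#' the unique Cys peptide, keyed as `"<accession>:Cys<pos>[,Cys<pos>...]"`
#' with sorted 1-based protein coordinates.
#'
#' Zero intensities encode "not observed" and are preserved as zeros.
#' Peptides mapping to several proteins keep the first listed accession; the
#' full list is recorded in the `all_accessions` provenance column.
#'
#' @param path Path to the TSV export.
#' @param design A validated channel design (see [read_channel_design()]);
#'   one intensity column per `channel_id` must be present.
#' @param column_map Named list mapping the roles `accession`, `sequence`,
#'   `positions`, `contaminant` to column names in the file; see
#'   [default_column_map()].
#'
#' @return A tibble with columns `site_key`, `accession`, `positions`
#'   (comma-separated integers), `all_accessions`, then one numeric column
#'   per design channel, sorted by `site_key`.
#' @export
read_reporter_table <- function(path, design,
                                column_map = default_column_map()) {
  if (!file.exists(path)) stop_data("reporter table file not found: %s", path)
  design <- validate_channel_design(design)
  column_map <- modifyList(default_column_map(), as.list(column_map))

  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)

  needed <- unlist(column_map[c("accession", "sequence", "positions")])
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop_data("reporter table is missing required column(s): %s",
              paste(missing_cols, collapse = ", "))
  }
  missing_channels <- setdiff(design$channel_id, names(raw))
  if (length(missing_channels) > 0) {
    stop_data("design channel(s) with no matching intensity column: %s",
              paste(missing_channels, collapse = ", "))
  }

  intens <- lapply(design$channel_id, function(ch) {
    v <- trimws(raw[[ch]])
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & nzchar(v))
    if (length(bad) > 0) {
      stop_data("non-numeric intensity '%s' in column '%s', row %d",
                v[bad[1]], ch, bad[1])
    }
    num[is.na(num)] <- 0
    num
  })
  names(intens) <- design$channel_id

  contam <- if (column_map$contaminant %in% names(raw)) {
    parse_contaminant(raw[[column_map$contaminant]])
  } else {
    rep(FALSE, nrow(raw))
  }

  tbl <- tibble(
    accession_full = trimws(raw[[column_map$accession]]),
    sequence = toupper(trimws(raw[[column_map$sequence]])),
    positions_raw = raw[[column_map$positions]],
    contaminant = contam
  )
  tbl <- dplyr::bind_cols(tbl, as_tibble(intens))

  keep <- !tbl$contaminant & grepl("C", tbl$sequence, fixed = TRUE)
  tbl <- tbl[keep, , drop = FALSE]
  if (nrow(tbl) == 0) {
    warn("no rows left after contaminant and non-Cys filtering")
  }

  pos_list <- parse_positions(tbl$positions_raw)
  empty <- which(lengths(pos_list) == 0)
  if (length(empty) > 0) {
    stop_data("no Cys position could be parsed from '%s' (filtered row %d)",
              tbl$positions_raw[empty[1]], empty[1])
  }
  accession <- vapply(strsplit(tbl$accession_full, "[;,]"),
                      function(a) trimws(a[1]), "")

  tbl$site_key <- make_site_key(accession, pos_list)
  tbl$accession <- accession
  tbl$positions <- vapply(pos_list, paste, "", collapse = ",")

  out <- tbl |>
    dplyr::group_by(.data$site_key) |>
    dplyr::summarise(
      accession = .data$accession[1],
      positions = .data$positions[1],
      all_accessions = .data$accession_full[1],
      dplyr::across(dplyr::all_of(design$channel_id), sum),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$site_key)
  out
}

#' Read a cysteine-modification annotation table
#'
#' Reads a tab-separated annotation table in the RedoxDB/UniProt style:
#' header columns `accession`, `position` (1-based protein coordinate) and
#' `modification_type`, optionally `source`. Exact duplicate
#' (accession, position, modification_type) rows are collapsed.
#'
#' @param path Path to a TSV file.
#'
#' @return A tibble with columns `accession`, `position` (integer),
#'   `modification_type`, `source`.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop_data("annotation file not found: %s", path)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = "NA", progress = FALSE)
  required <- c("accession", "position", "modification_type")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop_data("annotation table is missing required column(s): %s",
              paste(missing_cols, collapse = ", "))
  }
  pos <- suppressWarnings(as.numeric(raw$position))
  bad <- which(is.na(pos) | pos < 1 | pos != round(pos))
  if (length(bad) > 0) {
    stop_data("invalid 1-based position '%s' in annotation row %d",
              raw$position[bad[1]], bad[1])
  }
  out <- tibble(
    accession = trimws(raw$accession),
    position = as.integer(pos),
    modification_type = trimws(raw$modification_type),
    source = if ("source" %in% names(raw)) raw$source else NA_character_
  )
  dplyr::distinct(out, .data$accession, .data$position,
                  .data$modification_type, .keep_all = TRUE)
}

#' Write a result table as TSV
#'
#' Writes any result tibble to a tab-separated file with a header row,
#' missing values rendered as the literal `NA`, and doubles at full
#' round-trippable precision, so that [read_results()] reproduces the table
#' bit-exactly.
#'
#' @param table A data frame.
#' @param path Output file path.
#'
#' @return `table`, invisibly (so writes can sit inside a pipe).
#' @export
write_results <- function(table, path) {
  readr::write_tsv(as_tibble(table), path, na = "NA", progress = FALSE)
  invisible(table)
}

#' Read back a result table written by [write_results()]
#'
#' @param path Path to a TSV file with `NA` as the missing-value sentinel.
#'
#' @return A tibble with guessed column types.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop_data("result file not found: %s", path)
  readr::read_tsv(path, na = "NA", progress = FALSE, show_col_types = FALSE)
}
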