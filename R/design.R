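#' Validate a channel design
#'
#' A channel design maps every reporter channel of a multiplexed run to its
#' sample, condition, replicate and label class. The label class records which
#' of the two sequential iodoTMT labels the channel carries: `"SH"` for the
#' first label (free thiols, blocked before reduction) or `"Sox"` for the
#' second label (previously oxidized thiols, labelled after reduction).
#'
#' Validation enforces the pairing invariant of the sequential design: every
#' sample must appear with exactly one SH channel and exactly one Sox channel
#' within its plex run, channel ids must be unique (they name the intensity
#' columns of the reporter table), and each sample must belong to a single
#' plex run.
#'
#' @param design A data frame with columns `channel_id`, `plex_run`,
#'   `sample_id`, `condition`, `replicate`, `label_class`.
#'
#' @return The validated design as a tibble, invisibly usable downstream.
#' @export
#' @examples
#' design <- tibble::tibble(
#'   channel_id = c("c1", "c2", "c3", "c4"),
#'   plex_run = "run1",
#'   sample_id = rep(c("ctrl_1", "aza_1"), each = 2),
#'   condition = rep(c("ctrl", "aza"), each = 2),
#'   replicate = 1L,
#'   label_class = rep(c("SH", "Sox"), 2)
#' )
#' validate_channel_design(design)
validate_channel_design <- function(design) {
  required <- c("channel_id", "plex_run", "sample_id", "condition",
                "replicate", "label_class")
  missing_cols <- setdiff(required, names(design))
  if (length(missing_cols) > 0) {
    stop_data("channel design is missing required column(s): %s",
              paste(missing_cols, collapse = ", "))
  }
  design <- as_tibble(design)
  design$channel_id <- as.character(design$channel_id)
  design$plex_run <- as.character(design$plex_run)
  design$sample_id <- as.character(design$sample_id)
  design$condition <- as.character(design$condition)
  design$replicate <- as.integer(design$replicate)
  design$label_class <- as.character(design$label_class)

  bad_class <- setdiff(unique(design$label_class), c("SH", "Sox"))
  if (length(bad_class) > 0) {
    stop_data("label_class must be 'SH' or 'Sox'; found: %s",
              paste(bad_class, collapse = ", "))
  }
  if (any(is.na(design$replicate) | design$replicate < 1L)) {
    stop_data("replicate must be a positive integer")
  }
  if (anyDuplicated(design$channel_id)) {
    dup <- unique(design$channel_id[duplicated(design$channel_id)])
    stop_data("duplicated channel_id(s): %s (channel ids name intensity columns and must be unique)",
              paste(dup, collapse = ", "))
  }
  runs_per_sample <- tapply(design$plex_run, design$sample_id,
                            function(x) length(unique(x)))
  if (any(runs_per_sample > 1)) {
    stop_data("sample(s) assigned to more than one plex_run: %s",
              paste(names(runs_per_sample)[runs_per_sample > 1], collapse = ", "))
  }
  pairing <- dplyr::count(design, .data$sample_id, .data$label_class)
  pairing <- tidyr::pivot_wider(pairing, names_from = "label_class",
                                values_from = "n", values_fill = 0L)
  for (cls in c("SH", "Sox")) {
    if (!cls %in% names(pairing)) pairing[[cls]] <- 0L
  }
  bad <- pairing$sample_id[pairing$SH != 1L | pairing$Sox != 1L]
  if (length(bad) > 0) {
    stop_data("sample(s) without exactly one SH and one Sox channel: %s",
              paste(bad, collapse = ", "))
  }
  design
}

#' Read a channel design table
#'
#' Reads a tab-separated channel design (header columns `channel_id`,
#' `plex_run`, `sample_id`, `condition`, `replicate`, `label_class`) and
#' validates it with [validate_channel_design()].
#'
#' @param path Path to a TSV file.
#'
#' @return A validated design tibble.
#' @export
read_channel_design <- function(path) {
  if (!file.exists(path)) stop_data("channel design file not found: %s", path)
  design <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                            na = "NA", progress = FALSE)
  validate_channel_design(design)
}

# Helper: channels of one sample as a named list c(SH = ..., Sox = ...)
sample_channels <- function(design) {
  split(design, design$sample_id) |>
    lapply(function(d) setNames(d$channel_id, d$label_class))
}

# Helper: sample -> condition lookup (one row per sample)
sample_table <- function(design) {
  dplyr::distinct(design, .data$sample_id, .data$condition, .data$replicate,
                  .data$plex_run)
}
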