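#' Join Cys sites to modification or domain annotations
#'
#' Exact accession-plus-position join of quantified Cys sites to an
#' annotation table (RedoxDB-style cysteine modifications, or
#' UniProt-derived domain positions). Peptides spanning several Cys
#' residues match if any of their positions matches a record; the matched
#' position is recorded. Coordinates are 1-based protein positions on both
#' sides — no fuzzy matching.
#'
#' @param sites A data frame with a `site_key` column
#'   (`"<accession>:Cys<pos>[,Cys<pos>...]"`), e.g. an oxidation table.
#' @param annotations An annotation tibble from [read_annotation_table()].
#' @param modification_filter Optional modification type (e.g.
#'   `"S-glutathionylation"`); restricts matches to that type.
#'
#' @return A tibble with one row per site x matched record (unmatched
#'   sites keep one row with `NA` match columns): `site_key`, `accession`,
#'   `matched_position`, `modification_type`, `source`, `n_matches`.
#' @export
map_sites_to_annotations <- function(sites, annotations,
                                     modification_filter = NULL) {
  keys <- unique(sites$site_key)
  acc <- sub(":.*$", "", keys)
  pos_list <- parse_positions(sub("^[^:]*:", "", keys))
  site_pos <- tibble(
    site_key = rep(keys, lengths(pos_list)),
    accession = rep(acc, lengths(pos_list)),
    matched_position = unlist(pos_list)
  )
  ann <- as_tibble(annotations)
  if (!is.null(modification_filter)) {
    ann <- ann[ann$modification_type == modification_filter, , drop = FALSE]
  }
  hits <- dplyr::inner_join(
    site_pos, ann,
    by = c(accession = "accession", matched_position = "position")
  )
  all_sites <- tibble(site_key = keys, accession = acc)
  out <- dplyr::left_join(all_sites, hits,
                          by = c("site_key", "accession")) |>
    dplyr::group_by(.data$site_key) |>
    dplyr::mutate(n_matches = sum(!is.na(.data$matched_position))) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$site_key, .data$matched_position)
  out
}

#' Global S-glutathionylation index (P-SSG)
#'
#' Aggregates oxidation over sites annotated as carrying a given reversible
#' modification — by default S-glutathionylation — into a per-sample index
#' of the global modification load. Both the median and the mean over
#' annotated sites are reported (the appropriate aggregate is a reported
#' parameter of the analysis, not a fixed convention), together with the
#' number of annotated sites contributing in each sample.
#'
#' @param ox An oxidation tibble (`site_key` + sample columns).
#' @param joins Output of [map_sites_to_annotations()], already filtered to
#'   the modification of interest (e.g. via `modification_filter`).
#'
#' @return A tibble with columns `sample_id`, `median_ox`, `mean_ox`,
#'   `n_sites`. Samples where every annotated site is missing get `NA`
#'   aggregates with a warning.
#' @export
pssg_index <- function(ox, joins) {
  annotated <- unique(joins$site_key[joins$n_matches > 0])
  if (length(annotated) == 0) {
    warn("no annotated sites; P-SSG index undefined")
    return(tibble(sample_id = character(), median_ox = double(),
                  mean_ox = double(), n_sites = integer()))
  }
  sub <- ox[ox$site_key %in% annotated, , drop = FALSE]
  sample_cols <- setdiff(names(ox), "site_key")
  out <- purrr::map_dfr(sample_cols, function(s) {
    v <- sub[[s]]
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      warn(sprintf("sample '%s': all annotated sites missing; index undefined", s))
      return(tibble(sample_id = s, median_ox = NA_real_, mean_ox = NA_real_,
                    n_sites = 0L))
    }
    tibble(sample_id = s, median_ox = median(v), mean_ox = mean(v),
           n_sites = length(v))
  })
  out
}
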