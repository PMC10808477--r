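#' Read a peak-intensity table
#'
#' Intensity tables are long-format TSVs with one row per sample x fragment
#' and header columns `sample_id`, `fragment_id`, `intensity_template`,
#' `intensity_competitor`. Intensities are non-negative spectrometer units:
#' `intensity_template` is the peak height of the genomic template allele,
#' `intensity_competitor` that of the co-amplified competitor oligo.
#'
#' @param path Path to the TSV file.
#' @param panel Optional [fragment_panel]; if supplied, rows whose
#'   `fragment_id` is not in the panel are rejected.
#' @return A tibble of intensity records, in file order.
#' @export
read_intensities <- function(path, panel = NULL) {
  if (!file.exists(path)) {
    stop_masscnv(paste0("intensity file not found: ", path), "masscnv_io_error")
  }
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      fragment_id = readr::col_character(),
      intensity_template = readr::col_double(),
      intensity_competitor = readr::col_double()
    )
  )
  required <- c("sample_id", "fragment_id",
                "intensity_template", "intensity_competitor")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop_masscnv(
      paste0("intensity table missing column(s): ", paste(missing, collapse = ", ")),
      "masscnv_parse_error"
    )
  }
  tab <- tab[, required]
  # line numbers: header is line 1
  line_no <- seq_len(nrow(tab)) + 1L
  bad <- which(is.na(tab$intensity_template) | is.na(tab$intensity_competitor) |
                 tab$intensity_template < 0 | tab$intensity_competitor < 0)
  if (length(bad) > 0) {
    stop_masscnv(
      paste0("negative or missing intensity at line ", line_no[bad[1]]),
      "masscnv_parse_error"
    )
  }
  key <- paste(tab$sample_id, tab$fragment_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop_masscnv(
      paste0("duplicate (sample_id, fragment_id) at line ", line_no[dup[1]],
             ": ", tab$sample_id[dup[1]], " / ", tab$fragment_id[dup[1]]),
      "masscnv_parse_error"
    )
  }
  if (!is.null(panel)) {
    unknown <- which(!(tab$fragment_id %in% panel$fragments$fragment_id))
    if (length(unknown) > 0) {
      stop_masscnv(
        paste0("unknown fragment_id '", tab$fragment_id[unknown[1]],
               "' at line ", line_no[unknown[1]]),
        "masscnv_parse_error"
      )
    }
  }
  tab
}

#' Write a peak-intensity table
#'
#' Writes the long-format TSV read back by [read_intensities()]. Intensities
#' are serialised with 12 significant digits so a write-then-read round trip
#' is numerically lossless at that precision.
#'
#' @param intensities Tibble with the four intensity columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intensities <- function(intensities, path) {
  out <- tibble::tibble(
    sample_id = intensities$sample_id,
    fragment_id = intensities$fragment_id,
    intensity_template = formatC(intensities$intensity_template,
                                 digits = 12, format = "g"),
    intensity_competitor = formatC(intensities$intensity_competitor,
                                   digits = 12, format = "g")
  )
  readr::write_tsv(out, path)
  invisible(path)
}
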