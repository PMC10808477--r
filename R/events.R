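#' Merge per-fragment calls into exon-range CNV events
#'
#' Maximal runs of consecutive target fragments (by `order_index`, within one
#' gene) sharing the same non-normal call are merged into one event. `no_call`
#' fragments break runs (conservative: a QC gap is never imputed), so a
#' deletion interrupted by a failed fragment is reported as two events.
#' Deletion and duplication runs are never merged, and events never span
#' genes.
#'
#' Labels are derived from the member exon labels: `"exon 5 deletion"` for a
#' single fully-covered exon, `"exon 1-2 deletion"` for a span, and
#' `"part of exon 11 deletion"` when the run covers a strict subset of the
#' fragments subdividing one exon.
#'
#' @param results TR result tibble from [compute_tr()]; may hold one or many
#'   samples.
#' @param panel The [fragment_panel] the results were computed on.
#' @param min_fragments Minimum run length for an event to be reported
#'   (default 1).
#' @return A tibble with one row per event: `sample_id`, `gene`,
#'   `first_fragment`, `last_fragment`, `exon_range_label`, `event_type`,
#'   `n_fragments`, `mean_tr`.
#' @export
merge_events <- function(results, panel, min_fragments = 1) {
  stopifnot(inherits(panel, "fragment_panel"))
  empty <- tibble::tibble(
    sample_id = character(0), gene = character(0),
    first_fragment = character(0), last_fragment = character(0),
    exon_range_label = character(0), event_type = character(0),
    n_fragments = integer(0), mean_tr = numeric(0)
  )
  if (is.null(results) || nrow(results) == 0) return(empty)

  ord <- panel$fragments[panel$fragments$role == "target",
                         c("fragment_id", "order_index")]
  res <- dplyr::left_join(
    results[, setdiff(names(results), "order_index")], ord, by = "fragment_id"
  )
  res <- dplyr::arrange(res, .data$sample_id, .data$gene, .data$order_index)

  events <- list()
  for (key in split(seq_len(nrow(res)),
                    paste(res$sample_id, res$gene, sep = "\r"))) {
    d <- res[key, ]
    runs <- rle(d$call)
    stops <- cumsum(runs$lengths)
    starts <- stops - runs$lengths + 1L
    for (i in seq_along(runs$values)) {
      type <- runs$values[i]
      if (!(type %in% c("deletion", "duplication"))) next
      if (runs$lengths[i] < min_fragments) next
      member <- d[starts[i]:stops[i], ]
      events[[length(events) + 1L]] <- tibble::tibble(
        sample_id = member$sample_id[1],
        gene = member$gene[1],
        first_fragment = member$fragment_id[1],
        last_fragment = member$fragment_id[nrow(member)],
        exon_range_label = exon_range_label(member$exon_label, member$gene[1],
                                            panel, type),
        event_type = type,
        n_fragments = nrow(member),
        mean_tr = mean(member$tr)
      )
    }
  }
  if (length(events) == 0) return(empty)
  dplyr::bind_rows(events)
}

# Deterministic event label from member exon labels.
exon_range_label <- function(member_labels, gene, panel, event_type) {
  px <- parse_exon_label(member_labels)
  if (anyNA(px$exon)) {
    # opaque labels: fall back to explicit fragment list
    return(paste0(paste(member_labels, collapse = ","), " ", event_type))
  }
  a <- min(px$exon)
  b <- max(px$exon)
  if (a == b) {
    frag <- panel$fragments
    gene_targets <- frag$exon_label[frag$role == "target" & frag$gene == gene]
    exon_frags <- gene_targets[parse_exon_label(gene_targets)$exon == a]
    covered_all <- length(member_labels) == length(exon_frags)
    if (covered_all) {
      paste0("exon ", a, " ", event_type)
    } else {
      paste0("part of exon ", a, " ", event_type)
    }
  } else {
    paste0("exon ", a, "-", b, " ", event_type)
  }
}

#' Sample-level CNV status
#'
#' A sample is `cnv_positive` iff it carries at least one event.
#'
#' @param events Event tibble from [merge_events()].
#' @param samples Optional character vector of all evaluated sample ids;
#'   samples absent from `events` are `cnv_negative`. Defaults to the samples
#'   present in `events`.
#' @return A tibble with columns `sample_id` and `status`.
#' @export
sample_status <- function(events, samples = NULL) {
  pos <- unique(events$sample_id)
  if (is.null(samples)) samples <- pos
  tibble::tibble(
    sample_id = as.character(samples),
    status = ifelse(samples %in% pos, "cnv_positive", "cnv_negative")
  )
}

#' Write per-fragment calls and per-event tables
#'
#' Writes `<prefix>_calls.tsv` (one row per sample x target fragment, TR with
#' four decimal places) and `<prefix>_events.tsv` (one row per merged event;
#' header only if there are no events).
#'
#' @param results TR result tibble from [compute_tr()] (non-empty).
#' @param events Event tibble from [merge_events()].
#' @param out_prefix Output path prefix.
#' @return Named character vector of the two paths written, invisibly.
#' @export
write_calls <- function(results, events, out_prefix) {
  if (is.null(results) || nrow(results) == 0) {
    stop_masscnv("no TR results to write", "masscnv_argument_error")
  }
  calls_path <- paste0(out_prefix, "_calls.tsv")
  events_path <- paste0(out_prefix, "_events.tsv")
  fmt4 <- function(x) ifelse(is.na(x), "NA", sprintf("%.4f", x))
  out <- tibble::tibble(
    sample_id = results$sample_id,
    fragment_id = results$fragment_id,
    gene = results$gene,
    exon_label = results$exon_label,
    well = results$well,
    ratio_raw = fmt4(results$ratio_raw),
    normalizer = fmt4(results$normalizer),
    tr = fmt4(results$tr),
    call = results$call,
    qc_flags = results$qc_flags
  )
  readr::write_tsv(out, calls_path)
  ev <- tibble::tibble(
    sample_id = as.character(events$sample_id),
    gene = as.character(events$gene),
    first_fragment = as.character(events$first_fragment),
    last_fragment = as.character(events$last_fragment),
    exon_range_label = as.character(events$exon_range_label),
    event_type = as.character(events$event_type),
    n_fragments = as.integer(events$n_fragments),
    mean_tr = fmt4(events$mean_tr)
  )
  readr::write_tsv(ev, events_path)
  invisible(c(calls = calls_path, events = events_path))
}

#' Read back a per-fragment call table
#' @param path Path to a `*_calls.tsv` written by [write_calls()].
#' @return A tibble shaped like [compute_tr()] output.
#' @export
read_calls <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    fragment_id = readr::col_character(),
    gene = readr::col_character(),
    exon_label = readr::col_character(),
    well = readr::col_character(),
    ratio_raw = readr::col_double(),
    normalizer = readr::col_double(),
    tr = readr::col_double(),
    call = readr::col_character(),
    qc_flags = readr::col_character()
  )) |>
    dplyr::mutate(qc_flags = ifelse(is.na(.data$qc_flags), "", .data$qc_flags))
}

#' Read back an event table
#' @param path Path to a `*_events.tsv` written by [write_calls()].
#' @return An event tibble shaped like [merge_events()] output.
#' @export
read_events <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    gene = readr::col_character(),
    first_fragment = readr::col_character(),
    last_fragment = readr::col_character(),
    exon_range_label = readr::col_character(),
    event_type = readr::col_character(),
    n_fragments = readr::col_integer(),
    mean_tr = readr::col_double()
  ))
}
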