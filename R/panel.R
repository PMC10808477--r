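#' Assay panel: fragments, roles, wells
#'
#' A `fragment_panel` describes the layout of a multiplex dosage assay: the
#' amplified fragments (one row each), the gene and exon each target fragment
#' interrogates, which multiplex reaction ("well") each fragment belongs to,
#' and which genes serve as assumed-diploid internal references.
#'
#' @param fragments A data frame with columns `fragment_id`, `gene`,
#'   `exon_label`, `role` (`"target"` or `"reference"`), `well`, and
#'   `order_index` (5'->3' fragment order within gene; required for targets,
#'   may be `NA` for references).
#' @param name Panel name.
#' @param reference_genes Character vector of genes whose fragments act as
#'   internal diploid references.
#' @param pooled_normalization If `TRUE`, wells without their own reference
#'   fragment are allowed and normalisation pools references across wells.
#'
#' @return An object of class `fragment_panel`: a list with elements `name`,
#'   `reference_genes`, `pooled_normalization` and `fragments` (a tibble).
#' @export
#' @examples
#' frags <- tibble::tibble(
#'   fragment_id = c("B1e1", "B1e2", "ALB_W1", "EIF2C1_W1", "RNaseP_W1"),
#'   gene        = c("BRCA1", "BRCA1", "ALB", "EIF2C1", "RNaseP"),
#'   exon_label  = c("ex1", "ex2", "ref", "ref", "ref"),
#'   role        = c("target", "target", "reference", "reference", "reference"),
#'   well        = "W1",
#'   order_index = c(1, 2, NA, NA, NA)
#' )
#' fragment_panel(frags, name = "mini")
fragment_panel <- function(fragments, name = "panel",
                           reference_genes = c("ALB", "EIF2C1", "RNaseP"),
                           pooled_normalization = FALSE) {
  fragments <- tibble::as_tibble(fragments)
  panel <- structure(
    list(
      name = as.character(name),
      reference_genes = as.character(reference_genes),
      pooled_normalization = isTRUE(pooled_normalization),
      fragments = fragments
    ),
    class = "fragment_panel"
  )
  validate_panel(panel)
}

#' @export
print.fragment_panel <- function(x, ...) {
  frag <- x$fragments
  cat(sprintf(
    "<fragment_panel '%s'>: %d fragments (%d target, %d reference) in %d well(s)\n",
    x$name, nrow(frag), sum(frag$role == "target"),
    sum(frag$role == "reference"), length(unique(frag$well))
  ))
  cat("reference genes:", paste(x$reference_genes, collapse = ", "), "\n")
  invisible(x)
}

validate_panel <- function(panel) {
  frag <- panel$fragments
  required <- c("fragment_id", "gene", "exon_label", "role", "well", "order_index")
  missing <- setdiff(required, names(frag))
  if (length(missing) > 0) {
    stop_masscnv(
      paste0("panel is missing fragment field(s): ", paste(missing, collapse = ", ")),
      "masscnv_schema_error"
    )
  }
  frag$order_index <- as.numeric(frag$order_index)
  if (anyDuplicated(frag$fragment_id)) {
    dups <- unique(frag$fragment_id[duplicated(frag$fragment_id)])
    stop_masscnv(
      paste0("duplicate fragment_id in panel: ", paste(dups, collapse = ", ")),
      "masscnv_schema_error"
    )
  }
  bad_role <- setdiff(unique(frag$role), c("target", "reference"))
  if (length(bad_role) > 0) {
    stop_masscnv(
      paste0("unknown fragment role(s): ", paste(bad_role, collapse = ", ")),
      "masscnv_schema_error"
    )
  }
  if (sum(frag$role == "target") < 1 || sum(frag$role == "reference") < 1) {
    stop_masscnv(
      "panel must contain at least one target and one reference fragment",
      "masscnv_schema_error"
    )
  }
  ref_bad <- frag$fragment_id[frag$role == "reference" &
                                !(frag$gene %in% panel$reference_genes)]
  if (length(ref_bad) > 0) {
    stop_masscnv(
      paste0(
        "reference fragment(s) with gene outside the configured reference set (",
        paste(panel$reference_genes, collapse = ", "), "): ",
        paste(ref_bad, collapse = ", ")
      ),
      "masscnv_schema_error"
    )
  }
  # each well holding targets needs a co-amplified reference, unless pooling
  if (!panel$pooled_normalization) {
    target_wells <- unique(frag$well[frag$role == "target"])
    ref_wells <- unique(frag$well[frag$role == "reference"])
    orphan <- setdiff(target_wells, ref_wells)
    if (length(orphan) > 0) {
      stop_masscnv(
        paste0(
          "well(s) with target fragments but no reference fragment: ",
          paste(orphan, collapse = ", "),
          " (set pooled_normalization = TRUE to allow)"
        ),
        "masscnv_schema_error"
      )
    }
  }
  targets <- frag[frag$role == "target", ]
  if (anyNA(targets$order_index)) {
    stop_masscnv(
      paste0(
        "target fragment(s) without order_index: ",
        paste(targets$fragment_id[is.na(targets$order_index)], collapse = ", ")
      ),
      "masscnv_schema_error"
    )
  }
  for (g in unique(targets$gene)) {
    oi <- targets$order_index[targets$gene == g]
    if (any(diff(oi) <= 0)) {
      stop_masscnv(
        paste0("order_index not strictly increasing within gene ", g),
        "masscnv_schema_error"
      )
    }
  }
  panel$fragments <- frag
  panel
}

#' Read a panel definition from JSON or YAML
#'
#' The on-disk schema is a mapping with keys `name`, `reference_genes`,
#' optionally `pooled_normalization`, and `fragments`: a list of records with
#' `fragment_id`, `gene`, `exon_label`, `role`, `well`, `order_index`.
#' Files ending in `.yaml`/`.yml` are parsed as YAML, anything else as JSON.
#'
#' @param path Path to the panel file.
#' @return A validated [fragment_panel].
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) {
    stop_masscnv(paste0("panel file not found: ", path), "masscnv_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  }
  for (key in c("name", "fragments")) {
    if (is.null(raw[[key]])) {
      stop_masscnv(paste0("panel file missing required key: ", key),
                   "masscnv_schema_error")
    }
  }
  frag <- raw$fragments
  if (!is.data.frame(frag)) {
    # YAML yields a list of records
    frag <- dplyr::bind_rows(lapply(frag, function(r) {
      r$order_index <- r$order_index %||% NA_real_
      tibble::as_tibble(r)
    }))
  }
  fragment_panel(
    frag,
    name = raw$name,
    reference_genes = raw$reference_genes %||% c("ALB", "EIF2C1", "RNaseP"),
    pooled_normalization = raw$pooled_normalization %||% FALSE
  )
}

#' Write a panel definition to JSON
#'
#' @param panel A [fragment_panel].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "fragment_panel"))
  obj <- list(
    name = panel$name,
    reference_genes = panel$reference_genes,
    pooled_normalization = panel$pooled_normalization,
    fragments = panel$fragments
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

# Parse "ex<k>" / "ex<k>_part<j>" labels into exon number and part number.
parse_exon_label <- function(label) {
  m <- regmatches(label, regexec("^ex([0-9]+)(?:_part([0-9]+))?$", label))
  exon <- vapply(m, function(x) if (length(x) >= 2) as.integer(x[2]) else NA_integer_,
                 integer(1))
  part <- vapply(m, function(x) {
    if (length(x) >= 3 && nzchar(x[3])) as.integer(x[3]) else NA_integer_
  }, integer(1))
  tibble::tibble(exon = exon, part = part)
}

#' The shipped fixture panel
#'
#' A four-well BRCA1/BRCA2 exon panel used by the simulator, tests and the
#' worked examples: one target fragment per BRCA1 exon (labels `ex1`..`ex23`)
#' and per BRCA2 exon, with the large BRCA2 exon 11 subdivided into five
#' fragments (`ex11_part1`..`ex11_part5`), plus ALB/EIF2C1/RNaseP reference
#' fragments in every well.
#'
#' @return A [fragment_panel] with 54 target and 12 reference fragments.
#' @export
fixture_panel <- function() {
  brca1 <- tibble::tibble(
    gene = "BRCA1",
    exon_label = paste0("ex", 1:23),
    order_index = 1:23
  )
  brca2_labels <- c(paste0("ex", 1:10),
                    paste0("ex11_part", 1:5),
                    paste0("ex", 12:27))
  brca2 <- tibble::tibble(
    gene = "BRCA2",
    exon_label = brca2_labels,
    order_index = seq_along(brca2_labels)
  )
  targets <- dplyr::bind_rows(brca1, brca2)
  targets$fragment_id <- paste0(
    ifelse(targets$gene == "BRCA1", "B1_", "B2_"), targets$exon_label
  )
  targets$role <- "target"
  targets$well <- c(
    rep("W1", 12), rep("W2", 11),      # BRCA1 ex1-12 | ex13-23
    rep("W3", 15), rep("W4", 16)       # BRCA2 ex1-11part5 | ex12-27
  )
  ref_genes <- c("ALB", "EIF2C1", "RNaseP")
  refs <- tidyr::expand_grid(gene = ref_genes, well = paste0("W", 1:4))
  refs <- tibble::tibble(
    fragment_id = paste0(refs$gene, "_", refs$well),
    gene = refs$gene,
    exon_label = "ref",
    role = "reference",
    well = refs$well,
    order_index = NA_real_
  )
  fragment_panel(
    dplyr::bind_rows(
      targets[, c("fragment_id", "gene", "exon_label", "role", "well", "order_index")],
      refs
    ),
    name = "brca-fixture-4well",
    reference_genes = ref_genes
  )
}
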