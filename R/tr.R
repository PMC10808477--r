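#' Deletion/duplication cutoffs on the Target Ratio scale
#'
#' Fragments with TR at or below `deletion_max` are called deletions; TR at
#' or above `duplication_min` are duplications; everything in between is
#' copy-neutral. The shipped defaults are 0.65 and 1.30, i.e. roughly five
#' diploid standard deviations away from the two-copy expectation of 1.0.
#'
#' @param deletion_max Upper bound (inclusive) for a deletion call.
#' @param duplication_min Lower bound (inclusive) for a duplication call.
#' @return An object of class `tr_cutoffs`.
#' @export
cutoffs <- function(deletion_max = 0.65, duplication_min = 1.30) {
  if (!is_scalar_number(deletion_max) || !is_scalar_number(duplication_min) ||
      !(deletion_max > 0 && deletion_max < 1 && duplication_min > 1)) {
    stop_masscnv(
      sprintf(
        "invalid cutoffs: need 0 < deletion_max < 1 < duplication_min, got (%s, %s)",
        format(deletion_max), format(duplication_min)
      ),
      "masscnv_calibration_error"
    )
  }
  structure(list(deletion_max = deletion_max, duplication_min = duplication_min),
            class = "tr_cutoffs")
}

#' @export
print.tr_cutoffs <- function(x, ...) {
  cat(sprintf("<tr_cutoffs> deletion: TR <= %.4f | duplication: TR >= %.4f\n",
              x$deletion_max, x$duplication_min))
  invisible(x)
}

#' Call the copy state of a fragment from its Target Ratio
#'
#' Boundary values are inclusive: `TR <= deletion_max` is a deletion and
#' `TR >= duplication_min` a duplication. A TR of zero (template peak absent,
#' homozygous deletion) is a deletion.
#'
#' @param tr Numeric vector of Target Ratio values (non-negative).
#' @param cut A [cutoffs()] object.
#' @return Character vector: `"deletion"`, `"normal"` or `"duplication"`.
#' @export
#' @examples
#' call_fragment(c(0.5, 0.65, 1.0, 1.30, 1.6))
call_fragment <- function(tr, cut = cutoffs()) {
  stopifnot(inherits(cut, "tr_cutoffs"))
  if (length(tr) == 0) return(character(0))
  if (any(!is.finite(tr)) || any(tr < 0)) {
    stop_masscnv("TR values must be finite and non-negative",
                 "masscnv_argument_error")
  }
  ifelse(tr <= cut$deletion_max, "deletion",
         ifelse(tr >= cut$duplication_min, "duplication", "normal"))
}

ratio_aggregate <- function(x, norm) {
  switch(norm,
    mean = mean(x),
    median = stats::median(x),
    geomean = exp(mean(log(x))),
    stop_masscnv(paste0("unknown normalisation mode: ", norm),
                 "masscnv_argument_error")
  )
}

#' Compute Target Ratios with double calibration
#'
#' For every target fragment the raw dosage ratio is
#' `r = intensity_template / intensity_competitor`; the competitor is
#' co-amplified with the same primers at two copies, so `r` cancels
#' per-fragment amplification efficiency. The second calibration divides `r`
#' by the aggregate (`mean` by default) of the same ratio over QC-passing
#' reference-gene fragments in the same multiplex well, giving
#' `TR = r(target) / N(well)`. With noise-free input encoding copy number
#' `c` against two competitor copies, `TR = c / 2` exactly.
#'
#' QC: a fragment with competitor peak 0 is flagged `missing_peak`; a peak
#' below `min_intensity` is flagged `low_intensity`. Flagged target fragments
#' get `call = "no_call"`; flagged reference fragments are dropped from the
#' normaliser. If every reference in a well fails QC, targets in that well
#' are flagged `no_reference`; a sample with no usable reference anywhere is
#' an error ("uncallable sample").
#'
#' @param intensities Intensity tibble (see [read_intensities()]); may hold
#'   one or many samples.
#' @param panel A [fragment_panel].
#' @param cut A [cutoffs()] object.
#' @param min_intensity Minimum acceptable peak intensity (default 0: any
#'   positive peak is accepted).
#' @param norm Reference-ratio aggregation: `"mean"`, `"median"` or
#'   `"geomean"`.
#' @return A tibble with one row per sample x target fragment: `sample_id`,
#'   `fragment_id`, `gene`, `exon_label`, `well`, `ratio_raw`, `normalizer`,
#'   `tr`, `call` and `qc_flags` (comma-joined, empty when clean).
#' @export
compute_tr <- function(intensities, panel, cut = cutoffs(),
                       min_intensity = 0, norm = c("mean", "median", "geomean")) {
  stopifnot(inherits(panel, "fragment_panel"))
  norm <- match.arg(norm)
  frag <- panel$fragments
  unknown <- setdiff(unique(intensities$fragment_id), frag$fragment_id)
  if (length(unknown) > 0) {
    stop_masscnv(
      paste0("intensity rows reference fragments absent from panel: ",
             paste(head(unknown, 5), collapse = ", ")),
      "masscnv_argument_error"
    )
  }

  dat <- dplyr::left_join(intensities, frag, by = "fragment_id")
  dat$qc_low <- min_intensity > 0 &
    (dat$intensity_template < min_intensity |
       dat$intensity_competitor < min_intensity)
  dat$qc_missing <- dat$intensity_competitor == 0
  dat$qc_pass <- !dat$qc_low & !dat$qc_missing
  dat$ratio_raw <- ifelse(dat$intensity_competitor > 0,
                          dat$intensity_template / dat$intensity_competitor,
                          NA_real_)

  out <- vector("list", length(unique(dat$sample_id)))
  names(out) <- unique(dat$sample_id)
  for (s in unique(dat$sample_id)) {
    d <- dat[dat$sample_id == s, ]
    refs <- d[d$role == "reference" & d$qc_pass, ]
    if (nrow(refs) == 0) {
      stop_masscnv(paste0("uncallable sample: ", s,
                          " has no QC-passing reference fragment"),
                   "masscnv_uncallable_sample")
    }
    norm_for_well <- function(w) {
      r <- if (panel$pooled_normalization) refs$ratio_raw else
        refs$ratio_raw[refs$well == w]
      if (length(r) == 0) NA_real_ else ratio_aggregate(r, norm)
    }
    tg <- d[d$role == "target", ]
    if (nrow(tg) == 0) next
    tg$normalizer <- vapply(tg$well, norm_for_well, numeric(1),
                            USE.NAMES = FALSE)
    flags <- mapply(function(low, missing, no_ref) {
      f <- c(if (low) "low_intensity", if (missing) "missing_peak",
             if (no_ref) "no_reference")
      paste(f, collapse = ",")
    }, tg$qc_low, tg$qc_missing, is.na(tg$normalizer))
    tg$qc_flags <- as.character(flags)
    tg$tr <- ifelse(tg$qc_flags == "", tg$ratio_raw / tg$normalizer, NA_real_)
    tg$call <- ifelse(tg$qc_flags == "", call_fragment_safe(tg$tr, cut), "no_call")
    out[[s]] <- tg[, c("sample_id", "fragment_id", "gene", "exon_label", "well",
                       "ratio_raw", "normalizer", "tr", "call", "qc_flags")]
  }
  dplyr::bind_rows(out)
}

# vectorised call_fragment tolerating NA (kept no_call upstream)
call_fragment_safe <- function(tr, cut) {
  res <- rep(NA_character_, length(tr))
  ok <- !is.na(tr)
  if (any(ok)) res[ok] <- call_fragment(tr[ok], cut)
  res
}

#' Calibrate TR cutoffs from control samples
#'
#' The base rule places the cutoffs `k` standard deviations away from the
#' diploid negative-control mean: `deletion_max = mean - k * sd`,
#' `duplication_min = mean + k * sd`. When CNV-positive standard samples are
#' supplied, each proposed cutoff is replaced by the midpoint between the
#' nearest negative-control extreme quantile (0.1% / 99.9%) and the nearest
#' positive-standard TR, whenever that midpoint separates the two label sets
#' and the k-rule does not. The returned cutoffs must classify every supplied
#' standard correctly and every negative control as copy-neutral; otherwise a
#' calibration error lists the values that no cutoff can separate.
#'
#' @param negative_controls TR values from diploid control samples (>= 20).
#' @param deletion_standards,duplication_standards TR values of CNV-positive
#'   standard samples with known deletions / duplications (optional).
#' @param k Width of the diploid band in standard deviations (default 5).
#' @return A [cutoffs()] object.
#' @export
calibrate_cutoffs <- function(negative_controls,
                              deletion_standards = numeric(0),
                              duplication_standards = numeric(0),
                              k = 5) {
  neg <- as.numeric(negative_controls)
  if (length(neg) < 20) {
    stop_masscnv(
      sprintf("need at least 20 negative-control TR values (got %d)", length(neg)),
      "masscnv_calibration_error"
    )
  }
  if (any(!is.finite(neg)) || any(neg <= 0)) {
    stop_masscnv("negative-control TR values must be finite and positive",
                 "masscnv_calibration_error")
  }
  m <- mean(neg)
  s <- stats::sd(neg)
  del_max <- m - k * s
  dup_min <- m + k * s
  q_lo <- unname(stats::quantile(neg, 0.001))
  q_hi <- unname(stats::quantile(neg, 0.999))

  if (length(deletion_standards) > 0) {
    k_separates <- all(deletion_standards <= del_max) && all(neg > del_max)
    mid <- (max(deletion_standards) + q_lo) / 2
    mid_separates <- all(deletion_standards <= mid) && all(neg > mid)
    if (!k_separates && mid_separates) del_max <- mid
  }
  if (length(duplication_standards) > 0) {
    k_separates <- all(duplication_standards >= dup_min) && all(neg < dup_min)
    mid <- (min(duplication_standards) + q_hi) / 2
    mid_separates <- all(duplication_standards >= mid) && all(neg < mid)
    if (!k_separates && mid_separates) dup_min <- mid
  }

  fail_calibration <- function(extra = character(0)) {
    overl <- sort(unique(c(
      neg[neg <= max(c(deletion_standards, -Inf)) |
            neg >= min(c(duplication_standards, Inf))],
      deletion_standards[deletion_standards >= min(neg)],
      duplication_standards[duplication_standards <= max(neg)],
      extra
    )))
    stop_masscnv(
      paste0(
        "cannot calibrate cutoffs separating diploid controls from standards",
        if (length(overl) > 0) {
          paste0("; overlapping/blocking TR values: ",
                 paste(format(head(overl, 10), digits = 4), collapse = ", "))
        } else ""
      ),
      "masscnv_calibration_error"
    )
  }

  if (!(del_max > 0 && del_max < 1 && dup_min > 1)) fail_calibration(c(del_max, dup_min))
  cut <- cutoffs(del_max, dup_min)

  calls_ok <-
    all(call_fragment_safe(deletion_standards, cut) == "deletion") &&
    all(call_fragment_safe(duplication_standards, cut) == "duplication") &&
    all(call_fragment_safe(neg, cut) == "normal")
  if (!calls_ok) fail_calibration()
  cut
}
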