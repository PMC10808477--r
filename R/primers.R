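#' Read primer intervals from BED
#'
#' Converts BED 0-based half-open intervals to the 1-based inclusive
#' convention used by [screen_primers()].
#'
#' @param path Path to a BED file with a name column.
#' @return Tibble with `name`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_primer_bed <- function(path) {
  bed <- read_bed(path)
  tibble::tibble(
    name = ifelse(is.na(bed$name), paste0("primer_", seq_len(nrow(bed))),
                  bed$name),
    chrom = bed$chrom,
    start = bed$start + 1,
    end = bed$end
  )
}

#' Read a frequency-annotated variant table
#'
#' Accepts either a TSV with columns `chrom`, `pos` (1-based) and `af`
#' (alternate-allele frequency), or a VCF (uncompressed or bgzipped) whose
#' INFO field carries `AF`; multi-allelic AF values take the maximum
#' alternate frequency.
#'
#' @param path Path to the variant file.
#' @return Tibble with columns `chrom`, `pos`, `af` (`NA` when missing).
#' @export
read_variant_table <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop_masscnv("vcfR is required to read VCF files", "masscnv_io_error")
    }
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    af_str <- vcfR::extract.info(vcf, element = "AF")
    af <- vapply(af_str, function(x) {
      if (is.na(x)) return(NA_real_)
      suppressWarnings(max(as.numeric(strsplit(x, ",", fixed = TRUE)[[1]])))
    }, numeric(1), USE.NAMES = FALSE)
    return(tibble::tibble(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                          af = af))
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    pos = readr::col_double(),
    af = readr::col_double()
  ))
  missing <- setdiff(c("chrom", "pos", "af"), names(tab))
  if (length(missing) > 0) {
    stop_masscnv(
      paste0("variant table missing column(s): ", paste(missing, collapse = ", ")),
      "masscnv_parse_error"
    )
  }
  tab[, c("chrom", "pos", "af")]
}

#' Screen primers for common SNPs in their binding sites
#'
#' A variant under a primer binding site can suppress amplification of one
#' allele and mimic a heterozygous deletion, so primer intervals must avoid
#' polymorphic positions. A primer is flagged when at least one overlapping
#' variant has minor allele frequency above `maf_max` (default 0.005, i.e.
#' 0.5%). MAF folds the allele frequency: `MAF = min(AF, 1 - AF)`. Variants
#' without a frequency are skipped; their count is reported as a warning.
#'
#' @param primers Tibble with `name`, `chrom`, `start`, `end` (1-based
#'   inclusive), e.g. from [read_primer_bed()].
#' @param variants Tibble with `chrom`, `pos`, `af`, e.g. from
#'   [read_variant_table()].
#' @param maf_max Maximum tolerated minor allele frequency.
#' @return Tibble: one row per primer with `n_overlapping`, `max_maf` and
#'   logical `flagged`.
#' @export
screen_primers <- function(primers, variants, maf_max = 0.005) {
  primers <- tibble::as_tibble(primers)
  variants <- tibble::as_tibble(variants)
  stopifnot(all(c("name", "chrom", "start", "end") %in% names(primers)),
            all(c("chrom", "pos", "af") %in% names(variants)))
  n_missing <- sum(is.na(variants$af))
  if (n_missing > 0) {
    rlang::warn(sprintf("%d variant(s) without allele frequency were skipped",
                        n_missing))
    variants <- variants[!is.na(variants$af), ]
  }
  variants$maf <- pmin(variants$af, 1 - variants$af)
  res <- lapply(seq_len(nrow(primers)), function(i) {
    p <- primers[i, ]
    ov <- variants[variants$chrom == p$chrom &
                     variants$pos >= p$start & variants$pos <= p$end, ]
    tibble::tibble(
      name = p$name, chrom = p$chrom, start = p$start, end = p$end,
      n_overlapping = nrow(ov),
      max_maf = if (nrow(ov) > 0) max(ov$maf) else NA_real_,
      flagged = nrow(ov) > 0 && any(ov$maf > maf_max)
    )
  })
  dplyr::bind_rows(res)
}
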