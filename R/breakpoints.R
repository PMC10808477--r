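#' Parse an HGVS-style genomic deletion/duplication
#'
#' Accepts strings like `"g.61,101_98,034del"`, optionally prefixed with a
#' reference sequence name (`"NG_005905.2:g.61101_98034del"`). Thousands
#' separators are stripped. Coordinates follow the HGVS g. convention:
#' 1-based, inclusive at both ends.
#'
#' @param text A single coordinate string.
#' @return An object of class `genomic_variant`: list with `sequence_name`
#'   (may be `NA`), `start`, `end`, `kind` (`"del"` or `"dup"`).
#' @export
#' @examples
#' parse_hgvs_g("g.61,101_98,034del")
parse_hgvs_g <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  m <- regexec("^(?:([A-Za-z0-9_.]+):)?g\\.([0-9,]+)_([0-9,]+)(del|dup)$",
               trimws(text))
  parts <- regmatches(trimws(text), m)[[1]]
  if (length(parts) == 0) {
    stop_masscnv(paste0("cannot parse genomic variant: '", text, "'"),
                 "masscnv_parse_error")
  }
  start <- as.numeric(gsub(",", "", parts[3], fixed = TRUE))
  end <- as.numeric(gsub(",", "", parts[4], fixed = TRUE))
  if (is.na(start) || is.na(end) || start < 1 || start > end) {
    stop_masscnv(
      paste0("invalid coordinates in '", text, "': need 1 <= start <= end"),
      "masscnv_parse_error"
    )
  }
  structure(list(
    sequence_name = if (nzchar(parts[2])) parts[2] else NA_character_,
    start = start, end = end, kind = parts[5]
  ), class = "genomic_variant")
}

#' @export
print.genomic_variant <- function(x, ...) {
  cat(sprintf("<genomic_variant> %sg.%s_%s%s (%d bp)\n",
              if (is.na(x$sequence_name)) "" else paste0(x$sequence_name, ":"),
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              x$kind, event_size(x)))
  invisible(x)
}

#' Size of a genomic event in bp
#' @param v A `genomic_variant`.
#' @return `end - start + 1`.
#' @export
event_size <- function(v) {
  stopifnot(inherits(v, "genomic_variant"))
  as.integer(v$end - v$start + 1)
}

#' Junction microhomology of a deletion (or tandem duplication)
#'
#' Measures the breakpoint-ambiguity length: how far the (start, end)
#' placement can slide while producing an identical rearranged sequence.
#' Extended identity (tens of bp, e.g. between Alu elements) is the
#' signature of non-allelic homologous recombination; blunt or few-bp
#' junctions point to end-joining. The forward component is the longest `k`
#' with `ref[start..start+k-1] == ref[end+1..end+k]`; the backward component
#' mirrors it upstream; their sum equals the number of shift-equivalent
#' placements minus one. A tandem duplication's novel junction (end joined
#' back to start) has the same ambiguity, so the identical computation
#' applies to both kinds.
#'
#' @param v A `genomic_variant`.
#' @param reference Reference sequence: a character string, or a
#'   `Biostrings::DNAString`/`DNAStringSet` (first sequence used), covering
#'   at least positions 1..end of the variant.
#' @return A list with `homology_len` and `start_range` (the inclusive range
#'   of alternative start placements yielding an identical mutant sequence).
#' @export
junction_homology <- function(v, reference) {
  stopifnot(inherits(v, "genomic_variant"))
  ref <- as_reference_string(reference)
  L <- nchar(ref)
  if (v$end > L) {
    stop_masscnv(
      sprintf("reference too short: variant needs positions 1..%d, have %d",
              v$end, L),
      "masscnv_argument_error"
    )
  }
  chars <- strsplit(ref, "", fixed = TRUE)[[1]]
  # forward: ref[start + j] vs ref[end + 1 + j]
  fwd_max <- L - v$end
  k1 <- 0L
  if (fwd_max > 0) {
    a <- chars[v$start + seq_len(fwd_max) - 1]
    b <- chars[v$end + seq_len(fwd_max)]
    neq <- which(a != b)
    k1 <- if (length(neq) == 0) fwd_max else neq[1] - 1L
  }
  # backward: ref[start - j] vs ref[end - j + 1]
  bwd_max <- v$start - 1
  k2 <- 0L
  if (bwd_max > 0) {
    a <- chars[v$start - seq_len(bwd_max)]
    b <- chars[v$end - seq_len(bwd_max) + 1]
    neq <- which(a != b)
    k2 <- if (length(neq) == 0) bwd_max else neq[1] - 1L
  }
  list(
    homology_len = as.integer(k1 + k2),
    start_range = c(v$start - k2, v$start + k1)
  )
}

as_reference_string <- function(reference) {
  if (is.character(reference)) {
    if (length(reference) != 1) reference <- reference[[1]]
    return(toupper(reference))
  }
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    if (methods::is(reference, "DNAStringSet")) {
      return(toupper(as.character(reference[[1]])))
    }
    if (methods::is(reference, "DNAString") || methods::is(reference, "XString")) {
      return(toupper(as.character(reference)))
    }
  }
  stop_masscnv("reference must be a character string or Biostrings object",
               "masscnv_argument_error")
}

#' Read a reference FASTA
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector of sequences.
#' @export
read_reference_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop_masscnv("Biostrings is required to read FASTA files",
                 "masscnv_io_error")
  }
  seqs <- Biostrings::readDNAStringSet(path)
  setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
}

# Collapse a repeat name to its element family for same-family NAHR evidence
# (AluSx and AluSz are both Alu; L1PA2 and L1MB5 are both L1; etc.).
repeat_family <- function(name) {
  vapply(name, function(x) {
    if (is.na(x) || !nzchar(x)) return(NA_character_)
    if (grepl("^Alu", x)) return("Alu")
    if (grepl("^L1", x)) return("L1")
    if (grepl("^L2", x)) return("L2")
    if (grepl("^MIR", x)) return("MIR")
    if (grepl("^(LTR|ERV|MLT|THE|MST)", x)) return("LTR")
    x
  }, character(1), USE.NAMES = FALSE)
}

#' Classify the rearrangement mechanism of a junction
#'
#' NAHR (non-allelic homologous recombination) when junction homology is at
#' least `nahr_min` bp, or when both breakpoints lie in annotated repeats of
#' the same family (e.g. two Alu elements) and the homology does not
#' contradict it; NHEJ (non-homologous end-joining) for junctions with at
#' most `nhej_max` bp of homology; MMEJ (microhomology-mediated end-joining)
#' in between. When same-family repeat evidence meets an end-joining-sized
#' junction (homology <= `nhej_max`) the two lines of evidence conflict and
#' the call is `"ambiguous"`.
#'
#' @param homology_len Junction homology in bp.
#' @param repeat_left,repeat_right Repeat element names at the two
#'   breakpoints, or `NA`.
#' @param nahr_min Minimum homology for NAHR (default 30 bp).
#' @param nhej_max Maximum homology for NHEJ (default 3 bp).
#' @return One of `"NAHR"`, `"NHEJ"`, `"MMEJ"`, `"ambiguous"`.
#' @export
classify_mechanism <- function(homology_len, repeat_left = NA,
                               repeat_right = NA,
                               nahr_min = 30, nhej_max = 3) {
  stopifnot(homology_len >= 0, nhej_max < nahr_min)
  fams <- repeat_family(c(repeat_left, repeat_right))
  same_family <- !anyNA(fams) && fams[1] == fams[2]
  if (homology_len >= nahr_min) return("NAHR")
  if (same_family) {
    if (homology_len <= nhej_max) return("ambiguous")
    return("NAHR")
  }
  if (homology_len <= nhej_max) return("NHEJ")
  "MMEJ"
}

#' Read BED-style intervals
#'
#' Minimal 0-based half-open interval reader with mandatory columns
#' chrom/start/end and an optional fourth name column. Parse failures report
#' the offending line number.
#'
#' @param path Path to the BED file.
#' @return Tibble with columns `chrom`, `start`, `end`, `name`, `line`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) {
    stop_masscnv(paste0("BED file not found: ", path), "masscnv_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) &
                  !grepl("^(#|track|browser)", trimws(lines)))
  rows <- lapply(keep, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop_masscnv(paste0("malformed BED line ", i, ": fewer than 3 fields"),
                   "masscnv_parse_error")
    }
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end) || start < 0 || end < start) {
      stop_masscnv(paste0("malformed BED line ", i, ": bad interval '",
                          f[2], "'-'", f[3], "'"),
                   "masscnv_parse_error")
    }
    tibble::tibble(chrom = f[1], start = start, end = end,
                   name = if (length(f) >= 4) f[4] else NA_character_,
                   line = i)
  })
  if (length(rows) == 0) {
    return(tibble::tibble(chrom = character(0), start = numeric(0),
                          end = numeric(0), name = character(0),
                          line = integer(0)))
  }
  dplyr::bind_rows(rows)
}

#' Annotate breakpoints with overlapping repeat elements
#'
#' For each of the two breakpoints (variant start and end, 1-based) reports
#' the name of the repeat interval containing it, after converting to the
#' BED 0-based half-open convention. When several repeats contain a
#' breakpoint the longest interval wins, ties broken by file order.
#'
#' @param v A `genomic_variant`.
#' @param repeats Repeat intervals as returned by [read_bed()].
#' @return A list with `repeat_left` and `repeat_right` (names or `NA`).
#' @export
annotate_repeats <- function(v, repeats) {
  stopifnot(inherits(v, "genomic_variant"))
  rep_tab <- tibble::as_tibble(repeats)
  if (!is.na(v$sequence_name) && "chrom" %in% names(rep_tab) &&
      any(rep_tab$chrom == v$sequence_name)) {
    rep_tab <- rep_tab[rep_tab$chrom == v$sequence_name, ]
  }
  hit_at <- function(pos1) {
    p0 <- pos1 - 1  # 0-based position of the 1-based breakpoint
    hits <- rep_tab[rep_tab$start <= p0 & p0 < rep_tab$end, ]
    if (nrow(hits) == 0) return(NA_character_)
    len <- hits$end - hits$start
    hits$name[order(-len, seq_len(nrow(hits)))[1]]
  }
  list(repeat_left = hit_at(v$start), repeat_right = hit_at(v$end))
}

#' Full breakpoint characterisation
#'
#' Combines size, junction homology, optional repeat annotation and
#' mechanism classification into one report.
#'
#' @param v A `genomic_variant` (or coordinate string for [parse_hgvs_g()]).
#' @param reference Optional reference sequence (see [junction_homology()]).
#' @param repeats Optional repeat intervals from [read_bed()].
#' @param nahr_min,nhej_max Mechanism thresholds (bp).
#' @return A one-row tibble: coordinates, `size_bp`, `homology_len`,
#'   `repeat_left`, `repeat_right`, `mechanism`.
#' @export
breakpoint_report <- function(v, reference = NULL, repeats = NULL,
                              nahr_min = 30, nhej_max = 3) {
  if (is.character(v)) v <- parse_hgvs_g(v)
  hom <- if (!is.null(reference)) {
    junction_homology(v, reference)$homology_len
  } else NA_integer_
  reps <- if (!is.null(repeats)) {
    annotate_repeats(v, repeats)
  } else list(repeat_left = NA_character_, repeat_right = NA_character_)
  mech <- if (!is.na(hom)) {
    classify_mechanism(hom, reps$repeat_left, reps$repeat_right,
                       nahr_min = nahr_min, nhej_max = nhej_max)
  } else NA_character_
  tibble::tibble(
    sequence_name = v$sequence_name, start = v$start, end = v$end,
    kind = v$kind, size_bp = event_size(v), homology_len = hom,
    repeat_left = reps$repeat_left, repeat_right = reps$repeat_right,
    mechanism = mech
  )
}
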