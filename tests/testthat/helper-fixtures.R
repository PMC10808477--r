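# Shared fixtures and independent oracles, built in code at test time.

# minimal valid panel: 2 BRCA1 targets + 3 references, one well
mini_panel <- function() {
  fragment_panel(
    tibble::tibble(
      fragment_id = c("B1e1", "B1e2", "ALB_W1", "EIF2C1_W1", "RNaseP_W1"),
      gene        = c("BRCA1", "BRCA1", "ALB", "EIF2C1", "RNaseP"),
      exon_label  = c("ex1", "ex2", "ref", "ref", "ref"),
      role        = c("target", "target", "reference", "reference", "reference"),
      well        = "W1",
      order_index = c(1, 2, NA, NA, NA)
    ),
    name = "mini"
  )
}

# flat intensity table for one sample on a panel: every peak = `value`
flat_intensities <- function(panel, sample_id = "S1", value = 1000) {
  tibble::tibble(
    sample_id = sample_id,
    fragment_id = panel$fragments$fragment_id,
    intensity_template = value,
    intensity_competitor = value
  )
}

# independent oracle for junction homology: enumerate every placement of a
# deletion of the same size and count those producing an identical mutant
brute_force_homology <- function(ref, start, end) {
  L <- nchar(ref)
  size <- end - start + 1
  mutant <- paste0(substr(ref, 1, start - 1), substr(ref, end + 1, L))
  count <- 0L
  for (s in seq_len(L - size + 1)) {
    e <- s + size - 1
    alt <- paste0(substr(ref, 1, s - 1), substr(ref, e + 1, L))
    if (alt == mutant) count <- count + 1L
  }
  count - 1L
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
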