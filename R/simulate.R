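#' Configure an intensity simulation
#'
#' The generative model mirrors the assay physics: template gDNA and a
#' competitor oligo are co-amplified with the same primers, so both share a
#' per-fragment-per-sample amplification efficiency `a ~ LogNormal(0,
#' sigma_efficiency^2)`. The competitor is input at two copies; the template
#' dosage is the true copy number. Measured peaks carry independent
#' multiplicative lognormal noise (`sigma_noise` on the log scale):
#'
#' \preformatted{
#'   intensity_template   = base * a * (d_T / 2) * exp(e1)
#'   intensity_competitor = base * a * (d_C / 2) * exp(e2),  d_C = 2
#' }
#'
#' An allele-dropout artifact (an SNV under a primer binding site suppressing
#' one template allele, the competitor being unaffected) reduces the template
#' dosage of the affected fragment by `dropout_fraction` of one allele:
#' `d_T = copy_number - dropout_fraction`. With full dropout on a diploid
#' fragment this yields TR 0.5 downstream -- a false-positive deletion.
#'
#' @param panel A [fragment_panel].
#' @param n_samples Number of samples; ids are `S001`, `S002`, ...
#' @param truth Tibble with columns `sample_id`, `fragment_id`, `copy_number`
#'   (integer 0..4) for every sample x fragment that deviates from the
#'   diploid default of 2. Target fragments only.
#' @param artifact Tibble with columns `sample_id`, `fragment_id`,
#'   `dropout_fraction` in \[0, 1\]. Target fragments only.
#' @param sigma_noise SD of the additive Gaussian on log intensity
#'   (default 0.05).
#' @param sigma_efficiency SD of the shared log-efficiency per
#'   fragment x sample (default 0.3).
#' @param base_intensity Baseline peak intensity in spectrometer units
#'   (default 10000).
#' @param missing_peak_prob Probability that a fragment's competitor peak is
#'   zeroed (missing peak), default 0.
#' @return A `sim_config` list, validated.
#' @export
simulation_config <- function(panel, n_samples,
                              truth = NULL, artifact = NULL,
                              sigma_noise = 0.05, sigma_efficiency = 0.3,
                              base_intensity = 10000,
                              missing_peak_prob = 0) {
  stopifnot(inherits(panel, "fragment_panel"))
  if (!is_scalar_number(n_samples) || n_samples < 1) {
    stop_masscnv("n_samples must be a positive integer", "masscnv_config_error")
  }
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  frag <- panel$fragments
  targets <- frag$fragment_id[frag$role == "target"]

  truth <- if (is.null(truth)) {
    tibble::tibble(sample_id = character(0), fragment_id = character(0),
                   copy_number = integer(0))
  } else tibble::as_tibble(truth)
  artifact <- if (is.null(artifact)) {
    tibble::tibble(sample_id = character(0), fragment_id = character(0),
                   dropout_fraction = numeric(0))
  } else tibble::as_tibble(artifact)

  check_refs <- function(tab, what) {
    bad_s <- setdiff(tab$sample_id, sample_ids)
    bad_f <- setdiff(tab$fragment_id, frag$fragment_id)
    if (length(bad_s) > 0 || length(bad_f) > 0) {
      stop_masscnv(
        paste0(what, " references unknown sample/fragment: ",
               paste(c(bad_s, bad_f), collapse = ", ")),
        "masscnv_config_error"
      )
    }
    on_ref <- setdiff(tab$fragment_id, targets)
    if (length(on_ref) > 0) {
      stop_masscnv(
        paste0(what, " must not touch reference fragments: ",
               paste(on_ref, collapse = ", ")),
        "masscnv_config_error"
      )
    }
  }
  check_refs(truth, "truth")
  check_refs(artifact, "artifact")
  if (nrow(truth) > 0 && !all(truth$copy_number %in% 0:4)) {
    stop_masscnv("copy_number must be an integer in 0..4", "masscnv_config_error")
  }
  if (nrow(artifact) > 0 &&
      !all(artifact$dropout_fraction >= 0 & artifact$dropout_fraction <= 1)) {
    stop_masscnv("dropout_fraction must lie in [0, 1]", "masscnv_config_error")
  }
  stopifnot(sigma_noise >= 0, sigma_efficiency >= 0, base_intensity > 0,
            missing_peak_prob >= 0, missing_peak_prob <= 1)

  structure(list(
    panel = panel, n_samples = as.integer(n_samples), sample_ids = sample_ids,
    truth = truth, artifact = artifact,
    sigma_noise = sigma_noise, sigma_efficiency = sigma_efficiency,
    base_intensity = base_intensity, missing_peak_prob = missing_peak_prob
  ), class = "sim_config")
}

#' Simulate a multiplexed peak-intensity table with known truth
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; the same seed yields bit-identical output.
#' @return A list with `intensities` (tibble as read by [read_intensities()]),
#'   and `truth`: a list with `copy_numbers` (sample x fragment tibble),
#'   `events` (true exon-range events via [merge_events()] semantics) and
#'   `status` (per-sample `cnv_positive`/`cnv_negative`).
#' @export
simulate_intensities <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  panel <- config$panel
  frag <- panel$fragments

  grid <- tidyr::expand_grid(sample_id = config$sample_ids,
                             fragment_id = frag$fragment_id)
  grid <- dplyr::left_join(grid, frag[, c("fragment_id", "role")],
                           by = "fragment_id")
  grid <- dplyr::left_join(grid, config$truth,
                           by = c("sample_id", "fragment_id"))
  grid$copy_number <- ifelse(grid$role == "reference", 2L,
                             ifelse(is.na(grid$copy_number), 2L,
                                    grid$copy_number))
  grid <- dplyr::left_join(grid, config$artifact,
                           by = c("sample_id", "fragment_id"))
  grid$dropout_fraction[is.na(grid$dropout_fraction)] <- 0

  n <- nrow(grid)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  log_a <- rnorm(n, 0, config$sigma_efficiency)
  e1 <- rnorm(n, 0, config$sigma_noise)
  e2 <- rnorm(n, 0, config$sigma_noise)
  drop_comp <- runif(n) < config$missing_peak_prob

  d_t <- grid$copy_number - grid$dropout_fraction
  base <- config$base_intensity
  grid$intensity_template <- base * exp(log_a) * (d_t / 2) * exp(e1)
  grid$intensity_competitor <- base * exp(log_a) * exp(e2)
  grid$intensity_competitor[drop_comp] <- 0

  intensities <- grid[, c("sample_id", "fragment_id",
                          "intensity_template", "intensity_competitor")]
  truth_cn <- grid[grid$role == "target",
                   c("sample_id", "fragment_id", "copy_number")]
  truth <- truth_from_copy_numbers(truth_cn, panel, config$sample_ids)
  list(intensities = tibble::as_tibble(intensities), truth = truth,
       config = config)
}

# Build the truth-table side of a simulation: true events via the same
# run-merging semantics as the caller, and per-sample status.
truth_from_copy_numbers <- function(truth_cn, panel, sample_ids) {
  pseudo <- tibble::as_tibble(truth_cn)
  frag <- panel$fragments[, c("fragment_id", "gene", "exon_label", "well")]
  pseudo <- dplyr::left_join(pseudo, frag, by = "fragment_id")
  pseudo$tr <- pseudo$copy_number / 2
  pseudo$ratio_raw <- pseudo$tr
  pseudo$normalizer <- 1
  pseudo$call <- ifelse(pseudo$copy_number < 2, "deletion",
                        ifelse(pseudo$copy_number > 2, "duplication", "normal"))
  pseudo$qc_flags <- ""
  events <- merge_events(pseudo, panel)
  list(
    copy_numbers = tibble::as_tibble(truth_cn),
    events = events,
    status = sample_status(events, samples = sample_ids)
  )
}

#' Simulate the 293-sample study cohort
#'
#' Builds a cohort on the shipped [fixture_panel()] emulating the study
#' composition: 8 true CNV-positive samples (two BRCA1 exon 1-2 deletions,
#' one BRCA1 exon 1 deletion, one BRCA1 exon 1-2 duplication, one BRCA1
#' exon 5-10 deletion, one BRCA2 exon 17-18 deletion and two BRCA2
#' part-of-exon-11 deletions), 4 samples with a full allele-dropout artifact
#' (an SNV under a primer binding site; truly diploid but indistinguishable
#' from a heterozygous deletion on the affected fragment), and 281 plain
#' diploid samples.
#'
#' @param seed Integer seed.
#' @param sigma_noise,sigma_efficiency Noise parameters passed to
#'   [simulation_config()]; set `sigma_noise = 0, sigma_efficiency = 0` for
#'   the deterministic limit.
#' @return As [simulate_intensities()] (the `config` element holds the full
#'   [simulation_config()]).
#' @export
make_study_fixture <- function(seed = 1, sigma_noise = 0.05,
                               sigma_efficiency = 0.3) {
  panel <- fixture_panel()
  n_samples <- 293
  ids <- sprintf("S%03d", seq_len(n_samples))

  b1 <- function(labels) paste0("B1_", labels)
  b2 <- function(labels) paste0("B2_", labels)
  cnv <- list(
    list(s = 1, f = b1(c("ex1", "ex2")), cn = 1L),              # BRCA1 ex1-2 del
    list(s = 2, f = b1("ex1"), cn = 1L),                        # BRCA1 ex1 del
    list(s = 3, f = b1(c("ex1", "ex2")), cn = 1L),              # BRCA1 ex1-2 del
    list(s = 4, f = b2(c("ex17", "ex18")), cn = 1L),            # BRCA2 ex17-18 del
    list(s = 5, f = b1(c("ex1", "ex2")), cn = 3L),              # BRCA1 ex1-2 dup
    list(s = 6, f = b1(paste0("ex", 5:10)), cn = 1L),           # BRCA1 ex5-10 del
    list(s = 11, f = b2(c("ex11_part2", "ex11_part3")), cn = 1L), # BRCA2 part ex11
    list(s = 12, f = b2(c("ex11_part3", "ex11_part4")), cn = 1L)  # BRCA2 part ex11
  )
  truth <- dplyr::bind_rows(lapply(cnv, function(x) {
    tibble::tibble(sample_id = ids[x$s], fragment_id = x$f, copy_number = x$cn)
  }))
  # samples 7-10: diploid, but one fragment suffers complete allele dropout
  artifact <- tibble::tibble(
    sample_id = ids[7:10],
    fragment_id = c(b1("ex14"), b1("ex20"), b2("ex3"), b2("ex24")),
    dropout_fraction = 1
  )
  config <- simulation_config(
    panel, n_samples, truth = truth, artifact = artifact,
    sigma_noise = sigma_noise, sigma_efficiency = sigma_efficiency
  )
  simulate_intensities(config, seed = seed)
}
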