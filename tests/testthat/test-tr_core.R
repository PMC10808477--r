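test_that("TR is the raw ratio normalised by the within-well reference mean", {
  p <- mini_panel()

  # identity case: every peak equal -> TR 1.0 everywhere
  res <- compute_tr(flat_intensities(p), p)
  expect_equal(res$tr, c(1, 1))
  expect_equal(res$call, c("normal", "normal"))

  # heterozygous-deletion idealisation: target at half dosage
  intens <- flat_intensities(p)
  intens$intensity_template[intens$fragment_id == "B1e1"] <- 500
  res <- compute_tr(intens, p)
  expect_equal(res$ratio_raw[res$fragment_id == "B1e1"], 0.5)
  expect_equal(res$normalizer[res$fragment_id == "B1e1"], 1.0)
  expect_equal(res$tr[res$fragment_id == "B1e1"], 0.5)
  expect_equal(res$call[res$fragment_id == "B1e1"], "deletion")

  # hand arithmetic: reference ratios 0.9/1.0/1.1 -> N = 1.0; target r = 1.5
  intens <- flat_intensities(p)
  intens$intensity_template[intens$fragment_id == "ALB_W1"] <- 900
  intens$intensity_template[intens$fragment_id == "EIF2C1_W1"] <- 1000
  intens$intensity_template[intens$fragment_id == "RNaseP_W1"] <- 1100
  intens$intensity_template[intens$fragment_id == "B1e1"] <- 1500
  res <- compute_tr(intens, p)
  expect_equal(res$normalizer[res$fragment_id == "B1e1"], 1.0)
  expect_equal(res$tr[res$fragment_id == "B1e1"], 1.5)
  expect_equal(res$call[res$fragment_id == "B1e1"], "duplication")

  # median / geometric-mean aggregation are selectable
  res_med <- compute_tr(intens, p, norm = "median")
  expect_equal(res_med$normalizer[1], 1.0)
  res_geo <- compute_tr(intens, p, norm = "geomean")
  expect_equal(res_geo$normalizer[1], exp(mean(log(c(0.9, 1, 1.1)))))
})

test_that("QC flags produce no_call and reference failures cascade", {
  p <- mini_panel()

  # competitor peak 0 on a target -> missing_peak, no_call
  intens <- flat_intensities(p)
  intens$intensity_competitor[intens$fragment_id == "B1e1"] <- 0
  res <- compute_tr(intens, p)
  expect_equal(res$call[res$fragment_id == "B1e1"], "no_call")
  expect_match(res$qc_flags[res$fragment_id == "B1e1"], "missing_peak")
  expect_true(is.na(res$tr[res$fragment_id == "B1e1"]))
  expect_equal(res$call[res$fragment_id == "B1e2"], "normal")

  # low_intensity below an explicit threshold
  intens <- flat_intensities(p)
  intens$intensity_template[intens$fragment_id == "B1e2"] <- 50
  res <- compute_tr(intens, p, min_intensity = 100)
  expect_match(res$qc_flags[res$fragment_id == "B1e2"], "low_intensity")
  expect_equal(res$call[res$fragment_id == "B1e2"], "no_call")

  # all references in the well fail -> every target no_reference;
  # the sample has no usable reference anywhere -> uncallable
  intens <- flat_intensities(p)
  intens$intensity_competitor[intens$fragment_id %in%
                                c("ALB_W1", "EIF2C1_W1", "RNaseP_W1")] <- 0
  expect_error(compute_tr(intens, p), "uncallable",
               class = "masscnv_uncallable_sample")
})

test_that("cutoff boundaries are inclusive and TR zero is a deletion", {
  expect_equal(call_fragment(0.5), "deletion")
  expect_equal(call_fragment(0.65), "deletion")
  expect_equal(call_fragment(1.0), "normal")
  expect_equal(call_fragment(1.30), "duplication")
  expect_equal(call_fragment(0.6500001), "normal")
  expect_equal(call_fragment(1.2999999), "normal")
  expect_equal(call_fragment(0), "deletion")  # homozygous loss
  expect_error(call_fragment(-0.1), class = "masscnv_argument_error")
  expect_error(cutoffs(1.2, 1.3), class = "masscnv_calibration_error")
  expect_error(cutoffs(0.65, 0.9), class = "masscnv_calibration_error")
})

test_that("TR is invariant to sample scaling and per-fragment efficiency", {
  p <- fixture_panel()
  sim <- simulate_intensities(simulation_config(p, n_samples = 3), seed = 21)
  base <- compute_tr(sim$intensities, p)

  for (c_scale in c(0.01, 3.7, 1e4)) {
    scaled <- sim$intensities
    scaled$intensity_template <- scaled$intensity_template * c_scale
    scaled$intensity_competitor <- scaled$intensity_competitor * c_scale
    res <- compute_tr(scaled, p)
    expect_equal(res$tr, base$tr, tolerance = 1e-12)
  }

  # competitor calibration: per-fragment efficiency multiplies template and
  # competitor of single fragments and cancels in TR
  set.seed(31)
  eff <- runif(nrow(sim$intensities), 0.2, 5)
  warped <- sim$intensities
  warped$intensity_template <- warped$intensity_template * eff
  warped$intensity_competitor <- warped$intensity_competitor * eff
  res <- compute_tr(warped, p)
  expect_equal(res$tr, base$tr, tolerance = 1e-12)
})

test_that("TR is monotone in target and reference template intensities", {
  p <- mini_panel()
  intens <- flat_intensities(p)
  tr_of <- function(x) x$tr[x$fragment_id == "B1e1"]
  base <- tr_of(compute_tr(intens, p))

  up <- intens
  up$intensity_template[up$fragment_id == "B1e1"] <- 1200
  expect_gt(tr_of(compute_tr(up, p)), base)

  ref_up <- intens
  ref_up$intensity_template[ref_up$fragment_id == "ALB_W1"] <- 1200
  expect_lt(tr_of(compute_tr(ref_up, p)), base)
})

test_that("cutoff calibration follows mean +/- k*sd and honours standards", {
  # clean separation: negatives around 1, standards at 0.5 / 1.5
  neg <- rep(c(0.95, 1.0, 1.05), 10)
  cut <- calibrate_cutoffs(neg, deletion_standards = 0.5,
                           duplication_standards = 1.5)
  expect_equal(call_fragment(0.5, cut), "deletion")
  expect_equal(call_fragment(1.5, cut), "duplication")
  expect_true(all(call_fragment(neg, cut) == "normal"))

  # degenerate: zero-spread negatives cannot give 0 < del_max < 1
  expect_error(calibrate_cutoffs(rep(1.0, 25)),
               class = "masscnv_calibration_error")

  # fewer than 20 negatives is rejected
  expect_error(calibrate_cutoffs(c(0.9, 1.0, 1.1)),
               class = "masscnv_calibration_error")

  # inseparable labels: a deletion standard inside the diploid cloud
  expect_error(
    calibrate_cutoffs(rep(c(0.95, 1, 1.05), 10), deletion_standards = 1.0),
    "overlap", class = "masscnv_calibration_error"
  )
})

test_that("Monte-Carlo calibration on simulated diploid controls lands near the shipped cutoffs", {
  p <- mini_panel()
  sim <- simulate_intensities(
    simulation_config(p, n_samples = 50, sigma_noise = 0.05), seed = 91
  )
  tr <- compute_tr(sim$intensities, p)$tr
  cut <- calibrate_cutoffs(tr, deletion_standards = 0.5,
                           duplication_standards = 1.5, k = 5)
  expect_gte(cut$deletion_max, 0.55)
  expect_lte(cut$deletion_max, 0.80)
  expect_gte(cut$duplication_min, 1.20)
  expect_lte(cut$duplication_min, 1.45)
})
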