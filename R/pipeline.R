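#' Run the full calling pipeline on an intensity table
#'
#' Convenience wrapper: [compute_tr()] then [merge_events()] then
#' [sample_status()] for every sample in the table.
#'
#' @inheritParams compute_tr
#' @param min_fragments Minimum fragments per event (see [merge_events()]).
#' @return A list with `calls` (per-fragment TR results), `events` and
#'   `status` (per-sample tibble).
#' @export
call_cnvs <- function(intensities, panel, cut = cutoffs(),
                      min_intensity = 0, norm = "mean", min_fragments = 1) {
  calls <- compute_tr(intensities, panel, cut = cut,
                      min_intensity = min_intensity, norm = norm)
  events <- merge_events(calls, panel, min_fragments = min_fragments)
  status <- sample_status(events, samples = unique(calls$sample_id))
  list(calls = calls, events = events, status = status)
}

#' Evaluate a simulated cohort end to end
#'
#' Runs [call_cnvs()] on simulated intensities and scores sample-level
#' status against the simulation truth.
#'
#' @param sim Output of [simulate_intensities()] or [make_study_fixture()].
#' @inheritParams call_cnvs
#' @return A list with `pipeline` (the [call_cnvs()] output), `cm`
#'   (confusion matrix) and `metrics` tibble.
#' @export
evaluate_simulation <- function(sim, cut = cutoffs(), min_intensity = 0,
                                norm = "mean", min_fragments = 1) {
  panel <- sim$config$panel
  pipe <- call_cnvs(sim$intensities, panel, cut = cut,
                    min_intensity = min_intensity, norm = norm,
                    min_fragments = min_fragments)
  cm <- confusion(pipe$status, sim$truth$status)
  list(pipeline = pipe, cm = cm, metrics = metrics(cm))
}
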