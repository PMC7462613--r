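# End-to-end convenience for simulated experiments.

#' Score a simulated experiment
#'
#' Runs the scoring pipeline on the count tensor of one assay of a
#' [simulate_sortseq()] result, using the simulator's own truth table as
#' the variant universe.
#'
#' @param sim A [simulate_sortseq()] result.
#' @param assay `"abundance"` or `"activity"`.
#' @param params A [scoring_params()].
#' @param ... Passed to [score_variants()].
#' @return A [score_variants()] table.
#' @export
sim_scores <- function(sim, assay = c("abundance", "activity"),
                       params = scoring_params(), ...) {
  stopifnot(inherits(sim, "sim_experiment"))
  assay <- match.arg(assay)
  score_variants(sim[[assay]]$reads$counts, sim$truth$variants, params, ...)
}
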