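#' Reagent cost inputs for a depletion reaction
#'
#' Defaults are the benchmarked values: ~$450 up-front for a synthesized
#' oligo probe set yielding >12,000 reactions, $4.98 of amplicon probe and
#' $12.90 of shared reagents per reaction.
#'
#' @param oligo_upfront Up-front cost of one synthesized probe set.
#' @param oligo_yield_reactions Reactions one probe set supports.
#' @param amplicon_per_reaction Amplicon probe cost per reaction.
#' @param shared_reagents_per_reaction Other reagent cost per reaction.
#' @return List of class `cost_inputs`.
#' @export
cost_inputs <- function(oligo_upfront = 450,
                        oligo_yield_reactions = 12000L,
                        amplicon_per_reaction = 4.98,
                        shared_reagents_per_reaction = 12.90) {
  stopifnot(oligo_upfront >= 0, oligo_yield_reactions >= 1,
            amplicon_per_reaction >= 0, shared_reagents_per_reaction >= 0)
  structure(list(oligo_upfront = oligo_upfront,
                 oligo_yield_reactions = as.integer(oligo_yield_reactions),
                 amplicon_per_reaction = amplicon_per_reaction,
                 shared_reagents_per_reaction = shared_reagents_per_reaction),
            class = "cost_inputs")
}

#' Per-reaction costs for oligo and amplicon probes
#'
#' Oligo probe cost per reaction is the up-front probe set cost amortized
#' over its reaction yield; totals add the shared reagents.
#'
#' @param inputs A [cost_inputs()].
#' @return List with `oligo_probe`, `amplicon_probe`, `oligo_total`,
#'   `amplicon_total` (currency per reaction).
#' @export
per_reaction_costs <- function(inputs = cost_inputs()) {
  oligo_probe <- inputs$oligo_upfront / inputs$oligo_yield_reactions
  list(oligo_probe = oligo_probe,
       amplicon_probe = inputs$amplicon_per_reaction,
       oligo_total = oligo_probe + inputs$shared_reagents_per_reaction,
       amplicon_total = inputs$amplicon_per_reaction +
         inputs$shared_reagents_per_reaction)
}

#' Break-even reaction count for synthesized probes
#'
#' Smallest integer n with
#' `oligo_upfront + n * oligo_per_reaction <= n * amplicon_per_reaction`
#' (shared reagents cancel). Also reported rounded to the nearest ten, and
#' the simpler `upfront / amplicon` ratio ignoring the amortized oligo cost.
#'
#' @param inputs A [cost_inputs()].
#' @return List with `exact` (integer, `NA` when no break-even exists),
#'   `nearest_ten`, `ratio_ignoring_oligo`.
#' @export
breakeven_reactions <- function(inputs = cost_inputs()) {
  oligo_per <- inputs$oligo_upfront / inputs$oligo_yield_reactions
  gap <- inputs$amplicon_per_reaction - oligo_per
  if (gap <= 0)
    return(list(exact = NA_integer_, nearest_ten = NA_integer_,
                ratio_ignoring_oligo = NA_real_))
  exact <- max(1L, as.integer(ceiling(inputs$oligo_upfront / gap)))
  list(exact = exact, nearest_ten = as.integer(round(exact / 10) * 10),
       ratio_ignoring_oligo = inputs$oligo_upfront /
         inputs$amplicon_per_reaction)
}

#' Probe mass for a hybridization reaction
#'
#' @param rna_input_ng Fragmented RNA input mass in ng.
#' @param probe_to_rna_ratio Probe:RNA mass ratio (default 5).
#' @return Probe mass in ng.
#' @export
hybridization_sheet <- function(rna_input_ng, probe_to_rna_ratio = 5) {
  stopifnot(rna_input_ng > 0)
  probe_to_rna_ratio * rna_input_ng
}
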