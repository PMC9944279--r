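#' Parameters of a synthetic infection census
#'
#' Stage-structured population of diatom host cells in five infection
#' stages: non-infected, early-infected, maturely-infected, post-infected,
#' and decaying. Infected means early + mature + post; decaying cells count
#' toward the total but not toward prevalence. Defaults follow the infected
#' treatment: ambient stage mix with 42% prevalence, per-stage mean
#' bacterial loads 6.5 / 9.9 / 9.6 / 16.1 / 24.2 bacteria per cell, and a
#' prevalence fold-enrichment of infected cells inside aggregates of
#' 71/42 (~1.69).
#'
#' @param n_cells cells scored per compartment.
#' @param stage_mix named fractions over
#'   c(non, early, mature, post, decaying), summing to 1; this is the
#'   ambient-water mix.
#' @param bacteria_mean_per_stage named non-negative means of bacteria per
#'   cell for each stage.
#' @param bacteria_dispersion negative-binomial size parameter (smaller =
#'   more overdispersed); default 4, matching the wide observed per-cell
#'   distributions.
#' @param aggregate_enrichment prevalence fold-enrichment of infected
#'   stages within the aggregate compartment relative to ambient water.
#' @param seed integer RNG seed.
#' @return a validated list of class `agg_census_params`.
#' @export
census_params <- function(n_cells = 500,
                          stage_mix = c(non = 0.50, early = 0.08,
                                        mature = 0.15, post = 0.19,
                                        decaying = 0.08),
                          bacteria_mean_per_stage = c(non = 6.5, early = 9.9,
                                                      mature = 9.6,
                                                      post = 16.1,
                                                      decaying = 24.2),
                          bacteria_dispersion = 4,
                          aggregate_enrichment = 71 / 42,
                          seed = 1L) {
  stages <- c("non", "early", "mature", "post", "decaying")
  check_number(n_cells, "n_cells", function(v) v >= 1 && v == round(v),
               "positive integer")
  if (!is.numeric(stage_mix) || !setequal(names(stage_mix), stages) ||
      any(stage_mix < 0)) {
    abort_config("`stage_mix` must be non-negative fractions named ",
                 paste(stages, collapse = ", "))
  }
  stage_mix <- stage_mix[stages]
  if (abs(sum(stage_mix) - 1) > 1e-9) {
    abort_config("`stage_mix` must sum to 1 (got ", sum(stage_mix), ")")
  }
  if (!is.numeric(bacteria_mean_per_stage) ||
      !setequal(names(bacteria_mean_per_stage), stages) ||
      any(bacteria_mean_per_stage < 0)) {
    abort_config("`bacteria_mean_per_stage` must be non-negative means named ",
                 paste(stages, collapse = ", "))
  }
  bacteria_mean_per_stage <- bacteria_mean_per_stage[stages]
  check_number(bacteria_dispersion, "bacteria_dispersion",
               function(v) v > 0, "> 0")
  check_number(aggregate_enrichment, "aggregate_enrichment",
               function(v) v > 0, "> 0")
  check_number(seed, "seed", function(v) v == round(v), "integer")
  structure(list(
    n_cells = as.integer(n_cells), stage_mix = stage_mix,
    bacteria_mean_per_stage = bacteria_mean_per_stage,
    bacteria_dispersion = bacteria_dispersion,
    aggregate_enrichment = aggregate_enrichment, seed = as.integer(seed)
  ), class = "agg_census_params")
}

# Reweight the ambient stage mix so that the aggregate-compartment
# prevalence is enrichment-fold the ambient prevalence. Infected stages
# scale by the enrichment factor; non-infected + decaying absorb the
# complement proportionally.
enrich_stage_mix <- function(stage_mix, enrichment) {
  infected <- c("early", "mature", "post")
  p_amb <- sum(stage_mix[infected])
  p_agg <- enrichment * p_amb
  if (p_agg > 1) {
    abort_config("aggregate_enrichment of ", enrichment,
                 " with ambient prevalence ", signif(p_amb, 3),
                 " would require negative non-infected fractions")
  }
  out <- stage_mix
  out[infected] <- stage_mix[infected] * enrichment
  rest <- setdiff(names(stage_mix), infected)
  p_rest <- sum(stage_mix[rest])
  out[rest] <- if (p_rest > 0) stage_mix[rest] * (1 - p_agg) / p_rest else 0
  out
}

#' Generate paired aggregate/ambient infection censuses
#'
#' Scores `n_cells` host cells per compartment. Stages are drawn from the
#' ambient mix (ambient water) and from the enrichment-reweighted mix
#' (aggregate compartment); each cell carries a bacterial count drawn from
#' a negative-binomial distribution with the stage's mean and the common
#' dispersion parameter.
#'
#' @param params a [census_params()] object.
#' @return tibble with one row per cell: `compartment`
#'   ("aggregate"/"ambient"), `cell_id`, `stage`, `bacteria`.
#' @examples
#' cc <- generate_cell_census(census_params(n_cells = 200))
#' table(cc$compartment, cc$stage)
#' @export
generate_cell_census <- function(params = census_params()) {
  if (!inherits(params, "agg_census_params")) {
    abort_config("`params` must come from census_params()")
  }
  stages <- names(params$stage_mix)
  agg_mix <- enrich_stage_mix(params$stage_mix, params$aggregate_enrichment)
  withr::with_seed(params$seed, {
    draw <- function(compartment, mix) {
      stage <- sample(stages, params$n_cells, replace = TRUE, prob = mix)
      mu <- params$bacteria_mean_per_stage[stage]
      bacteria <- rnbinom(params$n_cells, size = params$bacteria_dispersion,
                          mu = mu)
      tibble(compartment = compartment, cell_id = seq_len(params$n_cells),
             stage = factor(stage, levels = stages), bacteria = bacteria)
    }
    bind_rows(draw("aggregate", agg_mix), draw("ambient", params$stage_mix))
  })
}
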