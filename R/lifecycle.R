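# Within-season demographic processes. Cohorts and pools are plain lists of
# parallel vectors so that every operation stays vectorized; the engine is the
# only writer, these functions are pure (state in, state out) apart from RNG.

#' Aboveground plant cohort
#'
#' A cohort is a list of parallel vectors, one element per live plant:
#' `emg` (emergence date, days after start of season, DASS), `gt` (R-allele
#' count 0/1/2), `lnpz` (Ln of the quantitative tolerance phenotype Pz), and
#' `rhiz` (index of the secondary rhizome the tiller grew from; 0 for
#' seed-origin plants, which cannot regrow).
#'
#' @param emg,lnpz numeric vectors.
#' @param gt integer vector of R-allele counts.
#' @param rhiz integer vector of source-rhizome indices (0 = seedling).
#' @return list of class `jg_cohort`.
#' @export
plant_cohort <- function(emg = numeric(), gt = integer(),
                         lnpz = numeric(), rhiz = integer()) {
  n <- length(emg)
  stopifnot(length(gt) == n, length(lnpz) == n, length(rhiz) == n)
  structure(list(emg = as.numeric(emg), gt = as.integer(gt),
                 lnpz = as.numeric(lnpz), rhiz = as.integer(rhiz)),
            class = "jg_cohort")
}

#' @rdname plant_cohort
#' @param x a cohort.
#' @export
n_plants <- function(x) length(x$emg)

cohort_subset <- function(x, keep) {
  plant_cohort(x$emg[keep], x$gt[keep], x$lnpz[keep], x$rhiz[keep])
}

cohort_bind <- function(a, b) {
  plant_cohort(c(a$emg, b$emg), c(a$gt, b$gt), c(a$lnpz, b$lnpz),
               c(a$rhiz, b$rhiz))
}

#' Propagule pool (seedbank, tertiary/primary rhizomes)
#'
#' Seeds and rhizomes that are not currently scheduled as aboveground
#' individuals carry only their genetics: `gt` and `lnpz` parallel vectors.
#'
#' @param gt integer vector of R-allele counts.
#' @param lnpz numeric vector of Ln(Pz).
#' @return list of class `jg_pool`.
#' @export
propagule_pool <- function(gt = integer(), lnpz = numeric()) {
  stopifnot(length(gt) == length(lnpz))
  structure(list(gt = as.integer(gt), lnpz = as.numeric(lnpz)),
            class = "jg_pool")
}

#' @rdname propagule_pool
#' @param x a pool.
#' @export
pool_size <- function(x) length(x$gt)

# Stochastic rounding: preserves the expected value at low counts where
# plain truncation would bias fecundity downward.
stoch_round <- function(x) {
  f <- floor(x)
  as.integer(f + (stats::runif(length(x)) < x - f))
}

#' Sample emergence dates from the Weibull phenology model
#'
#' Emergence of seedlings and of tillers follows a two-parameter Weibull
#' distribution on days after the start of the season (DASS).
#'
#' @param n number of dates to draw.
#' @param shape,scale Weibull shape k and scale lambda (days); both > 0.
#' @return numeric vector of emergence dates (DASS).
#' @examples
#' mean(sample_emergence_dates(1e4, 10.5, 169))  # ~ 169 * gamma(1 + 1/10.5)
#' @export
sample_emergence_dates <- function(n, shape, scale) {
  stopifnot(n >= 0)
  if (shape <= 0 || scale <= 0) stop("Weibull shape and scale must be positive")
  stats::rweibull(n, shape = shape, scale = scale)
}

#' Germination draw on the seedbank
#'
#' Each seed independently emerges with probability `p_germ` (0.26 by
#' default in the scenarios: the complement is lost to predation and loss of
#' viability, so non-emerging seeds are removed rather than carried over).
#'
#' @param seedbank a [propagule_pool()].
#' @param p_germ germination probability in `[0, 1]`.
#' @return list with `seedlings` (a pool of emerged seeds, genetics copied
#'   from the seed records) and `seedbank` (the depleted bank — empty under
#'   the no-carryover rule).
#' @export
germinate <- function(seedbank, p_germ) {
  if (p_germ < 0 || p_germ > 1) stop("p_germ must lie in [0, 1]")
  n <- pool_size(seedbank)
  up <- stats::runif(n) < p_germ
  list(seedlings = propagule_pool(seedbank$gt[up], seedbank$lnpz[up]),
       seedbank = propagule_pool())
}

#' Pre-plant ("clean field") removal
#'
#' The field is clean at crop sowing: every plant that emerged strictly
#' before the sowing date is killed. Killed tillers leave their rhizome
#' eligible for regrowth (see [regrow_tillers()] with
#' `kill_date = sowing_date`).
#'
#' @param plants a [plant_cohort()].
#' @param sowing_date DASS of crop sowing.
#' @return list with `plants` (retained) and `killed` cohorts.
#' @export
remove_preplant <- function(plants, sowing_date) {
  kill <- plants$emg < sowing_date
  list(plants = cohort_subset(plants, !kill),
       killed = cohort_subset(plants, kill))
}

#' Herbicide specification
#'
#' @param name label, e.g. "glyphosate" or "ACCase".
#' @param resistance_architecture `"quantitative"` (survival decided by
#'   Pz >= dose) or `"single_gene"` (survival decided by genotype under
#'   complete dominance).
#' @param dose application dose in g a.e./ha (used by the quantitative
#'   classification; 1120 for glyphosate).
#' @param foliar_efficacy_early,foliar_efficacy_late kill probability of a
#'   sensitive aboveground plant at the early/late postemergence timing.
#' @param rhizome_efficacy_notill,rhizome_efficacy_till kill probability of
#'   a sensitive rhizome per application without/with tillage.
#' @return list of class `herbicide_spec`.
#' @export
herbicide_spec <- function(name,
                           resistance_architecture = c("quantitative",
                                                       "single_gene"),
                           dose = 1120,
                           foliar_efficacy_early = 0.95,
                           foliar_efficacy_late = 0.90,
                           rhizome_efficacy_notill = 0.25,
                           rhizome_efficacy_till = 0.50) {
  resistance_architecture <- match.arg(resistance_architecture)
  effs <- c(foliar_efficacy_early, foliar_efficacy_late,
            rhizome_efficacy_notill, rhizome_efficacy_till)
  if (any(effs < 0) || any(effs > 1)) stop("efficacies must lie in [0, 1]")
  stopifnot(dose > 0)
  structure(list(name = name,
                 resistance_architecture = resistance_architecture,
                 dose = dose,
                 foliar_efficacy_early = foliar_efficacy_early,
                 foliar_efficacy_late = foliar_efficacy_late,
                 rhizome_efficacy_notill = rhizome_efficacy_notill,
                 rhizome_efficacy_till = rhizome_efficacy_till),
            class = "herbicide_spec")
}

#' Postemergence application event
#'
#' @param date application date (DASS); the early application is 30 days
#'   after sowing.
#' @param timing `"early_post"` (targets plants emerged by the application
#'   date) or `"late_post"` (targets every plant of the season; its reduced
#'   efficacy folds in escapes emerging after the application).
#' @param herbicides list of [herbicide_spec()]s applied together (tank
#'   mix); a plant survives the event only if it survives every component.
#' @return list of class `application_event`.
#' @export
application_event <- function(date, timing = c("early_post", "late_post"),
                              herbicides) {
  timing <- match.arg(timing)
  if (inherits(herbicides, "herbicide_spec")) herbicides <- list(herbicides)
  structure(list(date = date, timing = timing, herbicides = herbicides),
            class = "application_event")
}

# survival probability of each (gt, lnpz) individual against one event;
# resistant individuals survive a component with probability 1, sensitive
# ones with 1 - efficacy, components independent.
.event_survival_prob <- function(gt, lnpz, event, dominance = 1) {
  surv <- rep(1, length(gt))
  early <- event$timing == "early_post"
  for (h in event$herbicides) {
    res <- if (h$resistance_architecture == "single_gene")
      is_resistant(gt, dominance) else lnpz >= log(h$dose)
    eff <- if (early) h$foliar_efficacy_early else h$foliar_efficacy_late
    surv <- surv * (1 - eff * !res)
  }
  surv
}

#' Foliar herbicide application
#'
#' The early postemergence event targets plants emerged on or before the
#' event date; the late event targets all plants of the season. Resistant
#' plants (single-gene: RR/RS; quantitative: Pz >= dose) survive each
#' matching component with probability 1; sensitive plants escape each
#' component with probability 1 - efficacy, independently across components
#' of a mixture.
#'
#' @param plants a [plant_cohort()].
#' @param event an [application_event()].
#' @param dominance dominance of the single-gene resistance allele.
#' @return list with `survivors` and `killed` cohorts.
#' @export
apply_foliar_herbicide <- function(plants, event, dominance = 1) {
  n <- n_plants(plants)
  targeted <- if (event$timing == "early_post")
    plants$emg <= event$date else rep(TRUE, n)
  surv <- rep(1, n)
  surv[targeted] <- .event_survival_prob(plants$gt[targeted],
                                         plants$lnpz[targeted],
                                         event, dominance)
  alive <- stats::runif(n) < surv
  list(survivors = cohort_subset(plants, alive),
       killed = cohort_subset(plants, !alive))
}

#' Secondary rhizome state
#'
#' Parallel vectors over secondary rhizomes: genetics (`gt`, `lnpz`),
#' `nodes` (node crowns, each of which sprouts one apical tiller), `mer`
#' reserve meristems remaining for regrowth (one dormant bud per node
#' crown), and `alive`.
#' @param gt,lnpz genetics vectors.
#' @param nodes integer vector of node crowns.
#' @param mer integer vector of reserve meristems.
#' @param alive logical vector.
#' @return list of class `jg_rhizomes`.
#' @export
rhizome_state <- function(gt = integer(), lnpz = numeric(),
                          nodes = integer(), mer = integer(),
                          alive = logical()) {
  structure(list(gt = as.integer(gt), lnpz = as.numeric(lnpz),
                 nodes = as.integer(nodes), mer = as.integer(mer),
                 alive = as.logical(alive)),
            class = "jg_rhizomes")
}

#' Herbicide action on rhizomes
#'
#' Translocation to the rhizomes is weaker than to shoots: a sensitive
#' rhizome is killed with probability 0.25 per application without tillage
#' and 0.50 with tillage (segmented rhizomes take up more active
#' ingredient). Resistance protects the whole genet, so resistant rhizomes
#' (same classification as plants, per component) are unaffected.
#'
#' @param rhizomes a [rhizome_state()].
#' @param event an [application_event()].
#' @param tillage logical: tillage scenario?
#' @param dominance dominance of the single-gene resistance allele.
#' @return the rhizome state with `alive` updated.
#' @export
apply_rhizome_herbicide <- function(rhizomes, event, tillage,
                                    dominance = 1) {
  idx <- which(rhizomes$alive)
  if (!length(idx)) return(rhizomes)
  surv <- rep(1, length(idx))
  for (h in event$herbicides) {
    res <- if (h$resistance_architecture == "single_gene")
      is_resistant(rhizomes$gt[idx], dominance)
    else rhizomes$lnpz[idx] >= log(h$dose)
    eff <- if (tillage) h$rhizome_efficacy_till else h$rhizome_efficacy_notill
    surv <- surv * (1 - eff * !res)
  }
  dead <- stats::runif(length(idx)) >= surv
  rhizomes$alive[idx[dead]] <- FALSE
  rhizomes
}

#' Tiller regrowth after an apical tiller dies
#'
#' Apical dominance holds a reserve bud dormant at each node crown while
#' its distal tiller is alive; when a tiller is killed, a replacement
#' regrows from the reserve meristem — at most one regrowth per killed
#' tiller and never more than the rhizome's remaining reserves, and only
#' while the rhizome itself is alive. The regrown tiller is a clone of its
#' rhizome and emerges three weeks after the kill date. Resistance-cost
#' carriers pay the survival reduction at regrowth, like any new tiller.
#'
#' @param rhizomes a [rhizome_state()].
#' @param killed cohort of plants killed at `kill_date` (only tiller-origin
#'   members, `rhiz > 0`, can trigger regrowth).
#' @param kill_date DASS of the kill event.
#' @param cost a [fitness_cost()].
#' @return list with `plants` (regrown tillers) and `rhizomes` (reserve
#'   meristems decremented).
#' @export
regrow_tillers <- function(rhizomes, killed, kill_date,
                           cost = fitness_cost("none")) {
  nR <- length(rhizomes$mer)
  kidx <- killed$rhiz[killed$rhiz > 0L]
  n_killed <- tabulate(kidx, nbins = nR)
  n_regrow <- pmin(n_killed, rhizomes$mer) * rhizomes$alive
  rhizomes$mer <- rhizomes$mer - n_regrow
  idx <- rep.int(seq_len(nR), n_regrow)
  gt <- rhizomes$gt[idx]
  p_surv <- apply_fitness_cost(rep(1, length(idx)), cost, gt > 0L, "survival")
  ok <- stats::runif(length(idx)) < p_surv
  list(plants = plant_cohort(rep(kill_date + 21, sum(ok)), gt[ok],
                             rhizomes$lnpz[idx][ok], idx[ok]),
       rhizomes = rhizomes)
}

#' Fecundity parameter set
#'
#' Seed output declines exponentially with emergence date, a proxy for
#' interspecific competition with the crop: `f(x) = a * exp(b * x)`, capped
#' at `max_seeds`.
#'
#' @param a intercept (seeds), > 0.
#' @param b per-day rate (negative in the fitted regions).
#' @param max_seeds field cap on seeds per plant, > 0.
#' @return list of class `fecundity_params`.
#' @export
fecundity_params <- function(a, b, max_seeds) {
  stopifnot(a > 0, max_seeds > 0)
  structure(list(a = a, b = b, max_seeds = max_seeds),
            class = "fecundity_params")
}

#' Seeds produced by a plant given its emergence date
#'
#' @param emergence_date DASS, >= 0 (vectorized).
#' @param params a [fecundity_params()].
#' @param method `"round"` (deterministic, nearest integer) or
#'   `"stochastic"` (expected-value-preserving stochastic rounding, used by
#'   the engine to avoid systematic bias at low fecundity).
#' @return integer vector of seed counts.
#' @examples
#' seeds_per_plant(0, fecundity_params(298660, -0.066, 356))    # cap binds
#' seeds_per_plant(168, fecundity_params(298660, -0.066, 356))  # ~ 5
#' @export
seeds_per_plant <- function(emergence_date, params,
                            method = c("round", "stochastic")) {
  method <- match.arg(method)
  stopifnot(all(emergence_date >= 0))
  f <- pmin(params$a * exp(params$b * emergence_date), params$max_seeds)
  if (method == "round") as.integer(round(f)) else stoch_round(f)
}

#' Sexual reproduction at season end
#'
#' Every adult mothers a fecundity-determined number of seeds (reduced by
#' the fecundity cost for R-allele carriers). Each seed is selfed with
#' probability `selfing_rate`, otherwise outcrossed to a father drawn
#' uniformly from all adults alive at seed set. Genotypes follow Mendelian
#' inheritance ([inherit_nuclear()]); each seed's Ln(Pz) is an independent
#' draw from the offspring normal given by [offspring_pz_params()] applied
#' to the realized adult Ln(Pz) distribution (SD taken as 0 when a single
#' adult remains).
#'
#' @param adults a [plant_cohort()] of plants alive at season end.
#' @param selfing_rate probability a seed is selfed (0.95).
#' @param quant_model a [quant_trait_model()].
#' @param cost a [fitness_cost()].
#' @param fecundity a [fecundity_params()].
#' @return a [propagule_pool()] of new seeds.
#' @export
reproduce_sexually <- function(adults, selfing_rate, quant_model, cost,
                               fecundity) {
  nA <- n_plants(adults)
  if (nA == 0L) return(propagule_pool())
  f <- pmin(fecundity$a * exp(fecundity$b * adults$emg), fecundity$max_seeds)
  f <- apply_fitness_cost(f, cost, adults$gt > 0L, "fecundity")
  nseed <- stoch_round(f)
  N <- sum(nseed)
  if (N == 0L) return(propagule_pool())
  mother <- rep.int(seq_len(nA), nseed)
  selfed <- stats::runif(N) < selfing_rate
  father <- mother
  n_out <- sum(!selfed)
  if (n_out) father[!selfed] <- sample.int(nA, n_out, replace = TRUE)
  gt <- stats::rbinom(N, 1L, adults$gt[mother] / 2) +
    stats::rbinom(N, 1L, adults$gt[father] / 2)
  par_sd <- if (nA >= 2L) stats::sd(adults$lnpz) else 0
  pp <- offspring_pz_params(mean(adults$lnpz), par_sd, quant_model)
  propagule_pool(gt, stats::rnorm(N, pp[["mean"]], pp[["sd"]]))
}

#' Secondary rhizome production at season start
#'
#' Each overwintered primary rhizome spawns Poisson(`mean_branches`)
#' secondary rhizomes (clonal genetics); each secondary bears
#' Poisson(`nodes_mean`) nodes. One node per secondary becomes the apical
#' tiller at sprouting; the rest are held as reserve meristems.
#'
#' @param primaries a [propagule_pool()] of primary rhizomes.
#' @param mean_branches Poisson mean of secondaries per primary (2).
#' @param nodes_mean Poisson mean of nodes per secondary (3).
#' @return a [rhizome_state()] with one reserve meristem per node crown.
#' @export
produce_secondary_rhizomes <- function(primaries, mean_branches, nodes_mean) {
  stopifnot(mean_branches >= 0, nodes_mean >= 0)
  k <- stats::rpois(pool_size(primaries), mean_branches)
  gt <- rep.int(primaries$gt, k)
  lnpz <- rep.int(primaries$lnpz, k)
  n <- length(gt)
  nodes <- stats::rpois(n, nodes_mean)
  rhizome_state(gt, lnpz, nodes, nodes, rep(TRUE, n))
}

#' Sprout tillers from secondary rhizome nodes
#'
#' Every node crown of a live secondary rhizome sprouts one apical tiller
#' (apical dominance acts within a crown: one active distal meristem each),
#' so a rhizome with 3 nodes fields 3 tillers and a primary rhizome fields
#' on average 2 x 3 = 6. Each tiller draws its own Weibull emergence date.
#' One dormant reserve bud per crown remains available for regrowth after a
#' tiller is killed. Carrier tillers pay the survival fitness cost at
#' establishment (a cost death does not trigger regrowth).
#'
#' @param rhizomes a [rhizome_state()] fresh from
#'   [produce_secondary_rhizomes()].
#' @param shape,scale tiller emergence Weibull parameters.
#' @param cost a [fitness_cost()].
#' @return list with `plants` (tiller cohort, `rhiz` pointing at its
#'   rhizome) and `rhizomes`.
#' @export
sprout_tillers <- function(rhizomes, shape, scale,
                           cost = fitness_cost("none")) {
  live <- which(rhizomes$alive)
  idx <- rep.int(live, rhizomes$nodes[live])
  gt <- rhizomes$gt[idx]
  p_surv <- apply_fitness_cost(rep(1, length(idx)), cost, gt > 0L, "survival")
  ok <- stats::runif(length(idx)) < p_surv
  emg <- sample_emergence_dates(sum(ok), shape, scale)
  list(plants = plant_cohort(emg, gt[ok], rhizomes$lnpz[idx][ok], idx[ok]),
       rhizomes = rhizomes)
}

#' Tertiary rhizome production by adults
#'
#' Adults (mature seedlings and tillers alive at season end) clone
#' themselves into Poisson(`rate_per_adult`) tertiary rhizomes each. The
#' per-adult rate is not an observed quantity; it is exposed as a scenario
#' knob (see the vignette for its calibration).
#'
#' @param adults a [plant_cohort()].
#' @param rate_per_adult Poisson mean of tertiary rhizomes per adult.
#' @return a [propagule_pool()] of tertiary rhizomes (clonal genetics).
#' @export
produce_tertiary_rhizomes <- function(adults, rate_per_adult) {
  stopifnot(rate_per_adult >= 0)
  k <- stats::rpois(n_plants(adults), rate_per_adult)
  propagule_pool(rep.int(adults$gt, k), rep.int(adults$lnpz, k))
}

#' Overwintering transition
#'
#' Each tertiary rhizome survives winter with probability
#' `1 - winter_mortality` (independent Bernoulli trials); survivors become
#' next season's primary rhizomes. Aboveground biomass does not survive
#' winter, and primary/secondary rhizomes die or lose physiological
#' activity after reproduction, so the between-season state is the
#' surviving tertiary pool plus the new seedbank.
#'
#' @param tertiaries a [propagule_pool()].
#' @param winter_mortality probability in `[0, 1]`.
#' @return a [propagule_pool()] of next season's primary rhizomes.
#' @export
overwinter <- function(tertiaries, winter_mortality) {
  if (winter_mortality < 0 || winter_mortality > 1)
    stop("winter_mortality must lie in [0, 1]")
  keep <- stats::runif(pool_size(tertiaries)) < 1 - winter_mortality
  propagule_pool(tertiaries$gt[keep], tertiaries$lnpz[keep])
}
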