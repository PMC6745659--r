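# Annual-cycle engine: one season = asexual sprouting + germination,
# pre-plant removal, two postemergence applications with tiller regrowth,
# census, reproduction, overwintering. Replicates iterate seasons until the
# density threshold is exceeded or the horizon/extinction is reached.

#' Initial population state
#'
#' Builds the year-0 state: a seedbank of
#' `initial_seedbank_density * field_area` seeds and
#' `initial_rhizome_density * field_area` primary rhizomes, each propagule
#' with a Hardy-Weinberg genotype at frequency `q` and an Ln(Pz) drawn from
#' the founding log-normal.
#'
#' @param cfg a [scenario_config()].
#' @return list with `seedbank` and `primaries` ([propagule_pool()]s).
#' @export
initial_state <- function(cfg) {
  n_seed <- round(cfg$initial_seedbank_density * cfg$field_area)
  n_rhiz <- round(cfg$initial_rhizome_density * cfg$field_area)
  qt <- cfg$quant_trait
  list(seedbank = propagule_pool(
         sample_initial_genotypes(n_seed, cfg$q),
         log(sample_initial_pz(qt, n_seed))),
       primaries = propagule_pool(
         sample_initial_genotypes(n_rhiz, cfg$q),
         log(sample_initial_pz(qt, n_rhiz))))
}

#' Weed-control failure check
#'
#' Control has failed when the standing live plant density at the
#' post-application census strictly exceeds the threshold (5 plants/m2);
#' the replicate then stops.
#'
#' @param n_plants standing live plants at the census.
#' @param field_area field size (m2).
#' @param threshold failure density (plants/m2).
#' @return logical.
#' @export
check_failure <- function(n_plants, field_area, threshold) {
  n_plants / field_area > threshold
}

#' Seedbank to tertiary-rhizome density ratio
#'
#' Per-season ratio of new seeds entering the seedbank to tertiary rhizomes
#' standing before winter (densities share the field area, so the ratio is
#' a count ratio). Undefined (NA) when no tertiary rhizome was produced;
#' such seasons are excluded from ensemble averages.
#'
#' @param n_seeds new seeds produced this season.
#' @param n_tertiary tertiary rhizomes before winter mortality.
#' @return dimensionless ratio or NA.
#' @export
seedbank_rhizome_ratio <- function(n_seeds, n_tertiary) {
  ifelse(n_tertiary > 0, n_seeds / n_tertiary, NA_real_)
}

# One full season. Returns the next between-season state plus the season's
# observation row. Order of operations: sprouting and germination (emergence
# dates Weibull), pre-plant clean field at sowing (killed tillers may regrow
# at sowing + 21), early POST (foliar + rhizome action, regrowth 21 d
# later), late POST (foliar + rhizome action, no further regrowth),
# census/failure check, then reproduction (seeds + tertiary rhizomes) and
# overwintering.
run_season_internal <- function(state, cfg, program) {
  cost <- cfg$cost
  seedbank_start <- pool_size(state$seedbank)

  ## asexual line: primaries -> secondaries -> apical tillers
  sec <- produce_secondary_rhizomes(state$primaries, cfg$rhizome_branch_mean,
                                    cfg$nodes_mean)
  sp <- sprout_tillers(sec, cfg$emergence_tiller[["shape"]],
                       cfg$emergence_tiller[["scale"]], cost)
  sec <- sp$rhizomes
  plants <- sp$plants

  ## sexual line: germination, emergence dates, establishment cost
  g <- germinate(state$seedbank, cfg$p_germination)
  sdl <- g$seedlings
  n_sdl <- pool_size(sdl)
  if (n_sdl) {
    p_surv <- apply_fitness_cost(rep(1, n_sdl), cost, sdl$gt > 0L, "survival")
    ok <- stats::runif(n_sdl) < p_surv
    emg <- sample_emergence_dates(sum(ok),
                                  cfg$emergence_seedling[["shape"]],
                                  cfg$emergence_seedling[["scale"]])
    plants <- cohort_bind(plants, plant_cohort(
      emg, sdl$gt[ok], sdl$lnpz[ok], integer(sum(ok))))
  }
  if (cfg$emergence_shift != 0)
    plants$emg <- pmax(plants$emg + cfg$emergence_shift, 0)

  ## clean field at sowing; killed tillers regrow
  if (cfg$preplant_removes_tillers) {
    rp <- remove_preplant(plants, cfg$sowing_date)
    plants <- rp$plants
    rg <- regrow_tillers(sec, rp$killed, cfg$sowing_date, cost)
    sec <- rg$rhizomes
    plants <- cohort_bind(plants, rg$plants)
  } else {
    keep <- plants$rhiz > 0L | plants$emg >= cfg$sowing_date
    plants <- cohort_subset(plants, keep)
  }

  ## postemergence program
  for (ev in program) {
    fh <- apply_foliar_herbicide(plants, ev, cfg$dominance)
    plants <- fh$survivors
    sec <- apply_rhizome_herbicide(sec, ev, cfg$tillage, cfg$dominance)
    if (ev$timing == "early_post") {
      rg <- regrow_tillers(sec, fh$killed, ev$date, cost)
      sec <- rg$rhizomes
      plants <- cohort_bind(plants, rg$plants)
    }
  }

  ## census
  n_cen <- n_plants(plants)
  glyph_dose <- cfg$herbicides$glyphosate$dose
  obs <- c(n_plants = n_cen,
           density = n_cen / cfg$field_area,
           frac_sg = if (n_cen) mean(is_resistant(plants$gt, cfg$dominance))
                     else NA_real_,
           frac_qt = if (n_cen) mean(plants$lnpz >= log(glyph_dose))
                     else NA_real_,
           allele_freq = if (n_cen) mean(plants$gt) / 2 else NA_real_,
           median_pz = if (n_cen) exp(stats::median(plants$lnpz))
                       else NA_real_,
           seedbank = seedbank_start,
           seeds_new = NA_real_, n_tertiary = NA_real_)
  failed <- check_failure(n_cen, cfg$field_area, cfg$density_threshold)
  if (failed)
    return(list(state = state, obs = obs, failed = TRUE))

  ## reproduction and between-season transition
  seeds <- reproduce_sexually(plants, cfg$selfing_rate, cfg$quant_trait,
                              cost, cfg$fecundity)
  tert <- produce_tertiary_rhizomes(plants, cfg$tertiary_rate)
  obs[["seeds_new"]] <- pool_size(seeds)
  obs[["n_tertiary"]] <- pool_size(tert)
  list(state = list(seedbank = seeds,
                    primaries = overwinter(tert, cfg$winter_mortality)),
       obs = obs, failed = FALSE)
}

#' Run one season of the annual cycle
#'
#' Executes the within-season process order on a between-season state:
#' rhizome sprouting and seedbank germination, pre-plant removal at sowing,
#' the postemergence program with tiller regrowth three weeks after the
#' early application, the census and failure check, then sexual
#' reproduction, tertiary-rhizome production and overwintering.
#'
#' @param state list with `seedbank` and `primaries` pools (see
#'   [initial_state()]).
#' @param cfg a [scenario_config()].
#' @return list with the next `state`, the season observation vector
#'   `obs`, and `failed`.
#' @export
run_season <- function(state, cfg) {
  validate_scenario_config(cfg)
  run_season_internal(state, cfg, scenario_program(cfg))
}

#' Classify evolved resistance from a replicate trajectory
#'
#' A replicate chronicles evolved resistance to a herbicide when the
#' resistant fraction of standing plants at the census (per that
#' herbicide's classification: RR/RS genotype for the single gene, Pz >=
#' dose for the quantitative trait) exceeds `threshold` in any season with
#' at least one standing plant.
#'
#' @param frac per-season resistant fractions (NA when no plants stood).
#' @param threshold fraction of standing plants (default 0.20).
#' @return list with `resistant` (logical) and `year` (first year, or NA).
#' @export
classify_resistance <- function(frac, threshold = 0.20) {
  hit <- which(!is.na(frac) & frac > threshold)
  list(resistant = length(hit) > 0L,
       year = if (length(hit)) hit[[1L]] else NA_integer_)
}

#' Run a single 30-year replicate
#'
#' Iterates [run_season()] until weed control fails (census density above
#' the threshold), the population goes extinct (empty seedbank and rhizome
#' pools), or the horizon is reached.
#'
#' @param cfg a [scenario_config()].
#' @param seed optional integer seed for this replicate's RNG stream.
#' @return object of class `jg_replicate`: a list with the per-year
#'   trajectory matrix, `failure_year`, per-herbicide resistance
#'   classification, and the seedbank:tertiary ratio accumulators.
#' @export
run_replicate <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  program <- scenario_program(cfg)
  state <- initial_state(cfg)
  traj <- matrix(NA_real_, cfg$n_years, 9L,
                 dimnames = list(NULL, c("n_plants", "density", "frac_sg",
                                         "frac_qt", "allele_freq",
                                         "median_pz", "seedbank",
                                         "seeds_new", "n_tertiary")))
  failure_year <- NA_integer_
  for (yr in seq_len(cfg$n_years)) {
    res <- run_season_internal(state, cfg, program)
    traj[yr, ] <- res$obs
    state <- res$state
    if (res$failed) {
      failure_year <- yr
      break
    }
    if (pool_size(state$seedbank) == 0L && pool_size(state$primaries) == 0L) {
      if (yr < cfg$n_years) {  # extinct: remaining years are empty
        traj[(yr + 1L):cfg$n_years, c("n_plants", "density", "seedbank",
                                      "seeds_new", "n_tertiary")] <- 0
      }
      break
    }
  }
  acc <- classify_resistance(traj[, "frac_sg"], cfg$classify_threshold)
  gly <- classify_resistance(traj[, "frac_qt"], cfg$classify_threshold)
  ratio <- seedbank_rhizome_ratio(traj[, "seeds_new"], traj[, "n_tertiary"])
  structure(list(trajectory = traj,
                 failure_year = failure_year,
                 accase_resistant = acc$resistant,
                 accase_res_year = acc$year,
                 glyph_resistant = gly$resistant,
                 glyph_res_year = gly$year,
                 ratio_sum = sum(ratio, na.rm = TRUE),
                 ratio_n = sum(!is.na(ratio)),
                 seed = seed),
            class = "jg_replicate")
}

#' Run an ensemble of independent replicates
#'
#' Replicates use independent RNG streams spawned from one root seed, so an
#' ensemble is reproduced exactly by (configuration, seed, n). Aggregates
#' the probability of evolved resistance per herbicide architecture, the
#' mean failure year among failing replicates, and the pooled
#' seedbank:tertiary-rhizome density ratio.
#'
#' @param cfg a [scenario_config()].
#' @param n_replicates number of replicates (defaults to
#'   `cfg$n_replicates`).
#' @param seed root integer seed.
#' @param keep_trajectories keep each replicate's yearly trajectory matrix
#'   (memory grows with `n_replicates`; summaries never need it).
#' @param progress print a dot every 100 replicates.
#' @return object of class `jg_ensemble` with elements `replicates` (one
#'   row per replicate), `summary` (list: `accase_r_probability`,
#'   `glyph_r_probability`, `failure_probability`, `mean_failure_year`,
#'   `seedbank_rhizome_ratio`, ...), and the call metadata.
#' @export
run_ensemble <- function(cfg, n_replicates = cfg$n_replicates, seed = 1L,
                         keep_trajectories = FALSE, progress = FALSE) {
  validate_scenario_config(cfg)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  rows <- vector("list", n_replicates)
  trajs <- if (keep_trajectories) vector("list", n_replicates) else NULL
  for (i in seq_len(n_replicates)) {
    r <- run_replicate(cfg, rep_seeds[[i]])
    rows[[i]] <- data.frame(replicate = i, seed = rep_seeds[[i]],
                            failure_year = r$failure_year,
                            accase_resistant = r$accase_resistant,
                            accase_res_year = r$accase_res_year,
                            glyph_resistant = r$glyph_resistant,
                            glyph_res_year = r$glyph_res_year,
                            ratio_sum = r$ratio_sum, ratio_n = r$ratio_n)
    if (keep_trajectories) trajs[[i]] <- r$trajectory
    if (progress && i %% 100L == 0L) cat(".")
  }
  if (progress) cat("\n")
  reps <- do.call(rbind, rows)
  failed <- !is.na(reps$failure_year)
  summary <- list(
    n_replicates = n_replicates,
    accase_r_probability = mean(reps$accase_resistant),
    glyph_r_probability = mean(reps$glyph_resistant),
    failure_probability = mean(failed),
    mean_failure_year = if (any(failed)) mean(reps$failure_year[failed])
                        else NA_real_,
    mean_accase_res_year = if (any(reps$accase_resistant))
      mean(reps$accase_res_year[reps$accase_resistant]) else NA_real_,
    seedbank_rhizome_ratio = if (sum(reps$ratio_n) > 0)
      sum(reps$ratio_sum) / sum(reps$ratio_n) else NA_real_)
  structure(list(replicates = reps, summary = summary,
                 trajectories = trajs,
                 scenario_id = cfg$scenario_id, config = cfg, seed = seed,
                 rng = "base R Mersenne-Twister, per-replicate set.seed"),
            class = "jg_ensemble")
}
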