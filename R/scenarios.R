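# Scenario configuration: regional parameter sets, preset scenarios T1-T9,
# and validation. All simulation inputs flow through this one structure.

REGION_PARAMS <- list(
  South = list(
    sowing_date = 138,                      # 16-Dec
    emergence_seedling = c(shape = 10.5, scale = 169),
    emergence_tiller = c(shape = 6.5, scale = 160),
    fecundity_a = 298660, fecundity_b = -0.066, max_seeds = 356,
    winter_mortality_notill = 0.25, winter_mortality_till = 0.50),
  North = list(
    sowing_date = 142,                      # 20-Dec
    emergence_seedling = c(shape = 4.1, scale = 165),
    emergence_tiller = c(shape = 5.2, scale = 165),
    fecundity_a = 1554053, fecundity_b = -0.066, max_seeds = 1852,
    winter_mortality_notill = 0.10, winter_mortality_till = 0.40))

#' Scenario configuration
#'
#' Assembles the full parameter set of one management scenario. Defaults are
#' the baseline: South region, no tillage, dual glyphosate + ACCase program
#' (tank-mixed at both postemergence timings), resistance-allele frequency
#' 1e-5, founding glyphosate LD50 1719 g a.e./ha, literature fitness cost.
#' Regional values (sowing date, emergence Weibulls, fecundity, winter
#' mortality) are filled from the region unless overridden explicitly.
#'
#' @param region "South" or "North".
#' @param tillage logical; tillage raises rhizome herbicide efficacy and
#'   winter mortality.
#' @param program character vector naming the herbicides applied (subset of
#'   `names(herbicides)`), tank-mixed at both the early and late
#'   postemergence timing.
#' @param herbicides named list of [herbicide_spec()]s.
#' @param q initial resistance-allele frequency of the single gene.
#' @param dominance dominance of the resistance allele (1).
#' @param selfing_rate proportion of selfed seeds (0.95).
#' @param initial_ld50 founding median Pz (g a.e./ha).
#' @param sigma_log founding SD of Ln(Pz) (0.5087).
#' @param mu_ratio,sigma_ratio offspring/parent ratios of mean and SD of
#'   Ln(Pz) (1 and 1.18).
#' @param cost a [fitness_cost()].
#' @param field_area field size in m2 (10,000).
#' @param density_threshold control-failure density (5 plants/m2).
#' @param n_years simulation horizon (30).
#' @param n_replicates default ensemble size (1,000).
#' @param initial_seedbank_density seeds/m2 at year 0 (10).
#' @param initial_rhizome_density rhizomes/m2 at year 0 (1).
#' @param p_germination seedbank germination probability (0.26).
#' @param rhizome_branch_mean Poisson mean secondaries per primary (2).
#' @param nodes_mean Poisson mean nodes per secondary (3).
#' @param tertiary_rate Poisson mean tertiary rhizomes per adult. Not a
#'   field-measured quantity; calibrated once against the baseline ensemble
#'   behaviour (see vignette) and recorded in run manifests.
#' @param classify_threshold resistant fraction of standing plants above
#'   which a replicate chronicles evolved resistance (0.20; a reporting
#'   knob, see vignette).
#' @param preplant_removes_tillers logical: does the pre-plant "clean
#'   field" removal kill tillers emerged before sowing as well as
#'   seedlings? When `FALSE` only seed-origin plants are removed (killed
#'   tillers always leave their rhizome eligible for regrowth).
#' @param sowing_date,emergence_seedling,emergence_tiller,fecundity,winter_mortality
#'   explicit overrides of the region-derived values; `emergence_*` are
#'   `c(shape=, scale=)`, `fecundity` a [fecundity_params()].
#' @param emergence_shift additive shift (days) applied to all sampled
#'   emergence dates (used by the sensitivity driver).
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(region = c("South", "North"),
                            tillage = FALSE,
                            program = c("glyphosate", "ACCase"),
                            herbicides = default_herbicides(),
                            q = 1e-5,
                            dominance = 1,
                            selfing_rate = 0.95,
                            initial_ld50 = 1719,
                            sigma_log = 0.5087,
                            mu_ratio = 1,
                            sigma_ratio = 1.18,
                            cost = fitness_cost("literature"),
                            field_area = 10000,
                            density_threshold = 5,
                            n_years = 30L,
                            n_replicates = 1000L,
                            initial_seedbank_density = 10,
                            initial_rhizome_density = 1,
                            p_germination = 0.26,
                            rhizome_branch_mean = 2,
                            nodes_mean = 3,
                            tertiary_rate = 0.8,
                            classify_threshold = 0.20,
                            preplant_removes_tillers = TRUE,
                            sowing_date = NULL,
                            emergence_seedling = NULL,
                            emergence_tiller = NULL,
                            fecundity = NULL,
                            winter_mortality = NULL,
                            emergence_shift = 0) {
  region <- match.arg(region)
  rp <- REGION_PARAMS[[region]]
  if (is.null(sowing_date)) sowing_date <- rp$sowing_date
  if (is.null(emergence_seedling)) emergence_seedling <- rp$emergence_seedling
  if (is.null(emergence_tiller)) emergence_tiller <- rp$emergence_tiller
  if (is.null(fecundity))
    fecundity <- fecundity_params(rp$fecundity_a, rp$fecundity_b, rp$max_seeds)
  if (is.null(winter_mortality))
    winter_mortality <- if (tillage) rp$winter_mortality_till else
      rp$winter_mortality_notill
  cfg <- structure(list(
    region = region, tillage = tillage, program = program,
    herbicides = herbicides,
    q = q, dominance = dominance, selfing_rate = selfing_rate,
    quant_trait = quant_trait_model(initial_ld50, sigma_log,
                                    mu_ratio, sigma_ratio),
    cost = cost,
    field_area = field_area, density_threshold = density_threshold,
    n_years = as.integer(n_years), n_replicates = as.integer(n_replicates),
    initial_seedbank_density = initial_seedbank_density,
    initial_rhizome_density = initial_rhizome_density,
    p_germination = p_germination,
    rhizome_branch_mean = rhizome_branch_mean, nodes_mean = nodes_mean,
    tertiary_rate = tertiary_rate,
    classify_threshold = classify_threshold,
    preplant_removes_tillers = preplant_removes_tillers,
    sowing_date = sowing_date,
    emergence_seedling = emergence_seedling,
    emergence_tiller = emergence_tiller,
    fecundity = fecundity,
    winter_mortality = winter_mortality,
    emergence_shift = emergence_shift), class = "scenario_config")
  validate_scenario_config(cfg)
}

#' Default herbicide set
#'
#' Glyphosate (quantitative resistance, 1,120 g a.e./ha) and a generic
#' ACCase-inhibiting herbicide (single dominant gene), both with foliar
#' efficacies 95 % (early) / 90 % (late) and rhizome efficacies 25 %
#' (no-till) / 50 % (tillage).
#'
#' @return named list of [herbicide_spec()]s.
#' @export
default_herbicides <- function() {
  list(glyphosate = herbicide_spec("glyphosate", "quantitative", dose = 1120),
       ACCase = herbicide_spec("ACCase", "single_gene", dose = 1120))
}

#' @rdname scenario_config
#' @param cfg a scenario configuration.
#' @export
validate_scenario_config <- function(cfg) {
  probs <- c(q = cfg$q, selfing = cfg$selfing_rate,
             germination = cfg$p_germination,
             winter_mortality = cfg$winter_mortality,
             dominance = cfg$dominance,
             classify_threshold = cfg$classify_threshold)
  bad <- names(probs)[probs < 0 | probs > 1]
  if (length(bad))
    stop("probabilities out of [0, 1]: ", paste(bad, collapse = ", "))
  if (!all(cfg$program %in% names(cfg$herbicides)))
    stop("program names herbicides missing from the herbicide list: ",
         paste(setdiff(cfg$program, names(cfg$herbicides)), collapse = ", "))
  stopifnot(cfg$field_area > 0, cfg$density_threshold > 0,
            cfg$n_years >= 1L, cfg$tertiary_rate >= 0,
            all(cfg$emergence_seedling > 0), all(cfg$emergence_tiller > 0))
  cfg
}

#' Postemergence program of a scenario
#'
#' Two application events: early POST 30 days after sowing and late POST 30
#' days after that, each tank-mixing all herbicides of `cfg$program`.
#'
#' @param cfg a [scenario_config()].
#' @return list of [application_event()]s.
#' @export
scenario_program <- function(cfg) {
  herbs <- cfg$herbicides[cfg$program]
  early <- cfg$sowing_date + 30
  list(application_event(early, "early_post", herbs),
       application_event(early + 30, "late_post", herbs))
}

#' Scenario presets T1-T9
#'
#' Reconstructed management scenarios. T5 is the baseline: South, no-till,
#' dual glyphosate + ACCase program, allele frequency 1e-5, founding LD50
#' 1,719 g a.e./ha, literature fitness cost. The others vary one axis at a
#' time: T1 glyphosate solo from a rare-resistance founding population
#' (LD50 85, i.e. 0.00002 % resistant); T2 ACCase solo with q = 1e-7;
#' T3 the dual program with q = 1e-7; T4 = T3 in the North; T6 = T5 in the
#' North; T7/T8 = T5 with maximal/no fitness cost; T9 = T5 with tillage.
#'
#' @param id one of "T1".."T9".
#' @param ... overrides forwarded to [scenario_config()].
#' @return a [scenario_config()].
#' @examples
#' build_scenario("T5")$q
#' @export
build_scenario <- function(id, ...) {
  presets <- list(
    T1 = list(program = "glyphosate", initial_ld50 = 85),
    T2 = list(program = "ACCase", q = 1e-7),
    T3 = list(q = 1e-7),
    T4 = list(q = 1e-7, region = "North"),
    T5 = list(),
    T6 = list(region = "North"),
    T7 = list(cost = fitness_cost("max")),
    T8 = list(cost = fitness_cost("none")),
    T9 = list(tillage = TRUE))
  if (!is.character(id) || length(id) != 1L || !id %in% names(presets))
    stop("unknown scenario id '", id, "'; available presets: ",
         paste(names(presets), collapse = ", "))
  args <- utils::modifyList(presets[[id]], list(...))
  cfg <- do.call(scenario_config, args)
  cfg$scenario_id <- id
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario configuration",
      if (!is.null(x$scenario_id)) paste0("(", x$scenario_id, ")"), "\n")
  cat("  region:", x$region, "  tillage:", x$tillage, "\n")
  cat("  program:", paste(x$program, collapse = " + "),
      "at DASS", x$sowing_date + 30, "and", x$sowing_date + 60, "\n")
  cat("  single gene: q =", format(x$q), " dominance =", x$dominance, "\n")
  cat("  quantitative: LD50 =", x$quant_trait$initial_ld50,
      "g a.e./ha, sigma_log =", x$quant_trait$sigma_log, "\n")
  cat("  fitness cost:", x$cost$preset,
      sprintf("(survival -%d%%, fecundity -%d%%)",
              round(100 * x$cost$survival_reduction),
              round(100 * x$cost$fecundity_reduction)), "\n")
  cat("  field:", x$field_area, "m2, failure above", x$density_threshold,
      "plants/m2,", x$n_years, "years\n")
  invisible(x)
}
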