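# Configuration files, result writers, run manifests, and synthetic-fixture
# generators. Configs are hierarchical YAML mirroring scenario_config();
# results are headed CSV plus a JSON summary so every artifact round-trips
# through plain text.

#' Serialize and restore scenario configurations
#'
#' `write_scenario_config()` writes a YAML file mirroring the
#' [scenario_config()] fields; `read_scenario_config()` rebuilds the
#' configuration (region-derived values present in the file override the
#' region defaults).
#'
#' @param cfg a [scenario_config()].
#' @param path file path.
#' @return `read_scenario_config()` returns a [scenario_config()];
#'   `write_scenario_config()` returns `path` invisibly.
#' @export
write_scenario_config <- function(cfg, path) {
  out <- list(
    scenario_id = cfg$scenario_id,
    region = cfg$region, tillage = cfg$tillage,
    program = as.list(cfg$program),
    herbicides = lapply(cfg$herbicides, function(h) unclass(h)),
    single_gene = list(q = cfg$q, dominance = cfg$dominance,
                       selfing_rate = cfg$selfing_rate),
    quant_trait = unclass(cfg$quant_trait),
    fitness_cost = unclass(cfg$cost),
    simulation = list(field_area = cfg$field_area,
                      density_threshold = cfg$density_threshold,
                      n_years = cfg$n_years,
                      n_replicates = cfg$n_replicates,
                      classify_threshold = cfg$classify_threshold),
    ecology = list(initial_seedbank_density = cfg$initial_seedbank_density,
                   initial_rhizome_density = cfg$initial_rhizome_density,
                   p_germination = cfg$p_germination,
                   rhizome_branch_mean = cfg$rhizome_branch_mean,
                   nodes_mean = cfg$nodes_mean,
                   tertiary_rate = cfg$tertiary_rate,
                   winter_mortality = cfg$winter_mortality,
                   sowing_date = cfg$sowing_date,
                   emergence_seedling = as.list(cfg$emergence_seedling),
                   emergence_tiller = as.list(cfg$emergence_tiller),
                   emergence_shift = cfg$emergence_shift,
                   fecundity = unclass(cfg$fecundity)))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  herbs <- lapply(y$herbicides, function(h) do.call(herbicide_spec, h))
  cost <- if (identical(y$fitness_cost$preset, "custom"))
    fitness_cost("custom", y$fitness_cost$survival_reduction,
                 y$fitness_cost$fecundity_reduction)
  else fitness_cost(y$fitness_cost$preset)
  cfg <- scenario_config(
    region = y$region, tillage = y$tillage,
    program = unlist(y$program), herbicides = herbs,
    q = y$single_gene$q, dominance = y$single_gene$dominance,
    selfing_rate = y$single_gene$selfing_rate,
    initial_ld50 = y$quant_trait$initial_ld50,
    sigma_log = y$quant_trait$sigma_log,
    mu_ratio = y$quant_trait$mu_ratio,
    sigma_ratio = y$quant_trait$sigma_ratio,
    cost = cost,
    field_area = y$simulation$field_area,
    density_threshold = y$simulation$density_threshold,
    n_years = y$simulation$n_years,
    n_replicates = y$simulation$n_replicates,
    classify_threshold = y$simulation$classify_threshold,
    initial_seedbank_density = y$ecology$initial_seedbank_density,
    initial_rhizome_density = y$ecology$initial_rhizome_density,
    p_germination = y$ecology$p_germination,
    rhizome_branch_mean = y$ecology$rhizome_branch_mean,
    nodes_mean = y$ecology$nodes_mean,
    tertiary_rate = y$ecology$tertiary_rate,
    winter_mortality = y$ecology$winter_mortality,
    sowing_date = y$ecology$sowing_date,
    emergence_seedling = unlist(y$ecology$emergence_seedling),
    emergence_tiller = unlist(y$ecology$emergence_tiller),
    emergence_shift = y$ecology$emergence_shift,
    fecundity = do.call(fecundity_params, y$ecology$fecundity))
  cfg$scenario_id <- y$scenario_id
  cfg
}

#' Apply `key=value` overrides to a configuration
#'
#' Keys name top-level [scenario_config()] fields or dotted paths into
#' nested components (e.g. `"winter_mortality=0.5"`,
#' `"fecundity.a=300000"`, `"quant_trait.initial_ld50=85"`). Values are
#' coerced to the type of the field they replace.
#'
#' @param cfg a [scenario_config()].
#' @param overrides character vector of `key=value` strings.
#' @return the modified, re-validated configuration.
#' @export
apply_overrides <- function(cfg, overrides) {
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("override must be key=value: '", ov, "'")
    path <- strsplit(kv[[1L]], ".", fixed = TRUE)[[1L]]
    cur <- cfg[[path]]
    if (is.null(cur)) stop("unknown configuration key '", kv[[1L]], "'")
    val <- if (is.logical(cur)) as.logical(kv[[2L]])
    else if (is.numeric(cur)) as.numeric(kv[[2L]])
    else kv[[2L]]
    if (is.na(val)) stop("cannot parse value for key '", kv[[1L]], "'")
    cfg[[path]] <- if (is.integer(cur)) as.integer(val) else val
  }
  validate_scenario_config(cfg)
}

#' Run manifest
#'
#' Snapshot written before a simulation starts: package version, timestamp,
#' root seed, RNG scheme, the full configuration (including the calibrated
#' `tertiary_rate` and `classify_threshold` knobs), and any overrides —
#' enough to reproduce the run exactly.
#'
#' @param cfg a [scenario_config()].
#' @param seed root seed of the run.
#' @param overrides character vector of applied overrides.
#' @param outputs named list/character of output paths.
#' @return manifest list (invisibly written by [write_manifest()]).
#' @export
run_manifest <- function(cfg, seed, overrides = character(),
                         outputs = character()) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_scenario_config(cfg, tmp)
  list(package = "jgrass",
       version = as.character(utils::packageVersion("jgrass")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = seed,
       rng = "base R Mersenne-Twister; per-replicate streams via set.seed on seeds drawn from the root seed",
       calibrated_knobs = list(tertiary_rate = cfg$tertiary_rate,
                               classify_threshold = cfg$classify_threshold),
       overrides = as.list(overrides),
       config = yaml::read_yaml(tmp),
       outputs = as.list(outputs))
}

#' @rdname run_manifest
#' @param manifest a manifest list.
#' @param path output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Write ensemble results to a directory
#'
#' Writes `replicates.csv` (one row per replicate), `summary.json`, and —
#' when trajectories were kept — `trajectories.csv` with one row per
#' (replicate, year) carrying raw counts alongside per-m2 densities.
#'
#' @param ens a `jg_ensemble`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_ensemble_results <- function(ens, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(replicates = file.path(dir, "replicates.csv"),
             summary = file.path(dir, "summary.json"))
  utils::write.csv(ens$replicates, paths[["replicates"]], row.names = FALSE)
  jsonlite::write_json(ens$summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(ens$trajectories)) {
    area <- ens$config$field_area
    tr <- do.call(rbind, lapply(seq_along(ens$trajectories), function(i) {
      m <- ens$trajectories[[i]]
      data.frame(replicate = i, year = seq_len(nrow(m)), m,
                 seedbank_per_m2 = m[, "seedbank"] / area,
                 tertiary_per_m2 = m[, "n_tertiary"] / area)
    }))
    paths[["trajectories"]] <- file.path(dir, "trajectories.csv")
    utils::write.csv(tr, paths[["trajectories"]], row.names = FALSE)
  }
  invisible(paths)
}

#' Synthetic emergence fixture
#'
#' Simulates a quadrat emergence survey: `n` plants with Weibull emergence
#' dates, counted per interval at the evaluation dates (counts are interval
#' tallies, as recorded in the field; plants emerging after the last
#' evaluation go uncounted). The true parameters are attached as
#' attributes.
#'
#' @param shape,scale true Weibull parameters.
#' @param n number of emerging plants.
#' @param dates evaluation dates (DASS); defaults follow a five-visit
#'   summer survey.
#' @param cohort,site labels for the output columns.
#' @return data.frame (date, count, cohort, site) with attributes `shape`,
#'   `scale`, `n`.
#' @export
generate_emergence_data <- function(shape, scale, n = 500,
                                    dates = c(159, 181, 203, 227, 255),
                                    cohort = "seedling", site = "synthetic") {
  emg <- sample_emergence_dates(n, shape, scale)
  counts <- diff(c(0, vapply(dates, function(d) sum(emg <= d), 0)))
  structure(data.frame(date = dates, count = as.integer(counts),
                       cohort = cohort, site = site),
            shape = shape, scale = scale, n = n)
}

#' Synthetic fecundity fixture
#'
#' Counts (panicles or seeds per plant) generated from the exponential
#' decline `a * exp(b * x)` with multiplicative log-normal noise.
#'
#' @param a,b true regression parameters.
#' @param x emergence dates.
#' @param noise_sd SD of the log-scale noise (0 = exact curve points).
#' @return data.frame (date, count) with attributes `a`, `b`, `noise_sd`.
#' @export
generate_fecundity_data <- function(a, b, x = seq(20, 180, by = 20),
                                    noise_sd = 0) {
  stopifnot(a > 0, noise_sd >= 0)
  y <- a * exp(b * x) * exp(stats::rnorm(length(x), 0, noise_sd))
  structure(data.frame(date = x, count = y), a = a, b = b,
            noise_sd = noise_sd)
}
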