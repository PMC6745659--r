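#' jgrass: individual-based simulation of herbicide-resistance evolution in a
#' seed- and rhizome-propagated perennial weed
#'
#' An annual-cycle, individual-based model of Johnsongrass (*Sorghum
#' halepense*) in soybean cropping systems. Plants arise sexually from a soil
#' seedbank and asexually from a three-tier rhizome system; postemergence
#' herbicides select either on a single dominant nuclear resistance gene
#' (ACCase-inhibiting herbicides) or on a quantitative log-normal tolerance
#' phenotype Pz (glyphosate). Ensembles of replicates yield the probability of
#' evolved resistance and the year weed control fails (density above 5
#' plants/m2).
#'
#' Start with [build_scenario()] and [run_ensemble()]; see the package
#' vignette for the model description.
#'
#' @keywords internal
"_PACKAGE"

# Genotypes at the single resistance locus are coded as the number of
# resistance (R) alleles an individual carries: 0 = SS, 1 = RS, 2 = RR.
GT_LEVELS <- c("SS", "RS", "RR")

#' Genotype codes and labels
#'
#' The single-gene module codes genotypes as integer R-allele counts
#' (0 = SS, 1 = RS, 2 = RR). These helpers convert between codes and labels.
#'
#' @param gt integer vector of R-allele counts in 0:2.
#' @param label character vector of labels among "SS", "RS", "RR".
#' @return `genotype_label()` returns a character vector; `genotype_code()`
#'   an integer vector.
#' @examples
#' genotype_label(c(0L, 1L, 2L))
#' genotype_code(c("RR", "SS"))
#' @export
genotype_label <- function(gt) {
  stopifnot(all(gt %in% 0:2))
  GT_LEVELS[gt + 1L]
}

#' @rdname genotype_label
#' @export
genotype_code <- function(label) {
  i <- match(label, GT_LEVELS)
  if (anyNA(i)) stop("unknown genotype label; use SS, RS or RR")
  i - 1L
}

#' Hardy-Weinberg genotype probabilities
#'
#' Initial genotype frequencies at the resistance locus for a resistance
#' allele at frequency `q`, assuming Hardy-Weinberg proportions. For rare
#' alleles the resistant fraction (RR + RS) is approximately `2q`, which is
#' how the model's initial allele frequencies map onto initial resistant
#' fractions (1e-5 -> 0.002 %; 1e-7 -> 0.00002 %).
#'
#' @param q resistance-allele frequency in `[0, 1]`.
#' @return named numeric vector `c(RR=, RS=, SS=)` summing to 1.
#' @examples
#' initial_genotype_probs(1e-5)
#' sum(initial_genotype_probs(0.5)[c("RR", "RS")])
#' @export
initial_genotype_probs <- function(q) {
  stopifnot(length(q) == 1L, is.finite(q))
  if (q < 0 || q > 1) stop("allele frequency q must lie in [0, 1]")
  c(RR = q^2, RS = 2 * q * (1 - q), SS = (1 - q)^2)
}

#' Draw genotypes under Hardy-Weinberg proportions
#'
#' @param n number of individuals.
#' @param q resistance-allele frequency.
#' @return integer vector of R-allele counts (0/1/2) of length `n`.
#' @export
sample_initial_genotypes <- function(n, q) {
  p <- initial_genotype_probs(q)
  counts <- stats::rmultinom(1L, n, prob = p[c("SS", "RS", "RR")])[, 1L]
  rep.int(0:2, counts)
}

#' Mendelian inheritance at the single resistance locus
#'
#' Each seed receives one allele drawn at random from the mother's pair and
#' one from the father's pair; selfing is signalled by `father = NULL`, in
#' which case both alleles are independent draws from the mother (so an RS
#' plant selfed segregates 1:2:1). Clonal (rhizome) propagation bypasses this
#' entirely: clones copy the parental genotype.
#'
#' @param mother integer vector of maternal R-allele counts (0/1/2).
#' @param father integer vector of paternal counts, recycled against
#'   `mother`, or `NULL` for selfing.
#' @return integer vector of offspring R-allele counts.
#' @export
inherit_nuclear <- function(mother, father = NULL) {
  n <- length(mother)
  if (is.null(father)) father <- mother
  stopifnot(all(mother %in% 0:2), all(father %in% 0:2))
  father <- rep_len(father, n)
  stats::rbinom(n, 1L, mother / 2) + stats::rbinom(n, 1L, father / 2)
}

#' Phenotypic resistance from genotype
#'
#' Under complete dominance (the model's setting, dominance = 1) both RR and
#' RS plants survive the herbicide while SS plants are controlled at the
#' stated efficacy. Partial dominance is not modelled: any `dominance < 1`
#' leaves only RR resistant.
#'
#' @param gt integer vector of R-allele counts (0/1/2).
#' @param dominance dominance of the resistance allele in `[0, 1]`.
#' @return logical vector: is the plant phenotypically resistant?
#' @examples
#' is_resistant(c(0L, 1L, 2L), dominance = 1)
#' @export
is_resistant <- function(gt, dominance = 1) {
  stopifnot(length(dominance) == 1L, dominance >= 0, dominance <= 1)
  if (dominance >= 1) gt >= 1L else gt == 2L
}

#' Quantitative-trait model for herbicide tolerance
#'
#' The quantitative resistance phenotype Pz (the highest dose an individual
#' survives, g a.e./ha) is log-normal: Ln(Pz) ~ Normal(ln LD50, sigma_log).
#' Offspring Ln(Pz) is drawn from a normal whose mean and SD are the realized
#' parental mean and SD multiplied by `mu_ratio` and `sigma_ratio`; the
#' default ratios (1, 1.18) come from a-priori crosses of the 20-locus
#' infinitesimal sub-model (see [infinitesimal_cross_sim()]).
#'
#' @param initial_ld50 median Pz of the founding population (g a.e./ha).
#' @param sigma_log SD of Ln(Pz), dimensionless (default 0.5087).
#' @param mu_ratio offspring/parent ratio of mean Ln(Pz).
#' @param sigma_ratio offspring/parent ratio of SD of Ln(Pz).
#' @return list of class `quant_trait_model`.
#' @export
quant_trait_model <- function(initial_ld50, sigma_log = 0.5087,
                              mu_ratio = 1, sigma_ratio = 1.18) {
  stopifnot(initial_ld50 > 0, sigma_log >= 0, mu_ratio > 0, sigma_ratio > 0)
  structure(list(initial_ld50 = initial_ld50, sigma_log = sigma_log,
                 mu_ratio = mu_ratio, sigma_ratio = sigma_ratio),
            class = "quant_trait_model")
}

#' Sample founding quantitative phenotypes
#'
#' @param model a [quant_trait_model()].
#' @param n number of individuals.
#' @return numeric vector of Pz values (g a.e./ha).
#' @export
sample_initial_pz <- function(model, n) {
  stopifnot(n >= 0)
  exp(stats::rnorm(n, log(model$initial_ld50), model$sigma_log))
}

#' Analytic resistant fraction of a log-normal tolerance distribution
#'
#' Upper-tail probability P(Pz >= dose) for Ln(Pz) ~ N(ln ld50, sigma_log).
#' This is the closed-form oracle for [sample_initial_pz()] and reproduces
#' the model's founding equivalences: LD50 1719 at dose 1120 gives ~0.80,
#' LD50 139 gives ~2.05e-5, LD50 85 gives ~2e-7.
#'
#' @param ld50 median of Pz (g a.e./ha), > 0.
#' @param sigma_log SD of Ln(Pz), >= 0.
#' @param dose herbicide dose (g a.e./ha), > 0.
#' @return probability that an individual's Pz meets or exceeds the dose.
#' @examples
#' resistant_fraction_analytic(1719, 0.5087, 1120)
#' @export
resistant_fraction_analytic <- function(ld50, sigma_log, dose) {
  if (any(ld50 <= 0) || any(dose <= 0)) stop("ld50 and dose must be positive")
  if (any(sigma_log < 0)) stop("sigma_log must be non-negative")
  ifelse(sigma_log == 0, as.numeric(ld50 >= dose),
         stats::pnorm(log(ld50 / dose) / sigma_log))
}

#' Offspring Ln(Pz) distribution parameters
#'
#' Applies the offspring/parent ratios of the quantitative model to the
#' realized parental mean and SD of Ln(Pz). Each new seed draws its Ln(Pz)
#' independently from Normal(mean', sd').
#'
#' @param parent_mean realized mean of parental Ln(Pz).
#' @param parent_sd realized SD of parental Ln(Pz), >= 0.
#' @param model a [quant_trait_model()].
#' @return named numeric vector `c(mean=, sd=)`.
#' @export
offspring_pz_params <- function(parent_mean, parent_sd, model) {
  stopifnot(parent_sd >= 0)
  c(mean = parent_mean * model$mu_ratio, sd = parent_sd * model$sigma_ratio)
}

#' A-priori infinitesimal-model cross simulation
#'
#' Separate individual-based sub-model used to derive the offspring/parent
#' ratios of mean and SD of Ln(Pz) under the weed's mixed mating system.
#' Each parent carries `n_loci` unlinked additive diploid loci; allelic
#' values are i.i.d. normal with SD chosen so the summed Ln(Pz) variance in
#' the founding generation equals `sigma_log^2`, centred so the founding
#' median Pz is `base_ld50`. Each parent mothers one offspring, selfed with
#' probability `selfing_rate` and otherwise outcrossed to a random father;
#' at each locus the seed receives one allele drawn from each parent's pair
#' (no recombination structure beyond independent assortment, no mutation,
#' no dominance).
#'
#' Partial selfing converts within-plant allelic heterozygosity into
#' between-seed variance, so the SD ratio exceeds 1 (about 1.21 at a selfing
#' rate of 0.95, sqrt(1.5) ~ 1.22 under complete selfing) while additivity
#' keeps the mean ratio at 1.
#'
#' @param n_loci number of additive diploid loci (default 20).
#' @param sigma_log founding SD of Ln(Pz).
#' @param population_size number of parents (>= 2).
#' @param selfing_rate probability a seed is selfed.
#' @param base_ld50 founding median Pz (g a.e./ha); only anchors the mean.
#' @return list with `mu_ratio` and `sigma_ratio` (offspring/parent ratios
#'   of mean and SD of Ln(Pz)) plus the parental and offspring moments.
#' @export
infinitesimal_cross_sim <- function(n_loci = 20L, sigma_log = 0.5087,
                                    population_size = 10000L,
                                    selfing_rate = 0.95,
                                    base_ld50 = 1719) {
  stopifnot(n_loci >= 1L, selfing_rate >= 0, selfing_rate <= 1)
  if (population_size < 2L) stop("population_size must be at least 2")
  n <- as.integer(population_size)
  sd_allele <- sigma_log / sqrt(2 * n_loci)
  # allele matrices: one column pair per locus
  a1 <- matrix(stats::rnorm(n * n_loci, 0, sd_allele), n, n_loci)
  a2 <- matrix(stats::rnorm(n * n_loci, 0, sd_allele), n, n_loci)
  parent_ln <- log(base_ld50) + rowSums(a1) + rowSums(a2)

  mother <- seq_len(n)
  selfed <- stats::runif(n) < selfing_rate
  father <- mother
  father[!selfed] <- sample.int(n, sum(!selfed), replace = TRUE)
  pick <- function(i) {  # one allele per locus from parent rows i
    from1 <- matrix(stats::runif(n * n_loci) < 0.5, n, n_loci)
    ifelse(from1, a1[i, , drop = FALSE], a2[i, , drop = FALSE])
  }
  off_ln <- log(base_ld50) + rowSums(pick(mother)) + rowSums(pick(father))

  list(mu_ratio = mean(off_ln) / mean(parent_ln),
       sigma_ratio = stats::sd(off_ln) / stats::sd(parent_ln),
       parent_mean = mean(parent_ln), parent_sd = stats::sd(parent_ln),
       offspring_mean = mean(off_ln), offspring_sd = stats::sd(off_ln))
}

#' Fitness-cost presets for resistance-allele carriers
#'
#' Carrying the target-site resistance allele can reduce survival of
#' seedlings/tillers and seed production of mature plants. The `literature`
#' preset (42 % survival, 36 % fecundity reduction) follows measurements on
#' an ACCase target-site mutant in black-grass; `max` is an extreme 90/90
#' assumption and `none` removes the cost. Costs apply equally to RR and RS
#' carriers, mirroring the complete dominance of resistance itself.
#'
#' @param preset one of "literature", "max", "none", or "custom".
#' @param survival_reduction,fecundity_reduction fractions in `[0, 1]`,
#'   required when `preset = "custom"`.
#' @return list of class `fitness_cost`.
#' @examples
#' fitness_cost("literature")
#' @export
fitness_cost <- function(preset = c("literature", "max", "none", "custom"),
                         survival_reduction = NULL, fecundity_reduction = NULL) {
  preset <- match.arg(preset)
  v <- switch(preset,
              literature = c(0.42, 0.36),
              max = c(0.90, 0.90),
              none = c(0, 0),
              custom = c(survival_reduction, fecundity_reduction))
  if (length(v) != 2L || any(v < 0) || any(v > 1))
    stop("survival and fecundity reductions must be fractions in [0, 1]")
  structure(list(preset = preset, survival_reduction = v[[1L]],
                 fecundity_reduction = v[[2L]]),
            class = "fitness_cost")
}

#' Apply a fitness cost to a demographic rate
#'
#' @param base_rate baseline survival probability or seed count (>= 0).
#' @param cost a [fitness_cost()].
#' @param carrier logical vector: does the individual carry an R allele?
#' @param which `"survival"` or `"fecundity"`.
#' @return adjusted rate: `base * (1 - reduction)` for carriers, unchanged
#'   otherwise.
#' @examples
#' apply_fitness_cost(1, fitness_cost("literature"), TRUE, "survival")
#' @export
apply_fitness_cost <- function(base_rate, cost, carrier,
                               which = c("survival", "fecundity")) {
  which <- match.arg(which)
  stopifnot(all(base_rate >= 0))
  red <- if (which == "survival") cost$survival_reduction else
    cost$fecundity_reduction
  base_rate * (1 - red * as.numeric(carrier))
}
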