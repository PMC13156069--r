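## Seeded synthetic generators with planted ground truth for every input
## the pipeline consumes. The generators carry the statistical structure
## the method assumes -- variant main effects, substrate main effects,
## variant x substrate interactions, feature loadings, cohort burden
## effects -- not physical chemistry.

# small pool of real drug structures for substrate columns, so the chemistry
# path (ligand descriptors) is exercisable on simulated tables
.SIM_SUBSTRATES <- c(
  metformin = "CN(C)C(=N)NC(=N)N",
  morphine = "CN1CC[C@]23c4c5ccc(O)c4O[C@H]2[C@@H](O)C=C[C@H]3[C@H]1C5",
  sumatriptan = "CNS(=O)(=O)Cc1ccc2[nH]cc(CCN(C)C)c2c1",
  tetraethylammonium = "CC[N+](CC)(CC)CC",
  tyramine = "NCCc1ccc(O)cc1",
  thiamine = "Cc1ncc(C[n+]2csc(CCO)c2C)c(N)n1",
  debrisoquine = "NC(=N)N1CCc2ccccc2C1",
  tropisetron = "CN1C2CCC1CC(C2)OC(=O)c1c[nH]c2ccccc12",
  cycloguanil = "CC1(C)N=C(N)N=C(N)N1c1ccc(Cl)cc1",
  pirenzepine = "CN1CCN(CC(=O)N2c3ccccc3C(=O)Nc3ccccn32)CC1")

.sim_variant_labels <- function(n) {
  # deterministic variant labels (uses the caller's seeded RNG)
  refs <- sample(.AA1, n, replace = TRUE)
  pos <- sample(20:480, n, replace = FALSE)
  alts <- vapply(refs, function(r) sample(setdiff(.AA1, r), 1), character(1))
  sprintf("p.%s%d%s", refs, pos, alts)
}

#' Simulate a variant-substrate activity table with planted effects
#'
#' Log10 activity (uptake ratio vs wildtype) is generated as
#' `variant effect + substrate effect + variant x substrate interaction +
#' noise` and exported as percent of wildtype through the standard
#' aggregation path. The default scales are chosen so that the three-bin
#' activity scheme is populated at roughly 20% decreased / 70% neutral /
#' 10% increased, mimicking curated uptake panels.
#'
#' @param n_genes number of genes (variants are split evenly).
#' @param n_variants total number of variants.
#' @param n_substrates number of substrates (drawn from a pool of real drug
#'   structures, recycled with suffixes beyond 10).
#' @param interaction_sd SD of the planted variant x substrate interaction
#'   (log10 units); 0 removes substrate specificity entirely.
#' @param noise_sd measurement noise SD (log10 units).
#' @param variant_effect_sd,variant_effect_mean distribution of variant
#'   main effects (log10 units).
#' @param substrate_effect_sd SD of substrate main effects (log10 units).
#' @param seed integer seed; regeneration with the same seed is
#'   bit-identical.
#' @return List with `table` (aggregated `ssep_activity`) and `truth`
#'   (a `simulation_truth`: per-variant/substrate effects, interaction
#'   matrix, `pairs` in table row order, seed).
#' @export
simulate_activity <- function(n_genes = 1, n_variants = 40, n_substrates = 8,
                              interaction_sd = 0.18, noise_sd = 0.08,
                              variant_effect_sd = 0.2,
                              variant_effect_mean = -0.08,
                              substrate_effect_sd = 0.08, seed = 1) {
  stopifnot(n_genes >= 1, n_variants >= 1, n_substrates >= 1,
            interaction_sd >= 0, noise_sd >= 0)
  with_seed(child_seed(seed, 101), {
    genes <- sprintf("GENE%02d", seq_len(n_genes))
    vlab <- .sim_variant_labels(n_variants)
    vgene <- genes[((seq_len(n_variants) - 1L) %% n_genes) + 1L]
    base <- names(.SIM_SUBSTRATES)
    subs <- if (n_substrates <= length(base)) base[seq_len(n_substrates)]
            else c(base, sprintf("%s_%d", base[((seq_len(n_substrates - length(base)) - 1L) %% length(base)) + 1L],
                                 seq_len(n_substrates - length(base))))
    smis <- .SIM_SUBSTRATES[sub("_\\d+$", "", subs)]
    ve <- stats::rnorm(n_variants, variant_effect_mean, variant_effect_sd)
    se <- stats::rnorm(n_substrates, 0, substrate_effect_sd)
    names(ve) <- vlab; names(se) <- subs
    inter <- matrix(stats::rnorm(n_variants * n_substrates, 0, interaction_sd),
                    n_variants, n_substrates, dimnames = list(vlab, subs))
    pairs <- expand.grid(vi = seq_len(n_variants), si = seq_len(n_substrates),
                         KEEP.OUT.ATTRS = FALSE)
    log_act <- ve[pairs$vi] + se[pairs$si] +
      inter[cbind(pairs$vi, pairs$si)] +
      stats::rnorm(nrow(pairs), 0, noise_sd)
    records <- data.frame(
      gene = vgene[pairs$vi], variant = vlab[pairs$vi],
      substrate = subs[pairs$si], smiles = unname(smis[pairs$si]),
      uptake_pct_wt = 100 * 10^log_act, source = "simulated")
    table <- aggregate_measurements(records)
    key <- paste(table$variant, table$substrate, sep = "\r")
    truth <- structure(list(
      variant_effects = ve, substrate_effects = se, interaction = inter,
      noise_sd = noise_sd, interaction_sd = interaction_sd,
      genes = stats::setNames(vgene, vlab),
      pairs = data.frame(variant = table$variant, substrate = table$substrate,
                         log_activity = (ve[table$variant] + se[table$substrate] +
                                           inter[cbind(table$variant, table$substrate)]),
                         stringsAsFactors = FALSE),
      seed = seed), class = "simulation_truth")
    list(table = table, truth = truth)
  })
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("<simulation_truth> %d variants x %d substrates, interaction_sd=%.2f, noise_sd=%.2f, seed=%d\n",
              length(x$variant_effects), length(x$substrate_effects),
              x$interaction_sd, x$noise_sd, x$seed))
  invisible(x)
}

#' Simulate feature bundles with planted loadings on the latent effects
#'
#' Block values are linear loadings on the planted latent effects plus
#' noise: embedding, mutation and in-silico blocks load only on the variant
#' main effect; the ligand block loads only on the substrate main effect;
#' the interaction block loads on the variant x substrate interaction.
#' Substrate specificity is therefore learnable only through blocks that
#' see the substrate, which is what the ablation contrasts exploit.
#'
#' @param truth a `simulation_truth` from [simulate_activity()].
#' @param embedding_dim embedding block width (default 16).
#' @param signal_fraction multiplier on all loadings; 0 gives pure-noise
#'   features.
#' @param feature_noise_sd per-coordinate feature noise SD (default 0.05).
#' @param seed integer seed.
#' @return List of [feature_bundle()] objects aligned with
#'   `truth$pairs` rows (one structure-complete bundle per pair).
#' @export
simulate_features <- function(truth, embedding_dim = 16, signal_fraction = 1,
                              feature_noise_sd = 0.05, seed = truth$seed) {
  stopifnot(inherits(truth, "simulation_truth"))
  dims <- c(embedding = as.integer(embedding_dim), insilico = 3L,
            mutation = 4L, ligand = 5L, interaction = 4L)
  with_seed(child_seed(seed, 202), {
    load <- lapply(dims, function(d) signal_fraction * stats::rnorm(d))
    pairs <- truth$pairs
    ve <- truth$variant_effects[pairs$variant]
    se <- truth$substrate_effects[pairs$substrate]
    ii <- truth$interaction[cbind(pairs$variant, pairs$substrate)]
    latent <- list(embedding = ve, insilico = ve, mutation = ve,
                   ligand = se, interaction = ii)
    lapply(seq_len(nrow(pairs)), function(i) {
      blocks <- lapply(names(dims), function(b)
        load[[b]] * latent[[b]][i] +
          stats::rnorm(dims[[b]], 0, feature_noise_sd))
      names(blocks) <- names(dims)
      feature_bundle(pairs$variant[i], pairs$substrate[i], blocks,
                     structure_id = "sim1")
    })
  })
}

#' Simulate a deep-mutational-scanning score table
#'
#' Dense per-variant scores for a single reporter substrate:
#' `variant effect + interaction(variant, reporter) + noise`.
#'
#' @param truth a `simulation_truth`.
#' @param reporter_substrate substrate name present in the truth.
#' @param coverage fraction of variants covered (default 1).
#' @param dms_noise_sd assay noise SD (default 0.05).
#' @param seed integer seed.
#' @return data.frame `variant`, `score`.
#' @export
simulate_dms <- function(truth, reporter_substrate, coverage = 1,
                         dms_noise_sd = 0.05, seed = truth$seed) {
  stopifnot(inherits(truth, "simulation_truth"),
            reporter_substrate %in% names(truth$substrate_effects))
  with_seed(child_seed(seed, 303), {
    vlab <- names(truth$variant_effects)
    keep <- sort(sample.int(length(vlab), max(1L, round(coverage * length(vlab)))))
    data.frame(
      variant = vlab[keep],
      score = truth$variant_effects[keep] +
        truth$interaction[keep, reporter_substrate] +
        stats::rnorm(length(keep), 0, dms_noise_sd),
      row.names = NULL)
  })
}

#' Simulate a cohort with a planted dose-burden association
#'
#' Genotypes follow Hardy-Weinberg proportions at the given minor allele
#' frequencies; daily dose is
#' `intercept + beta * burden + covariate terms + noise` with the burden
#' computed from the supplied per-variant weights. The defaults mirror a
#' metformin-style maintenance-dose design: intercept 1500 mg/day, residual
#' SD 300 mg/day, planted beta 30 mg/day per unit burden.
#'
#' @param n_subjects cohort size.
#' @param mafs named vector of minor allele frequencies in `(0, 0.5)`.
#' @param weights named per-variant weights used to generate the dose
#'   (default: standard-normal scores scaled to the SSEP range).
#' @param beta planted effect, mg/day per unit burden (default 30).
#' @param intercept baseline dose (mg/day).
#' @param covariate_effects list with `age`, `sex_m`, `bmi`, `ethnic`
#'   coefficients.
#' @param noise_sd residual dose SD (default 300 mg/day).
#' @param seed integer seed.
#' @return List with `genotypes` (subjects x variants dosage matrix),
#'   `subjects` (data.frame `id`, `daily_dose`, `age_at_prescription`,
#'   `sex`, `ethnic_group`, `bmi`), `weights`, `beta`.
#' @export
simulate_cohort <- function(n_subjects = 5000,
                            mafs = stats::setNames(
                              seq(0.002, 0.04, length.out = 11),
                              sprintf("rv%02d", 1:11)),
                            weights = NULL, beta = 30, intercept = 1500,
                            covariate_effects = list(age = 2, sex_m = 50,
                                                     bmi = 5,
                                                     ethnic = c(0, -20, 15)),
                            noise_sd = 300, seed = 1) {
  stopifnot(n_subjects >= 1, all(mafs > 0), all(mafs <= 0.5))
  with_seed(child_seed(seed, 404), {
    m <- length(mafs)
    G <- vapply(mafs, function(f) stats::rbinom(n_subjects, 2L, f),
                numeric(n_subjects))
    if (n_subjects == 1L) G <- matrix(G, 1, m, dimnames = list(NULL, names(mafs)))
    colnames(G) <- names(mafs)
    if (is.null(weights))
      weights <- stats::setNames(stats::rnorm(m, -0.25, 0.4), names(mafs))
    burden <- burden_score(G, weights)
    age <- stats::rnorm(n_subjects, 60, 10)
    sex <- ifelse(stats::runif(n_subjects) < 0.5, "F", "M")
    bmi <- stats::rnorm(n_subjects, 28, 4)
    eth <- sample(c("group1", "group2", "group3"), n_subjects,
                  replace = TRUE, prob = c(0.8, 0.1, 0.1))
    eth_eff <- covariate_effects$ethnic[match(eth, c("group1", "group2", "group3"))]
    dose <- intercept + beta * burden +
      covariate_effects$age * (age - 60) +
      covariate_effects$sex_m * (sex == "M") +
      covariate_effects$bmi * (bmi - 28) + eth_eff +
      stats::rnorm(n_subjects, 0, noise_sd)
    list(genotypes = G,
         subjects = data.frame(
           id = sprintf("S%06d", seq_len(n_subjects)),
           daily_dose = pmax(dose, 1),
           age_at_prescription = age, sex = sex,
           ethnic_group = eth, bmi = bmi, stringsAsFactors = FALSE),
         weights = weights, beta = beta)
  })
}
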