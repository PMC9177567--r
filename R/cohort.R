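#' Simulate a cohort with planted, SV-confounded associations
#'
#' Generates the four cohort matrices the association cascade consumes:
#' sample x species relative abundance, sample x (species, KO) SV genotype
#' (0/1, NA where the species is absent), sample x metabolite concentrations
#' with missing-completely-at-random dropout, and a phenotype with age/sex/BMI
#' covariates. For each planted triple (species, KO, metabolite) the
#' metabolite tracks the species' abundance only in samples whose strain is
#' SV-free at that KO (genotype 0, Spearman ~= `effect_size`); in
#' SV-carrying samples (genotype 1) the dependence is absent. The phenotype
#' (glucose-like) is a noisy negative linear function of the latent signals
#' of the first one or two planted metabolites, sized so the bacteria to
#' phenotype rank correlation lands near -0.3 to -0.4.
#'
#' @param n_samples samples (>= 40 so the 20% subgroup filter can pass).
#' @param n_species species columns.
#' @param n_metabolites metabolite columns.
#' @param n_kos_per_species SV (KO) columns per species (default 1, one
#'   dissectable SV-affected gene per species).
#' @param confounded_triples number of planted (species, KO, metabolite)
#'   triples; must not exceed min(n_species, n_metabolites).
#' @param effect_size target Spearman correlation in the SV0 subgroup
#'   (magnitude < 1).
#' @param seed integer seed.
#' @param species_presence probability a species occurs in a sample.
#' @param sv1_prob probability a present strain carries the SV (genotype 1).
#' @param metabolite_missingness MCAR missingness rate for metabolites.
#' @param phenotype_effect magnitude of each wired metabolite's (negative)
#'   weight in the phenotype.
#' @param phenotype_noise_sd standard deviation of the phenotype noise.
#' @return a `cohort_bundle`: list(abundance, sv_genotype, metabolites
#'   (matrices with sample rownames), phenotype (named numeric), covariates
#'   (data.frame age/sex/bmi), truth (data.frame species, ko, metabolite,
#'   effect), params).
#' @export
simulate_cohort <- function(n_samples = 100L, n_species = 6L,
                            n_metabolites = 10L, n_kos_per_species = 1L,
                            confounded_triples = 3L, effect_size = 0.7,
                            seed = 1L, species_presence = 0.9,
                            sv1_prob = 0.4, metabolite_missingness = 0.05,
                            phenotype_effect = 1, phenotype_noise_sd = 0.6) {
  if (n_samples < 40L) stop("n_samples must be >= 40")
  if (confounded_triples > min(n_species, n_metabolites))
    stop("confounded_triples exceeds available (species, metabolite) pairs")
  if (abs(effect_size) >= 1) stop("effect_size must have magnitude < 1")
  with_seed(seed, {
    samples <- sprintf("S%03d", seq_len(n_samples))
    species <- sprintf("sp%02d", seq_len(n_species))
    mets <- sprintf("met%02d", seq_len(n_metabolites))

    present <- matrix(stats::rbinom(n_samples * n_species, 1L,
                                    species_presence) == 1L,
                      n_samples, n_species,
                      dimnames = list(samples, species))
    abundance <- matrix(0, n_samples, n_species,
                        dimnames = list(samples, species))
    abundance[present] <- stats::rlnorm(sum(present), log(0.01), 1)

    sv_cols <- as.vector(t(outer(species, seq_len(n_kos_per_species),
                                 function(s, k) paste0(s, "|K",
                                                       sprintf("%05d", match(s, species) * 100L + k)))))
    sv_genotype <- matrix(NA_real_, n_samples, length(sv_cols),
                          dimnames = list(samples, sv_cols))
    for (j in seq_along(sv_cols)) {
      sp <- sub("\\|.*$", "", sv_cols[j])
      idx <- present[, sp]
      sv_genotype[idx, j] <- stats::rbinom(sum(idx), 1L, sv1_prob)
    }

    # latent (gaussianised-rank) abundance signal per species, present samples
    latent_ab <- matrix(NA_real_, n_samples, n_species,
                        dimnames = list(samples, species))
    for (s in species) {
      idx <- present[, s]
      latent_ab[idx, s] <- stats::qnorm(rank(abundance[idx, s]) /
                                          (sum(idx) + 1))
    }

    truth <- data.frame(
      species = species[seq_len(confounded_triples)],
      ko = vapply(seq_len(confounded_triples), function(i)
        sub("^.*\\|", "", sv_cols[(i - 1L) * n_kos_per_species + 1L]),
        character(1)),
      metabolite = mets[seq_len(confounded_triples)],
      effect = effect_size, stringsAsFactors = FALSE)

    b <- effect_size / sqrt(1 - effect_size^2)
    latent_met <- matrix(stats::rnorm(n_samples * n_metabolites),
                         n_samples, n_metabolites,
                         dimnames = list(samples, mets))
    if (effect_size != 0) {
      for (i in seq_len(nrow(truth))) {
        sp <- truth$species[i]
        svcol <- paste0(sp, "|", truth$ko[i])
        sv0 <- !is.na(sv_genotype[, svcol]) & sv_genotype[, svcol] == 0
        latent_met[sv0, truth$metabolite[i]] <-
          b * latent_ab[sv0, sp] + stats::rnorm(sum(sv0))
      }
    }
    metabolites <- exp(latent_met)  # non-negative concentrations
    drop <- matrix(stats::runif(length(metabolites)) < metabolite_missingness,
                   nrow(metabolites), ncol(metabolites))
    metabolites[drop] <- NA_real_

    wired <- truth$metabolite[seq_len(min(2L, nrow(truth)))]
    phen_lat <- latent_met[, wired, drop = FALSE]
    phenotype <- drop(phen_lat %*% rep(-phenotype_effect, ncol(phen_lat))) +
      stats::rnorm(n_samples, 0, phenotype_noise_sd)
    names(phenotype) <- samples

    covariates <- data.frame(
      age = round(stats::rnorm(n_samples, 45, 12)),
      sex = stats::rbinom(n_samples, 1L, 0.5),
      bmi = round(stats::rnorm(n_samples, 23, 3), 1),
      row.names = samples)

    structure(list(abundance = abundance, sv_genotype = sv_genotype,
                   metabolites = metabolites, phenotype = phenotype,
                   covariates = covariates, truth = truth,
                   params = list(n_samples = n_samples,
                                 species_presence = species_presence,
                                 sv1_prob = sv1_prob,
                                 effect_size = effect_size,
                                 metabolite_missingness = metabolite_missingness)),
              class = "cohort_bundle")
  })
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf(paste0("cohort_bundle: %d samples, %d species, %d SV columns, ",
                     "%d metabolites, %d planted triple(s)\n"),
              nrow(x$abundance), ncol(x$abundance), ncol(x$sv_genotype),
              ncol(x$metabolites), nrow(x$truth)))
  invisible(x)
}
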