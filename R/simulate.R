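#' Configuration for the synthetic methylation cohort
#'
#' Defaults mirror the structure of a two-arm infant-blood methylation trial:
#' 179 control and 190 treated samples, each gene carrying a small set of
#' promoter and body probes. Signal is generated on the logit scale so that
#' inverse-logit mapping keeps beta values strictly inside (0, 1).
#'
#' @param n_genes number of genes.
#' @param probes_per_region integer range `c(min, max)` (each >= 2) for the
#'   number of probes drawn per gene and region.
#' @param n_control,n_treated samples per group (each >= 2).
#' @param effect_genes number of genes carrying a treatment effect.
#' @param effect_size logit-scale shift added to body probes of treated
#'   samples in effect genes.
#' @param noise_sd logit-scale SD of per-probe, per-sample noise.
#' @param seed RNG seed; simulation is a pure function of this config.
#' @return validated config list of class `methyl_sim_config`.
#' @export
methyl_sim_config <- function(n_genes = 500,
                              probes_per_region = c(2, 4),
                              n_control = 179, n_treated = 190,
                              effect_genes = 0, effect_size = 0,
                              noise_sd = 0.5, seed = 1) {
  check_scalar(n_genes, "n_genes", lower = 1, integerish = TRUE)
  if (length(probes_per_region) != 2 ||
      any(probes_per_region < 2) ||
      probes_per_region[1] > probes_per_region[2])
    stop("'probes_per_region' must be c(min, max) with min >= 2", call. = FALSE)
  check_scalar(n_control, "n_control", lower = 2, integerish = TRUE)
  check_scalar(n_treated, "n_treated", lower = 2, integerish = TRUE)
  check_scalar(effect_genes, "effect_genes", lower = 0, upper = n_genes,
               integerish = TRUE)
  check_scalar(effect_size, "effect_size")
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(seed, "seed", integerish = TRUE)
  structure(list(n_genes = as.integer(n_genes),
                 probes_per_region = as.integer(probes_per_region),
                 n_control = as.integer(n_control),
                 n_treated = as.integer(n_treated),
                 effect_genes = as.integer(effect_genes),
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "methyl_sim_config")
}

#' Simulate a two-group methylation cohort with known ground truth
#'
#' Per gene, promoter and body baseline methylation levels are drawn on the
#' logit scale (promoters hypomethylated around logit -1.5, bodies methylated
#' around logit 1.0), each probe gets its own offset, and each probe x sample
#' cell gets Gaussian noise of SD `noise_sd`. For the `effect_genes` randomly
#' chosen effect genes, `effect_size` is added to the body-probe logits of
#' treated samples only, so the SIMPO body-minus-promoter contrast shifts in
#' the treated group. Values are mapped to (0, 1) by the inverse logit.
#'
#' @param cfg a [methyl_sim_config()].
#' @return list with `beta` (probes x samples matrix), `annotation`
#'   (`probe_id`, `gene`, `region`), `groups` (`sample_id`, `group`), and
#'   `truth` (`effect_genes`, `effect_size`).
#' @export
simulate_methylation_cohort <- function(cfg) {
  if (!inherits(cfg, "methyl_sim_config"))
    stop("cfg must come from methyl_sim_config()", call. = FALSE)
  with_seed(cfg$seed, {
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))
    m <- sample(cfg$probes_per_region[1]:cfg$probes_per_region[2],
                cfg$n_genes, replace = TRUE)
    n <- sample(cfg$probes_per_region[1]:cfg$probes_per_region[2],
                cfg$n_genes, replace = TRUE)
    annotation <- data.frame(
      probe_id = sprintf("cg%07d", seq_len(sum(m) + sum(n))),
      gene = c(rep(genes, m), rep(genes, n)),
      region = rep(c("body", "promoter"), c(sum(m), sum(n))),
      stringsAsFactors = FALSE)
    # per-gene baselines and per-probe offsets, all on the logit scale
    mu_body <- stats::rnorm(cfg$n_genes, 1.0, 0.5)
    mu_prom <- stats::rnorm(cfg$n_genes, -1.5, 0.5)
    base <- c(rep(mu_body, m), rep(mu_prom, n)) +
      stats::rnorm(nrow(annotation), 0, 0.3)
    samples <- c(sprintf("C%03d", seq_len(cfg$n_control)),
                 sprintf("T%03d", seq_len(cfg$n_treated)))
    grp <- rep(c("control", "treated"), c(cfg$n_control, cfg$n_treated))
    P <- nrow(annotation); S <- length(samples)
    logit <- matrix(base, P, S) +
      matrix(stats::rnorm(P * S, 0, cfg$noise_sd), P, S)
    effect_ids <- if (cfg$effect_genes > 0)
      sort(sample(genes, cfg$effect_genes)) else character(0)
    if (length(effect_ids) && cfg$effect_size != 0) {
      rows <- annotation$region == "body" & annotation$gene %in% effect_ids
      logit[rows, grp == "treated"] <-
        logit[rows, grp == "treated"] + cfg$effect_size
    }
    beta <- stats::plogis(logit)
    dimnames(beta) <- list(annotation$probe_id, samples)
    list(beta = beta,
         annotation = annotation,
         groups = data.frame(sample_id = samples, group = grp,
                             stringsAsFactors = FALSE),
         truth = list(effect_genes = effect_ids,
                      effect_size = cfg$effect_size))
  })
}

#' Configuration for synthetic GWAS summary statistics
#'
#' Governs one exposure/outcome pair. Exposure effects (instrument
#' strengths) are drawn from `N(instrument_strength[1],
#' instrument_strength[2])`; outcome effects are `theta * gamma + alpha + e`
#' where `alpha` is a pleiotropy draw applied to a fraction
#' `frac_pleiotropic` of instruments and `e` has the outcome standard error.
#' Standard errors follow the usual GWAS form
#' `se = 1 / sqrt(2 n maf (1 - maf))` for a unit-variance trait.
#'
#' @param n_snps number of SNPs.
#' @param instrument_strength `c(mean, sd)` of the exposure effects.
#' @param n_exposure,n_outcome effective sample sizes governing the SEs.
#' @param theta true causal effect of exposure on outcome.
#' @param pleiotropy_mean,pleiotropy_sd direct (pleiotropic) SNP-outcome
#'   effect distribution; mean != 0 gives directional pleiotropy. Draws are
#'   independent of instrument strength (the InSIDE assumption) unless
#'   `inside = FALSE`, in which case pleiotropy is made proportional to
#'   instrument strength plus noise, breaking InSIDE.
#' @param frac_pleiotropic fraction of instruments receiving a pleiotropy
#'   draw (the rest are valid instruments with `alpha = 0`).
#' @param maf_range `c(min, max)` minor-allele frequency range in (0, 0.5].
#' @param frac_palindromic expected fraction of A/T or C/G SNPs.
#' @param inside keep the InSIDE assumption (default TRUE).
#' @param seed RNG seed.
#' @return validated config list of class `gwas_sim_config`.
#' @export
gwas_sim_config <- function(n_snps = 50,
                            instrument_strength = c(0.3, 0.1),
                            n_exposure = 100000, n_outcome = 100000,
                            theta = 0,
                            pleiotropy_mean = 0, pleiotropy_sd = 0,
                            frac_pleiotropic = 1,
                            maf_range = c(0.1, 0.5),
                            frac_palindromic = 0.1,
                            inside = TRUE, seed = 1) {
  check_scalar(n_snps, "n_snps", lower = 1, integerish = TRUE)
  if (length(instrument_strength) != 2 || instrument_strength[2] < 0)
    stop("'instrument_strength' must be c(mean, sd >= 0)", call. = FALSE)
  check_scalar(n_exposure, "n_exposure", lower = 10)
  check_scalar(n_outcome, "n_outcome", lower = 10)
  check_scalar(theta, "theta")
  check_scalar(pleiotropy_mean, "pleiotropy_mean")
  check_scalar(pleiotropy_sd, "pleiotropy_sd", lower = 0)
  check_scalar(frac_pleiotropic, "frac_pleiotropic", lower = 0, upper = 1)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("'maf_range' must be c(min, max) within (0, 0.5]", call. = FALSE)
  check_scalar(frac_palindromic, "frac_palindromic", lower = 0, upper = 1)
  check_scalar(seed, "seed", integerish = TRUE)
  structure(list(n_snps = as.integer(n_snps),
                 instrument_strength = as.numeric(instrument_strength),
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 theta = theta, pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 frac_pleiotropic = frac_pleiotropic,
                 maf_range = as.numeric(maf_range),
                 frac_palindromic = frac_palindromic,
                 inside = isTRUE(inside), seed = as.integer(seed)),
            class = "gwas_sim_config")
}

NONPALINDROMIC_PAIRS <- rbind(c("A", "G"), c("A", "C"),
                              c("T", "G"), c("T", "C"),
                              c("G", "A"), c("C", "A"),
                              c("G", "T"), c("C", "T"))
PALINDROMIC_PAIRS <- rbind(c("A", "T"), c("T", "A"),
                           c("C", "G"), c("G", "C"))

#' Simulate an exposure/outcome GWAS summary-statistic pair
#'
#' Generates per-SNP summary statistics for a two-sample MR design with
#' known causal effect and pleiotropy. Exposure and outcome estimates are
#' drawn from independent samples (`beta_exp = gamma + e_x`,
#' `beta_out = theta * gamma + alpha + e_y`). Half of the outcome records
#' (in expectation) are stored with swapped effect/other alleles so that
#' harmonization is exercised; p-values satisfy
#' `p = 2 pnorm(-|beta / se|)` exactly.
#'
#' @param cfg a [gwas_sim_config()].
#' @param snp_prefix prefix for generated rsIDs.
#' @param traits length-2 character, trait labels for exposure and outcome.
#' @return list with `exposure`, `outcome` (GWAS data.frames with columns
#'   `snp`, `effect_allele`, `other_allele`, `beta`, `se`, `pval`, `eaf`,
#'   `trait`) and `truth` (`gamma`, `alpha`, `theta`, `valid`).
#' @export
simulate_gwas_pair <- function(cfg, snp_prefix = "rs",
                               traits = c("exposure", "outcome")) {
  if (!inherits(cfg, "gwas_sim_config"))
    stop("cfg must come from gwas_sim_config()", call. = FALSE)
  with_seed(cfg$seed, {
    J <- cfg$n_snps
    snp <- sprintf("%s%06d", snp_prefix, seq_len(J))
    maf <- stats::runif(J, cfg$maf_range[1], cfg$maf_range[2])
    se_exp <- 1 / sqrt(2 * cfg$n_exposure * maf * (1 - maf))
    se_out <- 1 / sqrt(2 * cfg$n_outcome * maf * (1 - maf))
    gamma <- stats::rnorm(J, cfg$instrument_strength[1],
                          cfg$instrument_strength[2])
    pleio <- stats::runif(J) < cfg$frac_pleiotropic
    alpha <- numeric(J)
    if (cfg$pleiotropy_mean != 0 || cfg$pleiotropy_sd > 0) {
      draw <- if (cfg$inside)
        stats::rnorm(J, cfg$pleiotropy_mean, cfg$pleiotropy_sd)
      else  # break InSIDE: pleiotropy tracks instrument strength
        cfg$pleiotropy_mean * gamma / max(abs(cfg$instrument_strength[1]),
                                          1e-8) +
          stats::rnorm(J, 0, cfg$pleiotropy_sd)
      alpha[pleio] <- draw[pleio]
    }
    beta_exp <- gamma + stats::rnorm(J, 0, se_exp)
    beta_out <- cfg$theta * gamma + alpha + stats::rnorm(J, 0, se_out)
    pal <- stats::runif(J) < cfg$frac_palindromic
    idx_pal <- sample(nrow(PALINDROMIC_PAIRS), J, replace = TRUE)
    idx_non <- sample(nrow(NONPALINDROMIC_PAIRS), J, replace = TRUE)
    ea <- ifelse(pal, PALINDROMIC_PAIRS[idx_pal, 1],
                 NONPALINDROMIC_PAIRS[idx_non, 1])
    oa <- ifelse(pal, PALINDROMIC_PAIRS[idx_pal, 2],
                 NONPALINDROMIC_PAIRS[idx_non, 2])
    eaf <- ifelse(stats::runif(J) < 0.5, maf, 1 - maf)
    exposure <- data.frame(snp = snp, effect_allele = ea, other_allele = oa,
                           beta = beta_exp, se = se_exp,
                           pval = 2 * stats::pnorm(-abs(beta_exp / se_exp)),
                           eaf = eaf, trait = traits[1],
                           stringsAsFactors = FALSE)
    # store ~half of the outcome rows on the opposite allele orientation
    swap <- stats::runif(J) < 0.5
    outcome <- data.frame(snp = snp,
                          effect_allele = ifelse(swap, oa, ea),
                          other_allele = ifelse(swap, ea, oa),
                          beta = ifelse(swap, -beta_out, beta_out),
                          se = se_out,
                          pval = 2 * stats::pnorm(-abs(beta_out / se_out)),
                          eaf = ifelse(swap, 1 - eaf, eaf),
                          trait = traits[2],
                          stringsAsFactors = FALSE)
    list(exposure = exposure, outcome = outcome,
         truth = list(gamma = gamma, alpha = alpha, theta = cfg$theta,
                      valid = alpha == 0, maf = maf))
  })
}

#' Simulate a linked exposure/mediator/outcome GWAS triplet
#'
#' Builds the summary-statistic inputs for a two-step mediation MR: one pair
#' for exposure -> mediator (causal effect `cfg1$theta`) and one for
#' mediator -> outcome (`cfg2$theta`). The mediator table contains both its
#' association records with the step-1 instruments and its own instruments
#' for step 2; the outcome table carries `shared_snps` of the step-2
#' instrument rsIDs (with `shared_snps = 0`, step 2 has no shared
#' instruments and [run_two_step()] fails in harmonization).
#'
#' @param cfg1,cfg2 [gwas_sim_config()]s for step 1 and step 2.
#' @param shared_snps number of step-2 SNPs present in the outcome table
#'   (default: all of them).
#' @return list with `exposure`, `mediator`, `outcome` tables and `truth`
#'   (`theta1`, `theta2`, `mediated_effect` and the per-step pair truths).
#' @export
simulate_gwas_triplet <- function(cfg1, cfg2, shared_snps = cfg2$n_snps) {
  if (!inherits(cfg1, "gwas_sim_config") ||
      !inherits(cfg2, "gwas_sim_config"))
    stop("cfg1 and cfg2 must come from gwas_sim_config()", call. = FALSE)
  check_scalar(shared_snps, "shared_snps", lower = 0, upper = cfg2$n_snps,
               integerish = TRUE)
  step1 <- simulate_gwas_pair(cfg1, snp_prefix = "rs1",
                              traits = c("exposure", "mediator"))
  step2 <- simulate_gwas_pair(cfg2, snp_prefix = "rs2",
                              traits = c("mediator", "outcome"))
  mediator <- rbind(step1$outcome, step2$exposure)
  mediator$trait <- "mediator"
  outcome <- step2$outcome[seq_len(shared_snps), , drop = FALSE]
  list(exposure = step1$exposure, mediator = mediator, outcome = outcome,
       truth = list(theta1 = cfg1$theta, theta2 = cfg2$theta,
                    mediated_effect = cfg1$theta * cfg2$theta,
                    step1 = step1$truth, step2 = step2$truth))
}
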