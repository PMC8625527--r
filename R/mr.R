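#' Select genome-wide significant instruments
#'
#' Keeps GWAS records whose p-value is strictly below the instrument
#' threshold (genome-wide significance, `5e-8`, by default). Order is
#' preserved. A warning is raised when no record survives.
#'
#' @param gwas data.frame of GWAS summary statistics with at least columns
#'   `snp`, `beta`, `se`, `pval`.
#' @param threshold strict upper bound on the instrument p-value.
#' @return the filtered data.frame.
#' @export
select_instruments <- function(gwas, threshold = 5e-8) {
  validate_gwas(gwas)
  check_scalar(threshold, "threshold", lower = 0, upper = 1)
  keep <- gwas$pval < threshold
  if (!any(keep))
    warning("no instrument passes p < ", format(threshold), call. = FALSE)
  gwas[keep, , drop = FALSE]
}

validate_gwas <- function(gwas, what = "GWAS table") {
  need_cols(gwas, c("snp", "effect_allele", "other_allele", "beta", "se",
                    "pval"), what)
  if (any(gwas$se <= 0)) stop(what, ": se must be > 0", call. = FALSE)
  if (any(gwas$effect_allele == gwas$other_allele))
    stop(what, ": effect and other allele must differ", call. = FALSE)
  dup <- unique(gwas$snp[duplicated(gwas$snp)])
  if (length(dup))
    stop(what, ": duplicate rsID(s): ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  invisible(gwas)
}

ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) ALLELE_COMPLEMENT[a1] == a2

#' Harmonize exposure and outcome summary statistics
#'
#' Inner-joins the two tables on rsID and aligns the outcome effect to the
#' exposure's effect allele. Outcome records whose alleles are swapped
#' relative to the exposure (directly or after strand complement) have their
#' beta sign flipped and EAF complemented. Palindromic SNPs (A/T or C/G) are
#' oriented by comparing effect-allele frequencies: both EAFs must fall
#' outside `0.5 +/- palindromic_eaf_window`, otherwise the SNP is excluded as
#' ambiguous. Allele sets that match neither directly nor swapped, with or
#' without strand complement, are excluded as mismatches.
#'
#' @param exposure,outcome GWAS data.frames (columns `snp`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval`, optionally `eaf`).
#' @param palindromic_eaf_window half-width of the EAF ambiguity zone around
#'   0.5 (default 0.08).
#' @return data.frame of harmonized pairs with columns `snp`, `beta_exp`,
#'   `se_exp`, `beta_out`, `se_out`, `eaf_exp`, `eaf_out`, `flipped`,
#'   `palindromic`, carrying the excluded records (with reason codes) in
#'   attribute `"excluded"`.
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_window = 0.08) {
  validate_gwas(exposure, "exposure table")
  validate_gwas(outcome, "outcome table")
  check_scalar(palindromic_eaf_window, "palindromic_eaf_window",
               lower = 0, upper = 0.5)
  shared <- intersect(exposure$snp, outcome$snp)
  if (!length(shared))
    stop("no shared instruments between exposure and outcome tables",
         call. = FALSE)
  e <- exposure[match(shared, exposure$snp), , drop = FALSE]
  o <- outcome[match(shared, outcome$snp), , drop = FALSE]
  if (is.null(e$eaf)) e$eaf <- NA_real_
  if (is.null(o$eaf)) o$eaf <- NA_real_

  n <- length(shared)
  keep <- logical(n); flipped <- logical(n); pal <- logical(n)
  reason <- character(n)
  beta_out <- o$beta; eaf_out <- o$eaf
  w <- palindromic_eaf_window
  for (i in seq_len(n)) {
    ea_e <- e$effect_allele[i]; oa_e <- e$other_allele[i]
    ea_o <- o$effect_allele[i]; oa_o <- o$other_allele[i]
    if (is_palindromic(ea_e, oa_e)) {
      pal[i] <- TRUE
      same_letters <- setequal(c(ea_o, oa_o), c(ea_e, oa_e))
      if (!same_letters) { reason[i] <- "allele mismatch"; next }
      fe <- e$eaf[i]; fo <- o$eaf[i]
      if (is.na(fe) || is.na(fo) ||
          abs(fe - 0.5) <= w || abs(fo - 0.5) <= w) {
        reason[i] <- "ambiguous palindromic"; next
      }
      # letters cannot orient a palindrome; frequencies decide
      keep[i] <- TRUE
      if ((fe < 0.5) != (fo < 0.5)) {
        flipped[i] <- TRUE
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
      }
    } else {
      cea <- ALLELE_COMPLEMENT[ea_o]; coa <- ALLELE_COMPLEMENT[oa_o]
      if ((ea_o == ea_e && oa_o == oa_e) ||
          (cea == ea_e && coa == oa_e)) {
        keep[i] <- TRUE
      } else if ((ea_o == oa_e && oa_o == ea_e) ||
                 (cea == oa_e && coa == ea_e)) {
        keep[i] <- TRUE
        flipped[i] <- TRUE
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
      } else {
        reason[i] <- "allele mismatch"
      }
    }
  }
  pairs <- data.frame(snp = shared,
                      effect_allele = e$effect_allele,
                      other_allele = e$other_allele,
                      beta_exp = e$beta, se_exp = e$se,
                      beta_out = beta_out, se_out = o$se,
                      eaf_exp = e$eaf, eaf_out = eaf_out,
                      flipped = flipped, palindromic = pal,
                      row.names = NULL,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  excluded <- data.frame(snp = shared[!keep], reason = reason[!keep],
                         row.names = NULL, stringsAsFactors = FALSE)
  if (nrow(excluded))
    message(nrow(excluded), " SNP(s) excluded during harmonization")
  attr(pairs, "excluded") <- excluded
  pairs
}

#' Per-SNP Wald ratio
#'
#' The single-instrument causal estimate: outcome effect divided by exposure
#' effect, with the first-order delta-method standard error
#' `se_out / |beta_exp|`.
#'
#' @param pairs harmonized pairs ([harmonize()]) or a data.frame with columns
#'   `beta_exp`, `beta_out`, `se_out`.
#' @return data.frame with columns `snp` (if present), `beta`, `se`.
#' @export
wald_ratio <- function(pairs) {
  need_cols(pairs, c("beta_exp", "beta_out", "se_out"), "harmonized pairs")
  if (any(pairs$beta_exp == 0))
    stop("Wald ratio undefined for beta_exp = 0", call. = FALSE)
  out <- data.frame(beta = pairs$beta_out / pairs$beta_exp,
                    se = pairs$se_out / abs(pairs$beta_exp))
  if (!is.null(pairs$snp)) out <- cbind(snp = pairs$snp, out)
  out
}

ivw_weights <- function(pairs) pairs$beta_exp^2 / pairs$se_out^2

mr_estimate <- function(method, beta, se, p_value, n_snps) {
  structure(list(method = method, beta = beta, se = se, p_value = p_value,
                 odds_ratio = exp(beta),
                 ci_low = exp(beta - 1.96 * se),
                 ci_high = exp(beta + 1.96 * se),
                 n_snps = as.integer(n_snps)),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4g (se %.4g), p = %.3g, OR = %.3f [%.3f, %.3f], J = %d\n",
              x$method, x$beta, x$se, x$p_value, x$odds_ratio,
              x$ci_low, x$ci_high, x$n_snps))
  invisible(x)
}

#' Inverse-variance-weighted causal estimate
#'
#' Combines per-SNP Wald ratios with weights `beta_exp^2 / se_out^2`
#' (equivalently, weighted regression of outcome on exposure effects through
#' the origin). Under the fixed-effect model the standard error is
#' `sqrt(1 / sum(w))`; under the default multiplicative random-effects model
#' it is inflated by `max(1, sqrt(Q / (J - 1)))` where `Q` is Cochran's Q at
#' the IVW estimate. P-values use the normal reference.
#'
#' @param pairs harmonized pairs (>= 2 rows, or 1 with
#'   `allow_single = TRUE`, in which case the estimate is the Wald ratio).
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @param allow_single permit a single instrument.
#' @return an `mr_estimate` (method `"ivw"`) with the heterogeneity `Q`
#'   attached as attribute `"Q"`.
#' @export
ivw_estimate <- function(pairs, model = c("multiplicative_random", "fixed"),
                         allow_single = FALSE) {
  model <- match.arg(model)
  J <- nrow(pairs)
  min_j <- if (allow_single) 1L else 2L
  if (J < min_j)
    stop("IVW requires >= ", min_j, " instrument(s), got ", J, call. = FALSE)
  wr <- wald_ratio(pairs)
  w <- ivw_weights(pairs)
  beta <- sum(w * wr$beta) / sum(w)
  se <- sqrt(1 / sum(w))
  Q <- sum(w * (wr$beta - beta)^2)
  if (model == "multiplicative_random" && J > 1)
    se <- se * max(1, sqrt(Q / (J - 1)))
  est <- mr_estimate("ivw", beta, se, 2 * stats::pnorm(-abs(beta / se)), J)
  attr(est, "Q") <- Q
  est
}

weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  wn <- weights[ord] / sum(weights)
  p <- cumsum(wn) - wn / 2
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  k <- max(which(p <= 0.5))
  if (p[k] == 0.5) return(r[k])
  r[k] + (r[k + 1] - r[k]) * (0.5 - p[k]) / (p[k + 1] - p[k])
}

#' Weighted-median causal estimate
#'
#' Consistent when at least half of the total instrument weight comes from
#' valid instruments. Wald ratios are sorted and the estimate interpolates
#' the weighted median: with normalized weights `w'`, cumulative positions
#' `p_k = sum_{i<=k} w'_i - w'_k / 2`, the estimate interpolates linearly
#' between the ratios bracketing `p = 0.5`. The standard error comes from a
#' parametric bootstrap of `(beta_exp, beta_out)`; the p-value uses the
#' normal reference.
#'
#' @param pairs harmonized pairs, at least 3.
#' @param n_boot bootstrap replicates for the SE (default 1000).
#' @param seed RNG seed for the bootstrap (required for reproducibility).
#' @return an `mr_estimate` (method `"weighted_median"`).
#' @export
weighted_median_estimate <- function(pairs, n_boot = 1000, seed = 1) {
  J <- nrow(pairs)
  if (J < 3)
    stop("weighted median requires >= 3 instruments, got ", J, call. = FALSE)
  check_scalar(n_boot, "n_boot", lower = 2, integerish = TRUE)
  wr <- wald_ratio(pairs)
  w <- ivw_weights(pairs)
  beta <- weighted_median_point(wr$beta, w)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(J, pairs$beta_exp, pairs$se_exp)
      by <- stats::rnorm(J, pairs$beta_out, pairs$se_out)
      ok <- bx != 0
      weighted_median_point(by[ok] / bx[ok], bx[ok]^2 / pairs$se_out[ok]^2)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  mr_estimate("weighted_median", beta, se,
              2 * stats::pnorm(-abs(beta / se)), J)
}

#' MR-Egger regression with pleiotropy intercept test
#'
#' Weighted least squares of outcome effects on exposure effects with a free
#' intercept and weights `1 / se_out^2`, after orienting every pair so that
#' `beta_exp >= 0` (the estimator is not invariant to allele orientation).
#' The slope estimates the causal effect; the intercept estimates average
#' directional pleiotropy. Both standard errors are inflated by the residual
#' scale factor `max(1, sqrt(Q_egger / (J - 2)))` and tested against a
#' t distribution with `J - 2` degrees of freedom. Pleiotropy is judged
#' absent when the intercept p-value exceeds 0.05.
#'
#' @param pairs harmonized pairs, at least 3.
#' @return list with elements `estimate` (an `mr_estimate`, method
#'   `"egger"`), `pleiotropy` (`intercept`, `se`, `p_value`), and
#'   `heterogeneity` (`q_stat`, `df`, `p_value`).
#' @export
egger_estimate <- function(pairs) {
  J <- nrow(pairs)
  if (J < 3)
    stop("MR-Egger requires >= 3 instruments, got ", J, call. = FALSE)
  s <- ifelse(pairs$beta_exp < 0, -1, 1)
  x <- s * pairs$beta_exp
  y <- s * pairs$beta_out
  w <- 1 / pairs$se_out^2
  W <- sum(w); Sx <- sum(w * x); Sy <- sum(w * y)
  Sxx <- sum(w * x * x); Sxy <- sum(w * x * y)
  D <- W * Sxx - Sx^2
  if (!is.finite(D) || D <= .Machine$double.eps * W * Sxx)
    stop("MR-Egger slope not identifiable: no spread in exposure effects",
         call. = FALSE)
  slope <- (W * Sxy - Sx * Sy) / D
  intercept <- (Sxx * Sy - Sx * Sxy) / D
  resid <- y - intercept - slope * x
  Q <- sum(w * resid^2)
  infl <- max(1, sqrt(Q / (J - 2)))
  se_slope <- sqrt(W / D) * infl
  se_int <- sqrt(Sxx / D) * infl
  p_slope <- 2 * stats::pt(-abs(slope / se_slope), J - 2)
  p_int <- 2 * stats::pt(-abs(intercept / se_int), J - 2)
  list(estimate = mr_estimate("egger", slope, se_slope, p_slope, J),
       pleiotropy = list(intercept = intercept, se = se_int,
                         p_value = p_int),
       heterogeneity = list(q_stat = Q, df = J - 2L,
                            p_value = stats::pchisq(Q, J - 2,
                                                    lower.tail = FALSE)))
}

#' Cochran's Q heterogeneity statistic
#'
#' Weighted sum of squared deviations of the Wald ratios from a central
#' estimate, with IVW weights. With the IVW estimate as center the statistic
#' is referred to a chi-square distribution with `J - 1` degrees of freedom.
#'
#' @param pairs harmonized pairs, at least 2.
#' @param center central estimate (defaults to the fixed-effect IVW beta).
#' @return list with `q_stat`, `df`, `p_value`.
#' @export
cochran_q <- function(pairs, center = NULL) {
  J <- nrow(pairs)
  if (J < 2) stop("Cochran's Q requires >= 2 instruments", call. = FALSE)
  wr <- wald_ratio(pairs)
  w <- ivw_weights(pairs)
  if (is.null(center)) center <- sum(w * wr$beta) / sum(w)
  Q <- sum(w * (wr$beta - center)^2)
  list(q_stat = Q, df = J - 1L,
       p_value = stats::pchisq(Q, J - 1, lower.tail = FALSE))
}

#' Leave-one-out sensitivity analysis
#'
#' Recomputes the IVW estimate excluding each instrument in turn, to flag
#' single SNPs that dominate the combined effect.
#'
#' @param pairs harmonized pairs, at least 3.
#' @param model IVW standard-error model, passed to [ivw_estimate()].
#' @return data.frame with one row per excluded SNP (`excluded_snp`, `beta`,
#'   `se`, `p_value`), in input order.
#' @export
leave_one_out <- function(pairs, model = "multiplicative_random") {
  J <- nrow(pairs)
  if (J < 3)
    stop("leave-one-out requires >= 3 instruments, got ", J, call. = FALSE)
  res <- lapply(seq_len(J), function(j) {
    est <- ivw_estimate(pairs[-j, , drop = FALSE], model = model)
    data.frame(excluded_snp = pairs$snp[j], beta = est$beta, se = est$se,
               p_value = est$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Convert a log-scale estimate to an odds ratio
#'
#' `OR = exp(beta)` with the 95% Wald interval `exp(beta +/- 1.96 se)`.
#' An OR below 1 is read as a risk reduction per SD increase of the exposure.
#'
#' @param beta log-scale causal estimate.
#' @param se its standard error (> 0).
#' @return list with `or`, `ci_low`, `ci_high`.
#' @export
to_odds_ratio <- function(beta, se) {
  if (any(se <= 0)) stop("se must be > 0", call. = FALSE)
  list(or = exp(beta), ci_low = exp(beta - 1.96 * se),
       ci_high = exp(beta + 1.96 * se))
}

#' Run the full two-sample MR suite on one exposure/outcome pair
#'
#' Convenience wrapper: instrument selection, harmonization, the requested
#' estimators, Cochran's Q at the IVW estimate, the Egger pleiotropy
#' intercept test, and leave-one-out sensitivity.
#'
#' @param exposure,outcome GWAS summary data.frames.
#' @param threshold instrument p-value threshold (strict `<`, default 5e-8).
#' @param methods subset of `c("ivw", "weighted_median", "egger")`.
#' @param ivw_model `"multiplicative_random"` or `"fixed"`.
#' @param n_boot,seed weighted-median bootstrap controls.
#' @param loo run leave-one-out (needs >= 3 instruments).
#' @param palindromic_eaf_window passed to [harmonize()].
#' @return object of class `mr_analysis`: list with `estimates` (data.frame,
#'   one row per method), `heterogeneity`, `pleiotropy` (NULL unless Egger
#'   ran), `loo`, `pairs`, `excluded`.
#' @export
run_mr <- function(exposure, outcome, threshold = 5e-8,
                   methods = c("ivw", "weighted_median", "egger"),
                   ivw_model = "multiplicative_random",
                   n_boot = 1000, seed = 1, loo = TRUE,
                   palindromic_eaf_window = 0.08) {
  methods <- match.arg(methods, c("ivw", "weighted_median", "egger"),
                       several.ok = TRUE)
  inst <- select_instruments(exposure, threshold)
  if (nrow(inst) < 2)
    stop("fewer than 2 instruments at p < ", format(threshold), call. = FALSE)
  pairs <- harmonize(inst, outcome,
                     palindromic_eaf_window = palindromic_eaf_window)
  if (nrow(pairs) < 2)
    stop("fewer than 2 instruments survive harmonization", call. = FALSE)
  ests <- list()
  het <- pleio <- NULL
  if ("ivw" %in% methods) {
    ivw <- ivw_estimate(pairs, model = ivw_model)
    ests <- c(ests, list(ivw))
    het <- cochran_q(pairs)
  }
  if ("weighted_median" %in% methods)
    ests <- c(ests, list(weighted_median_estimate(pairs, n_boot = n_boot,
                                                  seed = seed)))
  if ("egger" %in% methods) {
    eg <- egger_estimate(pairs)
    ests <- c(ests, list(eg$estimate))
    pleio <- eg$pleiotropy
  }
  est_df <- do.call(rbind, lapply(ests, function(e)
    data.frame(method = e$method, n_snps = e$n_snps, beta = e$beta,
               se = e$se, p_value = e$p_value, odds_ratio = e$odds_ratio,
               ci_low = e$ci_low, ci_high = e$ci_high,
               stringsAsFactors = FALSE)))
  loo_df <- if (loo && nrow(pairs) >= 3) leave_one_out(pairs,
                                                       model = ivw_model)
  structure(list(estimates = est_df, heterogeneity = het,
                 pleiotropy = pleio, loo = loo_df, pairs = pairs,
                 excluded = attr(pairs, "excluded")),
            class = "mr_analysis")
}

#' @export
print.mr_analysis <- function(x, ...) {
  cat("Two-sample MR on", nrow(x$pairs), "harmonized instrument(s)\n")
  print(x$estimates, digits = 4)
  if (!is.null(x$heterogeneity))
    cat(sprintf("Cochran's Q = %.3f (df %d, p = %.3g)\n",
                x$heterogeneity$q_stat, x$heterogeneity$df,
                x$heterogeneity$p_value))
  if (!is.null(x$pleiotropy))
    cat(sprintf("Egger intercept = %.4g (se %.4g, p = %.3g)\n",
                x$pleiotropy$intercept, x$pleiotropy$se,
                x$pleiotropy$p_value))
  invisible(x)
}

#' Two-step Mendelian randomization mediation analysis
#'
#' Step 1 estimates the causal effect of the exposure on the mediator; step 2
#' the effect of the mediator on the outcome. Each step runs the full MR
#' suite ([run_mr()]). The mediated effect is the product of the two IVW
#' betas; an optional delta-method SE
#' `sqrt(b2^2 se1^2 + b1^2 se2^2)` is attached. A consistency report flags
#' any step whose Egger intercept p-value is at or below 0.05, the working
#' rule for non-ignorable directional pleiotropy.
#'
#' @param exp_gwas,med_gwas,out_gwas GWAS summary data.frames for the
#'   exposure, mediator and outcome traits.
#' @param threshold,methods,ivw_model,n_boot,seed passed to [run_mr()].
#' @return object of class `two_step_mr`: list with `step1`, `step2`
#'   (`mr_analysis` objects), `mediated_effect`, `mediated_se`, and
#'   `pleiotropy_flags` (per step, TRUE when the Egger intercept test
#'   rejects).
#' @export
run_two_step <- function(exp_gwas, med_gwas, out_gwas, threshold = 5e-8,
                         methods = c("ivw", "weighted_median", "egger"),
                         ivw_model = "multiplicative_random",
                         n_boot = 1000, seed = 1) {
  step1 <- tryCatch(
    run_mr(exp_gwas, med_gwas, threshold = threshold, methods = methods,
           ivw_model = ivw_model, n_boot = n_boot, seed = seed),
    error = function(e) stop("step 1 (exposure -> mediator): ",
                             conditionMessage(e), call. = FALSE))
  step2 <- tryCatch(
    run_mr(med_gwas, out_gwas, threshold = threshold, methods = methods,
           ivw_model = ivw_model, n_boot = n_boot, seed = seed + 1),
    error = function(e) stop("step 2 (mediator -> outcome): ",
                             conditionMessage(e), call. = FALSE))
  b1 <- step1$estimates$beta[step1$estimates$method == "ivw"]
  s1 <- step1$estimates$se[step1$estimates$method == "ivw"]
  b2 <- step2$estimates$beta[step2$estimates$method == "ivw"]
  s2 <- step2$estimates$se[step2$estimates$method == "ivw"]
  if (!length(b1) || !length(b2))
    stop("two-step mediation requires the IVW method in both steps",
         call. = FALSE)
  flags <- c(step1 = !is.null(step1$pleiotropy) &&
               step1$pleiotropy$p_value <= 0.05,
             step2 = !is.null(step2$pleiotropy) &&
               step2$pleiotropy$p_value <= 0.05)
  structure(list(step1 = step1, step2 = step2,
                 mediated_effect = b1 * b2,
                 mediated_se = sqrt(b2^2 * s1^2 + b1^2 * s2^2),
                 pleiotropy_flags = flags),
            class = "two_step_mr")
}

#' @export
print.two_step_mr <- function(x, ...) {
  cat("Step 1 (exposure -> mediator):\n"); print(x$step1)
  cat("Step 2 (mediator -> outcome):\n"); print(x$step2)
  cat(sprintf("Mediated effect (product of IVW betas): %.4g (delta se %.4g)\n",
              x$mediated_effect, x$mediated_se))
  if (any(x$pleiotropy_flags))
    cat("Warning: Egger intercept test rejects in:",
        paste(names(x$pleiotropy_flags)[x$pleiotropy_flags],
              collapse = ", "), "\n")
  invisible(x)
}
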