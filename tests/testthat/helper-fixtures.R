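# Shared fixture builders and independent oracles.

make_pairs <- function(beta_exp, beta_out, se_out,
                       se_exp = rep(0.01, length(beta_exp))) {
  data.frame(snp = sprintf("rs%03d", seq_along(beta_exp)),
             beta_exp = beta_exp, se_exp = se_exp,
             beta_out = beta_out, se_out = se_out,
             stringsAsFactors = FALSE)
}

random_pairs <- function(J, seed) {
  set.seed(seed)
  make_pairs(beta_exp = rnorm(J, 0.3, 0.1),
             beta_out = rnorm(J, 0.1, 0.05),
             se_out = runif(J, 0.005, 0.05),
             se_exp = runif(J, 0.005, 0.02))
}

# Independent Benjamini-Hochberg step-up, written from the definition:
# sorted q_(k) = min_{l >= k} p_(l) * m / l, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  o <- order(p)
  q_sorted <- numeric(m)
  running <- Inf
  for (k in m:1) {
    running <- min(running, p[o[k]] * m / k)
    q_sorted[k] <- min(running, 1)
  }
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# Direct per-sample evaluation of the SIMPO formula for one gene.
simpo_oracle <- function(body, promoter, pooled = TRUE) {
  m <- length(body); n <- length(promoter)
  s1 <- var(body); s2 <- var(promoter)
  denom <- if (pooled) m + n - 2 else m + n + 1
  sw <- sqrt(((m - 1) * s1 + (n - 1) * s2) / denom)
  (mean(body) - mean(promoter)) / (sw * sqrt(1 / m + 1 / n))
}

# A small GWAS table with aligned alleles (no palindromes).
tiny_gwas <- function(beta, se, pval = 2 * pnorm(-abs(beta / se)),
                      eaf = rep(0.3, length(beta)),
                      ea = rep("A", length(beta)),
                      oa = rep("G", length(beta)),
                      trait = "trait") {
  data.frame(snp = sprintf("rs%03d", seq_along(beta)),
             effect_allele = ea, other_allele = oa,
             beta = beta, se = se, pval = pval, eaf = eaf, trait = trait,
             stringsAsFactors = FALSE)
}
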