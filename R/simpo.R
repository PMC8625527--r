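#' Gene-level SIMPO methylation scores
#'
#' Collapses probe-level methylation beta values into one score per gene and
#' sample by contrasting the mean methylation of gene-body probes against
#' promoter probes. For a gene with `m` body probes and `n` promoter probes,
#' the score for one sample is
#' \deqn{(\bar x - \bar y) / (S_w \sqrt{1/m + 1/n})}
#' where \eqn{\bar x, S_1^2} are the mean and variance of that sample's body
#' probe betas, \eqn{\bar y, S_2^2} of its promoter probe betas, and
#' \eqn{S_w = \sqrt{[(m-1)S_1^2 + (n-1)S_2^2]/(m+n-2)}} is the pooled standard
#' deviation. The score has the form of a two-sample t statistic with
#' `m + n - 2` degrees of freedom.
#'
#' Only "SIMPO-eligible" genes are scored: a gene needs at least two body and
#' two promoter probes, otherwise its variance terms are undefined. A probe
#' value missing for a sample is dropped from that sample's region moments; if
#' that leaves fewer than two probes in either region the gene is unscored
#' (`NA`) for that sample. A sample where the pooled SD is exactly zero scores
#' 0 when the two region means are equal and `NA` (with a warning) otherwise.
#'
#' @param beta numeric matrix of methylation beta values in `[0, 1]`
#'   (probes x samples) with probe ids as row names, or the list returned by
#'   [simulate_methylation_cohort()].
#' @param annot data.frame with columns `probe_id`, `gene`, `region`
#'   (`"promoter"` or `"body"`). Ignored when `beta` is a simulated cohort,
#'   which carries its own annotation.
#' @param sw `"pooled"` (default) computes the pooled SD with denominator
#'   `m + n - 2`, consistent with the declared t distribution; `"printed"`
#'   reproduces an alternative variant with denominator `m + n + 1`, kept for
#'   comparison only.
#' @return An object of class `simpo_scores`: a list with `scores` (genes x
#'   samples matrix), `df` (named integer, `m + n - 2` per gene), and the
#'   per-gene probe counts `m_body`, `n_promoter`.
#' @examples
#' beta <- rbind(cg1 = c(s1 = 0.6), cg2 = c(s1 = 0.8),
#'               cg3 = c(s1 = 0.2), cg4 = c(s1 = 0.4))
#' ann <- data.frame(probe_id = rownames(beta), gene = "G1",
#'                   region = c("body", "body", "promoter", "promoter"))
#' compute_simpo_scores(beta, ann)$scores  # 2.8284
#' @export
compute_simpo_scores <- function(beta, annot = NULL,
                                 sw = c("pooled", "printed")) {
  sw <- match.arg(sw)
  if (is.list(beta) && !is.null(beta$beta)) {
    if (is.null(annot)) annot <- beta$annotation
    beta <- beta$beta
  }
  if (!is.matrix(beta) || !is.numeric(beta))
    stop("beta must be a numeric matrix (probes x samples)", call. = FALSE)
  if (is.null(rownames(beta)))
    stop("beta must have probe ids as row names", call. = FALSE)
  need_cols(annot, c("probe_id", "gene", "region"), "probe annotation")
  bad_region <- setdiff(unique(as.character(annot$region)),
                        c("promoter", "body"))
  if (length(bad_region))
    stop("unknown region label(s): ", paste(bad_region, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(annot$probe_id))
    stop("duplicate probe_id in annotation", call. = FALSE)
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("beta values must lie in [0, 1]", call. = FALSE)

  annot <- annot[annot$probe_id %in% rownames(beta), , drop = FALSE]
  n_unannotated <- sum(!rownames(beta) %in% annot$probe_id)
  if (n_unannotated > 0)
    message(n_unannotated, " probe(s) in the beta matrix have no annotation ",
            "and were ignored")

  body_tab <- table(annot$gene[annot$region == "body"])
  prom_tab <- table(annot$gene[annot$region == "promoter"])
  genes <- sort(intersect(names(body_tab)[body_tab >= 2],
                          names(prom_tab)[prom_tab >= 2]))
  if (!length(genes)) {
    warning("no SIMPO-eligible genes (need >= 2 probes per region)",
            call. = FALSE)
    return(structure(list(
      scores = matrix(numeric(0), 0, ncol(beta),
                      dimnames = list(NULL, colnames(beta))),
      df = integer(0), m_body = integer(0), n_promoter = integer(0)),
      class = "simpo_scores"))
  }

  S <- ncol(beta)
  scores <- matrix(NA_real_, length(genes), S,
                   dimnames = list(genes, colnames(beta)))
  m_body <- n_promoter <- integer(length(genes))
  names(m_body) <- names(n_promoter) <- genes
  n_degenerate <- 0L
  for (i in seq_along(genes)) {
    g <- genes[i]
    rows_b <- annot$probe_id[annot$gene == g & annot$region == "body"]
    rows_p <- annot$probe_id[annot$gene == g & annot$region == "promoter"]
    m_body[i] <- length(rows_b)
    n_promoter[i] <- length(rows_p)
    B <- col_moments(beta[rows_b, , drop = FALSE])
    P <- col_moments(beta[rows_p, , drop = FALSE])
    ok <- B$n >= 2 & P$n >= 2
    num <- B$mean - P$mean
    denom_df <- if (sw == "pooled") B$n + P$n - 2 else B$n + P$n + 1
    sw_val <- sqrt(((B$n - 1) * B$var + (P$n - 1) * P$var) / denom_df)
    sc <- num / (sw_val * sqrt(1 / B$n + 1 / P$n))
    zero_sw <- ok & sw_val == 0
    sc[zero_sw & num == 0] <- 0
    deg <- zero_sw & num != 0
    n_degenerate <- n_degenerate + sum(deg, na.rm = TRUE)
    sc[deg] <- NA_real_
    sc[!ok] <- NA_real_
    scores[i, ] <- sc
  }
  if (n_degenerate > 0)
    warning(n_degenerate, " gene-sample score(s) had zero pooled SD with ",
            "unequal region means; set to NA", call. = FALSE)
  structure(list(scores = scores,
                 df = m_body + n_promoter - 2L,
                 m_body = m_body, n_promoter = n_promoter),
            class = "simpo_scores")
}

# Column-wise NA-aware moments of a (probes x samples) matrix.
col_moments <- function(x) {
  n <- colSums(!is.na(x))
  m <- ifelse(n > 0, colSums(x, na.rm = TRUE) / n, NA_real_)
  v <- ifelse(n > 1, (colSums(x * x, na.rm = TRUE) - n * m^2) / (n - 1),
              NA_real_)
  v[!is.na(v) & v < 0] <- 0
  list(n = n, mean = m, var = v)
}

#' @export
print.simpo_scores <- function(x, ...) {
  cat("SIMPO score matrix:", nrow(x$scores), "gene(s) x",
      ncol(x$scores), "sample(s)\n")
  invisible(x)
}

#' Differential methylation screen on SIMPO scores
#'
#' Per gene, compares SIMPO scores between the control and treated groups with
#' a two-sample t test (Welch by default; set `var_equal = TRUE` for the
#' pooled-variance test). A gene is called significant when `p < alpha`.
#'
#' @param scores a `simpo_scores` object from [compute_simpo_scores()], or a
#'   genes x samples numeric matrix.
#' @param groups sample -> group mapping: a named character vector or a
#'   data.frame with columns `sample_id`, `group` (`"control"`/`"treated"`).
#' @param alpha significance threshold on the p-value (default 0.05).
#' @param var_equal use the pooled-variance t test instead of Welch.
#' @return data.frame with columns `gene`, `t_stat`, `p_value`, `direction`
#'   (`"up"` if the treated mean score exceeds the control mean), and
#'   `significant`.
#' @export
diff_methylation_simpo <- function(scores, groups, alpha = 0.05,
                                   var_equal = FALSE) {
  if (inherits(scores, "simpo_scores")) scores <- scores$scores
  check_scalar(alpha, "alpha", lower = 0, upper = 1)
  grp <- as_group_factor(groups)
  if (!all(colnames(scores) %in% names(grp)))
    stop("every score column must have a group assignment", call. = FALSE)
  grp <- grp[colnames(scores)]
  if (sum(grp == "control") < 2 || sum(grp == "treated") < 2)
    stop("need >= 2 samples per group", call. = FALSE)

  ctl <- row_moments(scores[, grp == "control", drop = FALSE])
  trt <- row_moments(scores[, grp == "treated", drop = FALSE])
  diff <- trt$mean - ctl$mean
  if (var_equal) {
    df <- ctl$n + trt$n - 2
    sp2 <- ((ctl$n - 1) * ctl$var + (trt$n - 1) * trt$var) / df
    se <- sqrt(sp2 * (1 / ctl$n + 1 / trt$n))
  } else {
    a <- ctl$var / ctl$n
    b <- trt$var / trt$n
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (ctl$n - 1) + b^2 / (trt$n - 1))
  }
  t_stat <- diff / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  flat <- !is.na(se) & se == 0 & !is.na(diff) & diff == 0
  if (any(flat)) {
    t_stat[flat] <- 0
    p[flat] <- 1
    message(sum(flat), " gene(s) with zero variance in both groups and equal ",
            "means; p set to 1")
  }
  data.frame(gene = rownames(scores),
             t_stat = t_stat,
             p_value = p,
             direction = ifelse(diff > 0, "up", "down"),
             significant = !is.na(p) & p < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Probe-level differential methylation scan
#'
#' Per probe, fits the two-group comparison as a linear model on the group
#' indicator; with two groups the model F statistic equals the squared
#' pooled-variance t statistic. P-values are converted to q-values by
#' Benjamini-Hochberg ([adjust_qvalues()]) and probes are called significant
#' when `q < q_threshold`.
#'
#' @param beta probes x samples beta matrix (or simulated cohort list).
#' @param groups sample -> group mapping, as in [diff_methylation_simpo()].
#' @param q_threshold significance threshold on the q-value (default 0.001).
#' @return data.frame with columns `probe_id`, `stat` (F), `p_value`,
#'   `q_value`, `significant`.
#' @export
dmp_scan <- function(beta, groups = NULL, q_threshold = 0.001) {
  if (is.list(beta) && !is.null(beta$beta)) {
    if (is.null(groups)) groups <- beta$groups
    beta <- beta$beta
  }
  check_scalar(q_threshold, "q_threshold", lower = 0, upper = 1)
  grp <- as_group_factor(groups)
  if (!all(colnames(beta) %in% names(grp)))
    stop("every sample must have a group assignment", call. = FALSE)
  grp <- grp[colnames(beta)]
  n1 <- sum(grp == "control"); n2 <- sum(grp == "treated")
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per group", call. = FALSE)

  ctl <- row_moments(beta[, grp == "control", drop = FALSE])
  trt <- row_moments(beta[, grp == "treated", drop = FALSE])
  df2 <- ctl$n + trt$n - 2
  sp2 <- ((ctl$n - 1) * ctl$var + (trt$n - 1) * trt$var) / df2
  diff <- trt$mean - ctl$mean
  fstat <- diff^2 / (sp2 * (1 / ctl$n + 1 / trt$n))
  # constant probes: zero pooled variance and (up to round-off) equal means
  const <- !is.na(sp2) & sp2 == 0 &
    abs(diff) <= 1e-8 * pmax(abs(ctl$mean), abs(trt$mean), 1)
  fstat[const] <- 0
  p <- stats::pf(fstat, 1, df2, lower.tail = FALSE)
  p[!is.na(fstat) & fstat == 0] <- 1
  q <- adjust_qvalues(p)
  data.frame(probe_id = rownames(beta),
             stat = fstat,
             p_value = p,
             q_value = q,
             significant = !is.na(q) & q < q_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; a thin wrapper around
#' [stats::p.adjust()] with `method = "BH"` that validates its input. Output
#' order matches input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, same length and order.
#' @export
adjust_qvalues <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (!is.numeric(p_values) || any(!is.na(p_values) &
                                   (p_values < 0 | p_values > 1)))
    stop("p-values must be numeric in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Collapse significant probes to gene symbols
#'
#' Maps significant probes to genes through the annotation and returns the
#' sorted unique gene symbols. Probes without a gene annotation are dropped
#' with a message stating the count.
#'
#' @param dmps data.frame of significant probes (at least a `probe_id`
#'   column); typically `subset(dmp_scan(...), significant)`.
#' @param annot probe annotation data.frame (`probe_id`, `gene`).
#' @return sorted character vector of unique gene symbols.
#' @export
annotate_and_collapse <- function(dmps, annot) {
  need_cols(dmps, "probe_id", "DMP table")
  need_cols(annot, c("probe_id", "gene"), "probe annotation")
  idx <- match(dmps$probe_id, annot$probe_id)
  genes <- as.character(annot$gene[idx])
  dropped <- sum(is.na(idx) | is.na(genes) | !nzchar(genes))
  if (dropped > 0)
    message(dropped, " significant probe(s) without gene annotation dropped")
  sort(unique(genes[!is.na(genes) & nzchar(genes)]))
}

#' Intersect two gene lists
#'
#' Case-sensitive exact set intersection, returned sorted and unique.
#'
#' @param a,b character vectors of gene symbols.
#' @return sorted character vector of the intersection.
#' @export
intersect_gene_lists <- function(a, b) {
  sort(intersect(unique(as.character(a)), unique(as.character(b))))
}
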