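#' Read a GWAS summary-statistic table
#'
#' Tab-separated, one row per SNP, columns `snp`, `effect_allele`,
#' `other_allele`, `beta`, `se`, `pval` and optionally `eaf`, `trait`.
#' Alleles must be single upper-case characters; duplicate rsIDs, missing
#' columns and non-positive SEs are rejected with the offending location.
#'
#' @param path TSV file path.
#' @return validated data.frame.
#' @export
read_gwas_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  validate_gwas(tab, what = basename(path))
  for (col in c("beta", "se", "pval"))
    if (!is.numeric(tab[[col]]))
      stop(basename(path), ": column '", col, "' is not numeric",
           call. = FALSE)
  bad <- !tab$effect_allele %in% c("A", "C", "G", "T") |
    !tab$other_allele %in% c("A", "C", "G", "T")
  if (any(bad))
    stop(basename(path), ": invalid allele code(s) in row(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  tab
}

#' Write a data.frame as TSV
#'
#' Full-precision, tab-separated, no quoting or row names, so that a
#' write-then-read round trip reproduces numeric values exactly.
#'
#' @param table data.frame.
#' @param path output file path (parent directory must exist).
#' @export
write_tsv <- function(table, path) {
  utils::write.table(format(table, digits = 17, trim = TRUE,
                            scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a methylation beta matrix
#'
#' TSV with probe ids in the first column and one column per sample; empty
#' cells are treated as missing. Values must lie in `[0, 1]`.
#'
#' @param path TSV file path.
#' @return numeric matrix (probes x samples) with probe ids as row names.
#' @export
read_beta_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (ncol(tab) < 2)
    stop(basename(path), ": expected probe_id plus sample columns",
         call. = FALSE)
  if (anyDuplicated(tab[[1]]))
    stop(basename(path), ": duplicate probe id(s)", call. = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m))
    stop(basename(path), ": non-numeric beta value(s)", call. = FALSE)
  rownames(m) <- tab[[1]]
  rng <- range(m, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop(basename(path), ": beta values outside [0, 1]", call. = FALSE)
  m
}

#' Read a probe annotation table
#'
#' TSV with columns `probe_id`, `gene`, `region` ("promoter"/"body").
#'
#' @param path TSV file path.
#' @return validated data.frame.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need_cols(tab, c("probe_id", "gene", "region"), basename(path))
  bad <- !tab$region %in% c("promoter", "body")
  if (any(bad))
    stop(basename(path), ": region must be 'promoter' or 'body' (row ",
         which(bad)[1], ")", call. = FALSE)
  tab
}

#' Read a sample-to-group assignment table
#'
#' TSV with columns `sample_id`, `group` ("control"/"treated").
#'
#' @param path TSV file path.
#' @return validated data.frame.
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need_cols(tab, c("sample_id", "group"), basename(path))
  as_group_factor(tab)  # validates labels
  tab
}

#' Build a validated run configuration
#'
#' Bundles input paths, thresholds and the seed for the pipeline runners.
#' Thresholds must lie in (0, 1]. A YAML file with the same field names can
#' be loaded with `run_config_from_yaml()`.
#'
#' @param beta_file,annotation_file,groups_file methylation inputs.
#' @param exposure_file,mediator_file,outcome_file GWAS inputs
#'   (`mediator_file` switches [run_mr_pipeline()] to two-step mode).
#' @param alpha gene-level screen p threshold.
#' @param q_threshold probe-level screen q threshold.
#' @param instrument_p instrument selection threshold.
#' @param methods MR methods to run.
#' @param ivw_model IVW SE model.
#' @param n_boot weighted-median bootstrap replicates.
#' @param seed RNG seed for stochastic stages.
#' @param out_dir output directory (created if absent).
#' @return list of class `run_config`.
#' @export
run_config <- function(beta_file = NULL, annotation_file = NULL,
                       groups_file = NULL, exposure_file = NULL,
                       mediator_file = NULL, outcome_file = NULL,
                       alpha = 0.05, q_threshold = 0.001,
                       instrument_p = 5e-8,
                       methods = c("ivw", "weighted_median", "egger"),
                       ivw_model = "multiplicative_random",
                       n_boot = 1000, seed = 1, out_dir = ".") {
  for (th in c(alpha = alpha, q_threshold = q_threshold,
               instrument_p = instrument_p)) {
    if (!is.numeric(th) || th <= 0 || th > 1)
      stop("thresholds must lie in (0, 1]", call. = FALSE)
  }
  check_scalar(seed, "seed", integerish = TRUE)
  structure(list(beta_file = beta_file, annotation_file = annotation_file,
                 groups_file = groups_file, exposure_file = exposure_file,
                 mediator_file = mediator_file, outcome_file = outcome_file,
                 alpha = alpha, q_threshold = q_threshold,
                 instrument_p = instrument_p, methods = methods,
                 ivw_model = ivw_model, n_boot = n_boot,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file whose keys match the `run_config()` arguments.
#' @export
run_config_from_yaml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(run_config, vals)
}

write_manifest <- function(cfg, out_dir, extra = list()) {
  inputs <- Filter(Negate(is.null),
                   cfg[c("beta_file", "annotation_file", "groups_file",
                         "exposure_file", "mediator_file", "outcome_file")])
  checksums <- lapply(inputs, function(p)
    unname(tools::md5sum(p)))
  manifest <- c(list(package_version =
                       as.character(utils::packageVersion("simpomr")),
                     config = cfg[!vapply(cfg, is.null, logical(1))],
                     input_md5 = checksums),
                extra)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
}

#' Run the methylation differential screen end to end
#'
#' Computes SIMPO scores, runs the gene-level t-test screen and the
#' probe-level DMP scan, collapses significant probes to genes, and
#' intersects the two gene lists. All intermediate tables, the final
#' intersection and a run manifest (config echo, package version, input
#' checksums, stage counts) are written under `cfg$out_dir`.
#'
#' @param cfg a [run_config()] with the methylation inputs set, or a list
#'   with in-memory `beta`, `annotation`, `groups` elements in place of the
#'   file paths.
#' @return (invisibly) list with `scores`, `simpo_diff`, `dmp`, `simpo_genes`,
#'   `dmp_genes`, `intersection`.
#' @export
run_methylation_pipeline <- function(cfg) {
  beta <- if (!is.null(cfg$beta_file)) read_beta_matrix(cfg$beta_file)
          else cfg$beta
  annot <- if (!is.null(cfg$annotation_file))
             read_annotation(cfg$annotation_file) else cfg$annotation
  groups <- if (!is.null(cfg$groups_file)) read_groups(cfg$groups_file)
            else cfg$groups
  if (is.null(beta) || is.null(annot) || is.null(groups))
    stop("beta, annotation and groups inputs are all required", call. = FALSE)
  grp <- as_group_factor(groups)
  if (!setequal(colnames(beta), names(grp)))
    stop("sample sets differ between the beta matrix and the group file",
         call. = FALSE)
  alpha <- if (is.null(cfg$alpha)) 0.05 else cfg$alpha
  q_thr <- if (is.null(cfg$q_threshold)) 0.001 else cfg$q_threshold
  out_dir <- if (is.null(cfg$out_dir)) NULL else cfg$out_dir

  scores <- compute_simpo_scores(beta, annot)
  simpo_diff <- diff_methylation_simpo(scores, groups, alpha = alpha)
  simpo_genes <- sort(simpo_diff$gene[simpo_diff$significant])
  dmp <- dmp_scan(beta, groups, q_threshold = q_thr)
  dmp_genes <- annotate_and_collapse(dmp[dmp$significant, , drop = FALSE],
                                     annot)
  inter <- intersect_gene_lists(simpo_genes, dmp_genes)
  if (!length(inter))
    warning("empty intersection of the two differential gene lists",
            call. = FALSE)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(data.frame(gene = rownames(scores$scores), scores$scores,
                         check.names = FALSE),
              file.path(out_dir, "simpo_scores.tsv"))
    write_tsv(simpo_diff, file.path(out_dir, "simpo_diff.tsv"))
    write_tsv(dmp, file.path(out_dir, "dmp_results.tsv"))
    writeLines(dmp_genes, file.path(out_dir, "dmp_genes.txt"))
    writeLines(simpo_genes, file.path(out_dir, "simpo_genes.txt"))
    writeLines(inter, file.path(out_dir, "intersection.txt"))
    if (inherits(cfg, "run_config"))
      write_manifest(cfg, out_dir,
                     list(counts = list(
                       genes_scored = nrow(scores$scores),
                       simpo_significant = length(simpo_genes),
                       dmp_significant = sum(dmp$significant),
                       dmp_genes = length(dmp_genes),
                       intersection = length(inter))))
  }
  invisible(list(scores = scores, simpo_diff = simpo_diff, dmp = dmp,
                 simpo_genes = simpo_genes, dmp_genes = dmp_genes,
                 intersection = inter))
}

mr_diagnostics_df <- function(res) {
  rbind(
    if (!is.null(res$heterogeneity))
      data.frame(diagnostic = "cochran_q", value = res$heterogeneity$q_stat,
                 df = res$heterogeneity$df,
                 p_value = res$heterogeneity$p_value,
                 stringsAsFactors = FALSE),
    if (!is.null(res$pleiotropy))
      data.frame(diagnostic = "egger_intercept",
                 value = res$pleiotropy$intercept, df = NA_integer_,
                 p_value = res$pleiotropy$p_value,
                 stringsAsFactors = FALSE))
}

write_mr_outputs <- function(res, out_dir, prefix = "") {
  write_tsv(res$estimates, file.path(out_dir,
                                     paste0(prefix, "estimates.tsv")))
  diag <- mr_diagnostics_df(res)
  if (!is.null(diag))
    write_tsv(diag, file.path(out_dir, paste0(prefix, "diagnostics.tsv")))
  if (!is.null(res$loo))
    write_tsv(res$loo, file.path(out_dir, paste0(prefix, "loo.tsv")))
  write_tsv(res$pairs[, c("snp", "beta_exp", "se_exp", "beta_out",
                          "se_out")],
            file.path(out_dir, paste0(prefix, "scatter.tsv")))
}

#' Run the Mendelian randomization pipeline end to end
#'
#' In pair mode (no mediator input) runs the full MR suite on the
#' exposure/outcome tables; with a mediator it runs the two-step mediation
#' analysis. Estimate tables (method, n_snps, beta, se, p, OR, CI),
#' diagnostics, leave-one-out results, scatter-plot data and a manifest are
#' written under `cfg$out_dir`.
#'
#' @param cfg a [run_config()] with GWAS inputs set, or a list with
#'   in-memory `exposure`, `mediator`, `outcome` data.frames.
#' @return (invisibly) the `mr_analysis` or `two_step_mr` object.
#' @export
run_mr_pipeline <- function(cfg) {
  exposure <- if (!is.null(cfg$exposure_file))
                read_gwas_table(cfg$exposure_file) else cfg$exposure
  outcome <- if (!is.null(cfg$outcome_file))
               read_gwas_table(cfg$outcome_file) else cfg$outcome
  mediator <- if (!is.null(cfg$mediator_file))
                read_gwas_table(cfg$mediator_file) else cfg$mediator
  if (is.null(exposure) || is.null(outcome))
    stop("exposure and outcome inputs are required", call. = FALSE)
  thr <- if (is.null(cfg$instrument_p)) 5e-8 else cfg$instrument_p
  methods <- if (is.null(cfg$methods))
               c("ivw", "weighted_median", "egger") else cfg$methods
  ivw_model <- if (is.null(cfg$ivw_model)) "multiplicative_random"
               else cfg$ivw_model
  n_boot <- if (is.null(cfg$n_boot)) 1000 else cfg$n_boot
  seed <- if (is.null(cfg$seed)) 1L else cfg$seed
  out_dir <- cfg$out_dir

  res <- if (is.null(mediator)) {
    run_mr(exposure, outcome, threshold = thr, methods = methods,
           ivw_model = ivw_model, n_boot = n_boot, seed = seed)
  } else {
    run_two_step(exposure, mediator, outcome, threshold = thr,
                 methods = methods, ivw_model = ivw_model,
                 n_boot = n_boot, seed = seed)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (inherits(res, "two_step_mr")) {
      write_mr_outputs(res$step1, out_dir, "step1_")
      write_mr_outputs(res$step2, out_dir, "step2_")
      write_tsv(data.frame(mediated_effect = res$mediated_effect,
                           mediated_se = res$mediated_se),
                file.path(out_dir, "mediated_effect.tsv"))
    } else {
      write_mr_outputs(res, out_dir)
    }
    if (inherits(cfg, "run_config"))
      write_manifest(cfg, out_dir)
  }
  invisible(res)
}
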