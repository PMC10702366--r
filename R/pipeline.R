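# Pipeline orchestration: simulate -> process -> differential -> score ->
# enrich as one configured, logged, seed-stamped run producing the analysis
# tables (differential/volcano, site-kinase predictions, kinase enrichment
# scatter, pLogo motif statistics) plus a machine-readable run report.

#' Configuration for a pipeline run
#'
#' In `"simulate"` mode all inputs are generated from `sim` (a
#' [sim_config()]) and a synthetic library of `n_kinases`; in `"real"` mode
#' the delimited-text inputs are read from the given paths.
#'
#' @param mode `"simulate"` or `"real"`.
#' @param sim A [sim_config()] (simulate mode).
#' @param n_kinases,sharpness Synthetic library size / peakedness (simulate
#'   mode).
#' @param quant_path,design_path,pssm_path,impurity_path,protein_path Input
#'   files (real mode; `protein_path` optional enables phospho-to-protein
#'   normalization).
#' @param sites_path Site table with `site`, `protein`, `position`, `flank`,
#'   `n_phospho` columns (real mode).
#' @param contrast List with `numerator` and `denominator`, each a list of
#'   `genotype`/`treatment`/`group` selectors for [select_channels()].
#'   Default: TBK1-null versus WT within the untreated arm.
#' @param policy A [filter_policy()].
#' @param k Top-k predicted-kinase cutoff (default 15).
#' @param percentile_min Putative-substrate percentile cutoff (default 95).
#' @param alpha Enrichment significance level (default 0.1).
#' @param fc_min,reg_fdr_max,unreg_fc_max,unreg_fdr_min Classification
#'   thresholds (see [classify_sites()]).
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param seed Root seed (simulate mode; stamped into the report).
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "real"),
                       sim = sim_config(),
                       n_kinases = 50L, sharpness = 5,
                       quant_path = NULL, design_path = NULL,
                       pssm_path = NULL, impurity_path = NULL,
                       protein_path = NULL, sites_path = NULL,
                       contrast = list(
                         numerator = list(genotype = "KO",
                                          treatment = "untreated"),
                         denominator = list(genotype = "WT",
                                            treatment = "untreated")),
                       policy = filter_policy("phospho"),
                       k = 15L, percentile_min = 95, alpha = 0.1,
                       fc_min = 1, reg_fdr_max = 0.1,
                       unreg_fc_max = 1, unreg_fdr_min = 0.1,
                       out_dir = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "real") {
    paths <- c(quant_path, design_path, pssm_path, sites_path)
    if (length(paths) < 4L)
      stop_invalid("real mode needs quant, design, PSSM and site tables")
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop_invalid("input file(s) not found: %s", paste(missing, collapse = ", "))
  }
  if (alpha <= 0 || alpha >= 1) stop_invalid("alpha must be in (0, 1)")
  structure(as.list(environment()), class = "run_config")
}

#' Validate pipeline input files without mutating anything
#'
#' Checks schemas, channel-set consistency between quant table and design,
#' and site-id uniqueness; returns all diagnostics found (empty character
#' vector when clean).
#'
#' @param quant_path,design_path,pssm_path Paths to the delimited inputs.
#' @return Character vector of diagnostics.
#' @export
validate_inputs <- function(quant_path = NULL, design_path = NULL,
                            pssm_path = NULL) {
  diags <- character(0)
  note <- function(fmt, ...) diags <<- c(diags, sprintf(fmt, ...))
  quant <- NULL
  if (!is.null(quant_path)) {
    quant <- tryCatch(read_quant_table(quant_path),
                      error = function(e) { note("%s", conditionMessage(e)); NULL })
  }
  if (!is.null(design_path)) {
    design <- tryCatch(read_design(design_path),
                       error = function(e) { note("%s", conditionMessage(e)); NULL })
    if (!is.null(design) && !is.null(quant)) {
      extra <- setdiff(design$channel, colnames(quant))
      if (length(extra))
        note("design channel(s) absent from quant table: %s",
             paste(extra, collapse = ", "))
    }
  }
  if (!is.null(pssm_path)) {
    tryCatch(read_pssm_library(pssm_path),
             error = function(e) note("%s", conditionMessage(e)))
  }
  diags
}

#' Run the full kinase-inference pipeline
#'
#' Stages: (simulate or load inputs) -> PSM simulation, impurity correction
#' and quality filtering -> site quantification -> equal-loading
#' normalization (and phospho-to-protein normalization when a protein table
#' is supplied) -> log2 + median centering -> per-site Welch contrast, BH
#' FDR and regulated/unregulated classification -> PSSM scoring,
#' percentiles and top-k predicted kinases on deduplicated singly
#' phosphorylated sites -> per-kinase Fisher/BH enrichment with dual-side
#' exclusion -> pLogo motif statistics (foreground = selected-side regulated
#' flanks, background = unregulated flanks). Identical config and seed give
#' identical outputs.
#'
#' @param config A [run_config()].
#' @return List with all stage outputs (`sites`, `quant`, `differential`,
#'   `volcano`, `scores`, `percentiles`, `predicted`, `enrichment`,
#'   `scatter`, `motif_stats`, `truth` in simulate mode) and `report`
#'   (named stage counts). Tables are also written under `config$out_dir`
#'   when set.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  report <- list(mode = config$mode,
                 version = as.character(utils::packageVersion("phosmotif")))
  truth <- NULL
  if (config$mode == "simulate") {
    sim <- config$sim
    if (!is.null(config$seed)) sim$seed <- as.integer(config$seed)
    library <- make_library(config$n_kinases, config$sharpness, seed = sim$seed)
    if (is.null(sim$target_kinase) || isTRUE(is.na(sim$target_kinase))) {
      # keep target unset for null simulations
    } else if (!sim$target_kinase %in% library$kinases) {
      stop_invalid("target_kinase '%s' not in simulated library", sim$target_kinase)
    }
    sites <- make_sites(sim$n_sites, library, sim$motif_fraction, seed = sim$seed)
    sq <- simulate_quant(sites, sim)
    truth <- sq$truth
    impurity <- default_impurity(sim$n_channels)
    records <- simulate_psm_table(sq$quant, impurity, sim$artifact_rates,
                                  seed = sim$seed, sites = sites)
    design <- design_from_config(sim)
    report$seed <- sim$seed
    protein_tab <- NULL
  } else {
    quant0 <- read_quant_table(config$quant_path)
    design <- read_design(config$design_path)
    library <- read_pssm_library(config$pssm_path)
    sites <- utils::read.delim(config$sites_path, stringsAsFactors = FALSE)
    if (anyDuplicated(sites$site))
      stop_invalid("duplicate site id(s) in site table")
    extra <- setdiff(design$channel, colnames(quant0))
    if (length(extra))
      stop_invalid("design channel(s) absent from quant table: %s",
                   paste(extra, collapse = ", "))
    impurity <- if (!is.null(config$impurity_path))
      read_impurity(config$impurity_path) else NULL
    protein_tab <- if (!is.null(config$protein_path))
      read_quant_table(config$protein_path) else NULL
    records <- NULL
    report$seed <- config$seed
  }

  ch_cols <- NULL
  if (!is.null(records)) {
    ch_cols <- grep("^ch\\d+$", names(records), value = TRUE)
    rec_mat <- as.matrix(records[, ch_cols, drop = FALSE])
    rec_mat <- correct_impurities(rec_mat, impurity)
    records[, ch_cols] <- rec_mat
    records$summed_sn <- rowSums(rec_mat, na.rm = TRUE)
    flt <- filter_records(records, config$policy)
    report$records_in <- nrow(records)
    report$records_kept <- nrow(flt$kept)
    report$rejected_by_reason <- flt$counts
    kept <- flt$kept
    quant0 <- as.matrix(kept[, ch_cols, drop = FALSE])
    rownames(quant0) <- kept$site
    sites <- sites[sites$site %in% kept$site, , drop = FALSE]
  } else if (config$mode == "real" && !is.null(impurity)) {
    quant0 <- correct_impurities(quant0, impurity)
  }
  sites <- sites[sites$site %in% rownames(quant0), , drop = FALSE]
  quant0 <- quant0[sites$site, , drop = FALSE]

  quant <- normalize_equal_loading(quant0)
  if (!is.null(protein_tab)) {
    protein_tab <- normalize_equal_loading(protein_tab)
    quant <- normalize_phospho_to_protein(quant, protein_tab,
                                          proteins = sites$protein)
    report$sites_without_protein <- length(attr(quant, "unmatched"))
  }
  logq <- median_center(log2_transform(quant))

  num <- do.call(select_channels, c(list(design), config$contrast$numerator))
  den <- do.call(select_channels, c(list(design), config$contrast$denominator))
  diff <- contrast_stats(logq, num, den, input = "log2",
                         flanks = stats::setNames(sites$flank, sites$site))
  diff <- adjust_fdr(diff)
  diff <- classify_sites(diff, fc_min = config$fc_min,
                         reg_fdr_max = config$reg_fdr_max,
                         unreg_fc_max = config$unreg_fc_max,
                         unreg_fdr_min = config$unreg_fdr_min)
  volc <- volcano_table(diff)
  report$sites_tested <- nrow(diff)
  report$sites_skipped <- nrow(attr(diff, "skipped"))
  report$strata <- table(diff$regulation)

  scored_sites <- dedup_sites(sites)
  scored_sites <- scored_sites[scored_sites$site %in% diff$site, , drop = FALSE]
  flanks <- stats::setNames(scored_sites$flank, scored_sites$site)
  scores <- score_sites(library, flanks)
  percentiles <- score_percentiles(scores, library)
  k <- min(config$k, length(library$kinases))  # small libraries cap top-k
  predicted <- predict_kinases(percentiles, scores, k = k)
  report$sites_scored <- nrow(scores)

  enr <- kinase_enrichment(predicted, diff)
  enr <- finalize_enrichment(enr, alpha = config$alpha)
  scatter <- attr(enr, "scatter")
  report$kinases_tested <- nrow(enr)
  report$kinases_excluded <- sum(enr$excluded)
  report$kinases_significant <- sum(!enr$excluded & enr$final_q <= config$alpha)

  reg_map <- stats::setNames(diff$regulation, diff$site)
  fg_side <- if (any(reg_map[names(flanks)] == "up", na.rm = TRUE) &&
                 sum(reg_map[names(flanks)] == "down", na.rm = TRUE) == 0)
    "up" else "down"
  fg <- flanks[!is.na(reg_map[names(flanks)]) & reg_map[names(flanks)] == fg_side]
  bg <- flanks[!is.na(reg_map[names(flanks)]) &
                 reg_map[names(flanks)] == "unregulated"]
  motif <- if (length(fg) && length(bg)) plogo_stats(fg, bg) else NULL
  report$plogo_foreground <- length(fg)
  report$plogo_background <- length(bg)

  out <- list(sites = sites, quant = quant, log2_table = logq,
              differential = diff, volcano = volc, scores = scores,
              percentiles = percentiles, predicted = predicted,
              enrichment = enr, scatter = scatter, motif_stats = motif,
              truth = truth, design = design, library = library,
              report = report)
  if (!is.null(config$out_dir)) write_outputs(out, config$out_dir)
  out
}

write_outputs <- function(out, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  w(out$differential, "differential.tsv")
  w(out$volcano, "volcano.tsv")
  w(out$enrichment[, setdiff(names(out$enrichment), "neg_log10_q")],
    "enrichment.tsv")
  w(out$scatter, "enrichment_scatter.tsv")
  if (!is.null(out$motif_stats)) w(out$motif_stats, "motif_stats.tsv")
  pred_long <- data.frame(
    site = rep(rownames(out$predicted), times = ncol(out$predicted)),
    kinase = rep(colnames(out$predicted), each = nrow(out$predicted)),
    predicted = as.vector(out$predicted))
  w(pred_long[pred_long$predicted, c("site", "kinase")], "predicted_kinases.tsv")
  if (!is.null(out$truth))
    write_ground_truth(out$truth, file.path(dir, "ground_truth.tsv"))
  rep_lines <- unlist(lapply(names(out$report), function(k) {
    v <- out$report[[k]]
    if (length(v) > 1L)
      paste0(k, ".", names(v), "\t", as.vector(v))
    else paste0(k, "\t", v)
  }))
  writeLines(rep_lines, file.path(dir, "run_report.tsv"))
  invisible(dir)
}
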