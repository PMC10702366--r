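# Per-site contrasts between sample groups: Welch t statistics on log2
# abundances, Benjamini-Hochberg FDR, and classification into the
# regulated / unregulated strata used by the motif-enrichment stage.

#' Select channels from a design table
#'
#' @param design data.frame with columns `channel`, `genotype`, `treatment`
#'   (see [design_from_config()]).
#' @param genotype,treatment,group Optional values to match; `NULL` matches
#'   everything.
#' @return Character vector of channel ids.
#' @export
select_channels <- function(design, genotype = NULL, treatment = NULL,
                            group = NULL) {
  keep <- rep(TRUE, nrow(design))
  if (!is.null(genotype)) keep <- keep & design$genotype %in% genotype
  if (!is.null(treatment)) keep <- keep & design$treatment %in% treatment
  if (!is.null(group)) keep <- keep & design$group %in% group
  design$channel[keep]
}

#' Per-site contrast statistics between two channel groups
#'
#' For each site, the log2 fold change is the difference of mean log2
#' abundances (numerator minus denominator), and the P value comes from a
#' two-sample unequal-variance (Welch) t test on the log2 values. Sites with
#' fewer than two non-missing values on either side are skipped and reported
#' with a reason. Zero-variance sites with unequal means get the smallest
#' representable positive P and are flagged in the `degenerate` column;
#' zero-variance sites with equal means get P = 1.
#'
#' @param table Sites x channels matrix.
#' @param numerator,denominator Disjoint, non-empty character vectors of
#'   channel ids (each with >= 2 channels).
#' @param input `"linear"` (values are log2-transformed internally) or
#'   `"log2"`.
#' @param flanks Optional named character vector of flanking sequences to
#'   carry into the output.
#' @return data.frame with columns `site`, `flank`, `log2fc`, `t`, `df`,
#'   `p_value`, `degenerate`; attribute `skipped` lists skipped sites.
#' @export
contrast_stats <- function(table, numerator, denominator,
                           input = c("linear", "log2"), flanks = NULL) {
  input <- match.arg(input)
  if (!length(numerator) || !length(denominator))
    stop_invalid("contrast sides must be non-empty")
  if (length(intersect(numerator, denominator)))
    stop_invalid("contrast sides must be disjoint")
  missing_ch <- setdiff(c(numerator, denominator), colnames(table))
  if (length(missing_ch))
    stop_invalid("channel(s) not in table: %s", paste(missing_ch, collapse = ", "))
  x <- if (input == "linear") log2_transform(table) else table
  a <- x[, numerator, drop = FALSE]
  b <- x[, denominator, drop = FALSE]
  n1 <- rowSums(!is.na(a)); n2 <- rowSums(!is.na(b))
  ok <- n1 >= 2L & n2 >= 2L
  m1 <- rowMeans(a, na.rm = TRUE); m2 <- rowMeans(b, na.rm = TRUE)
  v1 <- row_vars(a); v2 <- row_vars(b)
  se2 <- v1 / n1 + v2 / n2
  log2fc <- m1 - m2
  tstat <- log2fc / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- ok & !is.na(se2) & se2 == 0
  zero_eq <- degenerate & log2fc == 0
  zero_ne <- degenerate & log2fc != 0
  p[zero_eq] <- 1; tstat[zero_eq] <- 0
  p[zero_ne] <- .Machine$double.xmin
  tstat[zero_ne] <- sign(log2fc[zero_ne]) * Inf
  res <- data.frame(site = rownames(table),
                    flank = if (is.null(flanks)) NA_character_ else
                      unname(flanks[rownames(table)]),
                    log2fc = log2fc, t = tstat, df = df, p_value = p,
                    degenerate = degenerate,
                    stringsAsFactors = FALSE, row.names = NULL)
  skipped <- data.frame(site = res$site[!ok],
                        reason = sprintf(
                          "fewer than 2 observations per side (%d vs %d)",
                          n1[!ok], n2[!ok]),
                        stringsAsFactors = FALSE)
  res <- res[ok, , drop = FALSE]
  attr(res, "skipped") <- skipped
  res
}

#' Benjamini-Hochberg FDR adjustment of per-site P values
#'
#' Step-up adjusted values, monotone in P and capped at 1, applied per
#' contrast across all tested sites.
#'
#' @param records data.frame from [contrast_stats()] (needs `p_value`).
#' @return The records with an `fdr` column appended.
#' @export
adjust_fdr <- function(records) {
  p <- records$p_value
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_invalid("p values must lie in [0, 1]")
  records$fdr <- stats::p.adjust(p, method = "BH")
  records
}

#' Classify sites into regulation classes and significance tiers
#'
#' Regulation strata follow the printed inequalities exactly:
#' down / up require |log2FC| >= `fc_min` and FDR <= `reg_fdr_max`;
#' unregulated requires |log2FC| < `unreg_fc_max` and FDR > `unreg_fdr_min`;
#' everything else is `intermediate` (member of neither enrichment stratum).
#' Tiers mark strongly changed sites: tier 1 = |log2FC| >= 1 and
#' P < `tier1_p` (0.01); tier 2 = |log2FC| >= 1 and P < `tier2_p` (0.05),
#' exclusive of tier 1.
#'
#' @param records data.frame with `log2fc`, `p_value`, `fdr`.
#' @param fc_min,reg_fdr_max Thresholds for the regulated strata.
#' @param unreg_fc_max,unreg_fdr_min Thresholds for the unregulated stratum.
#' @param tier1_p,tier2_p Raw-P cutoffs for the tiers.
#' @return The records with `regulation` and `tier` columns appended.
#' @export
classify_sites <- function(records, fc_min = 1, reg_fdr_max = 0.1,
                           unreg_fc_max = 1, unreg_fdr_min = 0.1,
                           tier1_p = 0.01, tier2_p = 0.05) {
  if (is.null(records$fdr)) stop_invalid("run adjust_fdr() first")
  fc <- records$log2fc; fdr <- records$fdr; p <- records$p_value
  regulation <- rep("intermediate", nrow(records))
  regulation[fc <= -fc_min & fdr <= reg_fdr_max] <- "down"
  regulation[fc >= fc_min & fdr <= reg_fdr_max] <- "up"
  regulation[abs(fc) < unreg_fc_max & fdr > unreg_fdr_min] <- "unregulated"
  tier <- rep("none", nrow(records))
  tier[abs(fc) >= fc_min & p < tier2_p] <- "tier2"
  tier[abs(fc) >= fc_min & p < tier1_p] <- "tier1"
  records$regulation <- regulation
  records$tier <- tier
  records
}

#' Volcano-plot table (-log10 P versus log2 fold change)
#'
#' @param records Classified differential records.
#' @return data.frame with `site`, `log2fc`, `neg_log10_p`, `regulation`,
#'   `tier`.
#' @export
volcano_table <- function(records) {
  data.frame(site = records$site,
             log2fc = records$log2fc,
             neg_log10_p = -log10(pmax(records$p_value, .Machine$double.xmin)),
             regulation = records$regulation %||% NA_character_,
             tier = records$tier %||% NA_character_,
             stringsAsFactors = FALSE)
}
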