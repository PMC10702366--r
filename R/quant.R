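# Reporter-level quantification cascade: isotopic impurity correction,
# PSM quality filtering, protein collapse, equal-loading normalization,
# phospho-to-protein normalization, and median centering.

#' Correct reporter intensities for reagent isotopic impurities
#'
#' TMTpro reagents leak a known fraction of their signal into neighbouring
#' channels. Given the mixing matrix M (column j = distribution of reagent
#' j's signal across observed channels), the observed vector is `M %*% x`;
#' this solves the full linear system for the true signal `x`. Small negative
#' solutions from numerical noise (above `-tol` relative to the largest
#' entry) are clamped to zero.
#'
#' @param raw Observed channel vector, or a records x channels matrix
#'   (corrected row-wise). Entries must be nonnegative; NA passes through.
#' @param impurity Square mixing matrix with positive diagonal.
#' @param tol Clamping tolerance for small negative solutions.
#' @return Corrected vector or matrix of the same shape.
#' @export
correct_impurities <- function(raw, impurity, tol = 1e-8) {
  if (is.matrix(raw)) {
    if (ncol(raw) != nrow(impurity))
      stop_invalid("raw has %d channels but impurity is %d x %d",
                   ncol(raw), nrow(impurity), ncol(impurity))
    out <- raw
    filled <- !is.na(raw)
    tmp <- raw
    tmp[!filled] <- 0
    sol <- tryCatch(t(solve(impurity, t(tmp))),
                    error = function(e)
                      stop_invalid("impurity matrix is singular: %s",
                                   conditionMessage(e)))
    scale <- pmax(apply(abs(sol), 1L, max), 1)
    sol[sol < 0 & sol > -tol * scale] <- 0
    out[filled] <- sol[filled]
    return(out)
  }
  if (length(raw) != nrow(impurity))
    stop_invalid("raw length %d does not match impurity dimension %d",
                 length(raw), nrow(impurity))
  if (any(raw < 0, na.rm = TRUE))
    stop_invalid("raw intensities must be nonnegative")
  x <- raw
  x[is.na(x)] <- 0
  sol <- tryCatch(as.vector(solve(impurity, x)),
                  error = function(e)
                    stop_invalid("impurity matrix is singular: %s",
                                 conditionMessage(e)))
  scale <- max(abs(sol), 1)
  sol[sol < 0 & sol > -tol * scale] <- 0
  sol[is.na(raw)] <- NA_real_
  sol
}

#' Quality-filter policy for reporter records
#'
#' Defaults follow the exclusion rules used for TMTpro quantification:
#' phosphoproteome records are excluded when 12 or more of the 16 reporter
#' channels are missing, isolation specificity is < 0.8, summed
#' signal-to-noise is < 160, or the site-localization score (AScore) is
#' below 13 (the 95%-confidence threshold). The total-proteome policy
#' relaxes isolation specificity to 0.7, rejects at >= 8 missing channels,
#' and applies no localization filter.
#'
#' @param type `"phospho"` or `"proteome"`.
#' @param min_isolation_specificity,min_summed_sn,max_missing_channels,min_localization_score
#'   Override individual thresholds. `max_missing_channels` is the largest
#'   missing count still kept. `min_localization_score = NA` disables the
#'   localization filter.
#' @param require_single_phospho Reject multiply phosphorylated records
#'   (used upstream of kinase scoring).
#' @return A list of class `filter_policy`.
#' @export
filter_policy <- function(type = c("phospho", "proteome"),
                          min_isolation_specificity = NULL,
                          min_summed_sn = NULL,
                          max_missing_channels = NULL,
                          min_localization_score = NULL,
                          require_single_phospho = FALSE) {
  type <- match.arg(type)
  def <- if (type == "phospho")
    list(min_isolation_specificity = 0.8, min_summed_sn = 160,
         max_missing_channels = 11L, min_localization_score = 13)
  else
    list(min_isolation_specificity = 0.7, min_summed_sn = 160,
         max_missing_channels = 7L, min_localization_score = NA_real_)
  p <- list(
    type = type,
    min_isolation_specificity = min_isolation_specificity %||%
      def$min_isolation_specificity,
    min_summed_sn = min_summed_sn %||% def$min_summed_sn,
    max_missing_channels = max_missing_channels %||% def$max_missing_channels,
    min_localization_score = min_localization_score %||%
      def$min_localization_score,
    require_single_phospho = isTRUE(require_single_phospho))
  if (p$min_isolation_specificity < 0 || p$min_isolation_specificity > 1)
    stop_invalid("min_isolation_specificity must be in [0, 1]")
  structure(p, class = "filter_policy")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

FILTER_REASONS <- c("missing_channels", "isolation_specificity", "summed_sn",
                    "localization", "no_quant")

#' Partition reporter records into kept and rejected sets
#'
#' Records failing any threshold are rejected and tagged with the first
#' failing reason in the fixed order: `missing_channels`,
#' `isolation_specificity`, `summed_sn`, `localization`, `no_quant`
#' (all channels missing). Exclusion is strict exactly as the thresholds
#' read: a summed S/N of exactly 160 or a localization score of exactly 13
#' is kept.
#'
#' @param records data.frame of reporter records (see
#'   [simulate_psm_table()] for the column dictionary).
#' @param policy A [filter_policy()].
#' @return List with `kept` and `rejected` data.frames (`rejected` gains a
#'   `reason` column) and a `counts` summary per reason.
#' @export
filter_records <- function(records, policy = filter_policy("phospho")) {
  stopifnot(inherits(policy, "filter_policy"))
  n <- nrow(records)
  if (n == 0L)
    return(list(kept = records,
                rejected = cbind(records, reason = character(0)),
                counts = stats::setNames(integer(length(FILTER_REASONS)),
                                         FILTER_REASONS)))
  reason <- rep(NA_character_, n)
  fail <- records$n_missing_channels > policy$max_missing_channels
  reason[is.na(reason) & fail] <- "missing_channels"
  fail <- records$isolation_specificity < policy$min_isolation_specificity
  reason[is.na(reason) & fail] <- "isolation_specificity"
  fail <- records$summed_sn < policy$min_summed_sn
  reason[is.na(reason) & fail] <- "summed_sn"
  if (!is.na(policy$min_localization_score) &&
      "localization_score" %in% names(records)) {
    fail <- records$localization_score < policy$min_localization_score
    reason[is.na(reason) & fail] <- "localization"
  }
  ch <- grep("^ch\\d+$", names(records), value = TRUE)
  if (length(ch)) {
    fail <- rowSums(!is.na(records[, ch, drop = FALSE])) == 0L
    reason[is.na(reason) & fail] <- "no_quant"
  }
  if (policy$require_single_phospho && "n_phospho" %in% names(records)) {
    fail <- records$n_phospho != 1L
    reason[is.na(reason) & fail] <- "multi_phospho"
  }
  kept <- records[is.na(reason), , drop = FALSE]
  rejected <- records[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  counts <- table(factor(rejected$reason,
                         levels = c(FILTER_REASONS, "multi_phospho")))
  list(kept = kept, rejected = rejected,
       counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Collapse reporter records to a protein-level quantification table
#'
#' Each protein row is the element-wise sum of its records' channel
#' intensities (summed signal-to-noise quantification). Missing channels
#' contribute zero; a cell whose contributing records are all missing is NA.
#' Records without a protein assignment are skipped; their count is attached
#' as attribute `n_skipped`.
#'
#' @param records data.frame with a `protein` column and `ch*` channel
#'   columns.
#' @return Proteins x channels numeric matrix.
#' @export
collapse_to_protein <- function(records) {
  ch <- grep("^ch\\d+$", names(records), value = TRUE)
  if (!length(ch)) stop_invalid("records carry no channel columns")
  has_prot <- !is.na(records$protein) & nzchar(records$protein)
  n_skipped <- sum(!has_prot)
  if (n_skipped > 0L)
    warning(sprintf("%d record(s) without protein assignment skipped", n_skipped))
  rec <- records[has_prot, , drop = FALSE]
  m <- as.matrix(rec[, ch, drop = FALSE])
  filled <- !is.na(m)
  m[!filled] <- 0
  sums <- rowsum(m, rec$protein)
  n_obs <- rowsum(filled + 0, rec$protein)
  sums[n_obs == 0L] <- NA_real_
  attr(sums, "n_skipped") <- n_skipped
  sums
}

#' Normalize channels assuming equal protein loading
#'
#' Each channel (column) is summed across all rows and rescaled so that all
#' column sums equal the mean of the original column sums; the grand total is
#' unchanged and the operation is idempotent.
#'
#' @param table Rows x channels matrix of nonnegative abundances (NA =
#'   missing).
#' @return Rescaled matrix; attribute `scale_factors` records the per-channel
#'   factors.
#' @export
normalize_equal_loading <- function(table) {
  cs <- colSums(table, na.rm = TRUE)
  if (any(cs <= 0)) {
    bad <- colnames(table)[cs <= 0] %||% which(cs <= 0)
    stop_invalid("channel(s) with zero total signal: %s",
                 paste(bad, collapse = ", "))
  }
  f <- mean(cs) / cs
  out <- sweep(table, 2L, f, `*`)
  attr(out, "scale_factors") <- f
  out
}

#' Normalize phosphosite abundances to protein abundance
#'
#' Each phosphosite row whose protein was quantified is divided channel-wise
#' by the protein's relative profile (protein channel value / protein row
#' mean), removing protein-level abundance changes so that residual channel
#' differences reflect phosphorylation stoichiometry. Sites without a
#' quantified protein (or whose protein row mean is zero) pass through
#' unchanged and are flagged.
#'
#' @param phospho Sites x channels matrix.
#' @param protein Proteins x channels matrix (same channel set).
#' @param proteins Character vector mapping each phospho row to a protein id;
#'   defaults to stripping the `_S123`/`_T123` suffix from rownames.
#' @return Normalized matrix; attribute `unmatched` lists pass-through sites.
#' @export
normalize_phospho_to_protein <- function(phospho, protein, proteins = NULL) {
  if (!identical(colnames(phospho), colnames(protein)))
    stop_invalid("phospho and protein tables must share the same channel set")
  if (is.null(proteins))
    proteins <- sub("_[STY]\\d+$", "", rownames(phospho))
  stopifnot(length(proteins) == nrow(phospho))
  out <- phospho
  prot_mean <- rowMeans(protein, na.rm = TRUE)
  matched <- proteins %in% rownames(protein)
  matched[matched] <- prot_mean[proteins[matched]] > 0 &
    is.finite(prot_mean[proteins[matched]])
  if (any(matched)) {
    rel <- protein[proteins[matched], , drop = FALSE] / prot_mean[proteins[matched]]
    rel[is.na(rel)] <- 1  # protein channel missing: leave site value as-is
    out[matched, ] <- phospho[matched, , drop = FALSE] / rel
  }
  attr(out, "unmatched") <- rownames(phospho)[!matched]
  out
}

#' Median-center a log2 quantification table
#'
#' Subtracts each channel's median so that all column medians are exactly
#' zero. Operates on log2-scale data, after phospho-to-protein
#' normalization, as the dataset-level normalization step.
#'
#' @param table Rows x channels matrix on the log2 scale.
#' @return Centered matrix.
#' @export
median_center <- function(table) {
  if (any(colSums(!is.na(table)) == 0L))
    stop_invalid("channel(s) with no observed values cannot be centered")
  med <- apply(table, 2L, stats::median, na.rm = TRUE)
  sweep(table, 2L, med, `-`)
}

#' Log2-transform a linear-scale quantification table
#'
#' Nonpositive or missing entries become NA.
#' @param table Rows x channels matrix, linear scale.
#' @return log2 matrix.
#' @export
log2_transform <- function(table) {
  out <- table
  out[!is.na(out) & out <= 0] <- NA_real_
  log2(out)
}
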