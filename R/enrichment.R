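# Per-kinase enrichment of predicted substrates among regulated versus
# unregulated phosphosites: one-sided Fisher tests, BH adjustment within
# each side, dual-side exclusion, selection of the more significant side,
# and pLogo-style position-residue binomial statistics.

#' Build the 2x2 table for one kinase
#'
#' a = regulated sites with the kinase predicted, b = regulated without,
#' c = unregulated with, d = unregulated without.
#'
#' @param predicted_sites Site ids for which the kinase is a predicted
#'   (top-k) kinase.
#' @param regulated,unregulated Disjoint site-id sets defining the strata.
#' @return Named integer vector `c(a, b, c, d)`.
#' @export
build_table <- function(predicted_sites, regulated, unregulated) {
  if (length(intersect(regulated, unregulated)))
    stop_invalid("regulated and unregulated strata overlap")
  a <- sum(regulated %in% predicted_sites)
  cc <- sum(unregulated %in% predicted_sites)
  c(a = a, b = length(regulated) - a,
    c = cc, d = length(unregulated) - cc)
}

#' One-sided Fisher exact test for over-representation among regulated sites
#'
#' The P value is the hypergeometric upper tail P(X >= a) given the table
#' margins. Degenerate margins (an empty stratum or no predicted sites)
#' give P = 1 by convention.
#'
#' @param table Named vector `c(a, b, c, d)` of nonnegative integers.
#' @return P value in [0, 1].
#' @export
fisher_greater <- function(table) {
  a <- table[["a"]]; b <- table[["b"]]; cc <- table[["c"]]; d <- table[["d"]]
  if (any(c(a, b, cc, d) < 0)) stop_invalid("table counts must be nonnegative")
  if (a + b == 0L || a + cc == 0L) return(1)
  stats::phyper(a - 1, m = a + cc, n = b + d, k = a + b, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment of a p-value vector
#'
#' Shared with the differential stage; applied across kinases within each
#' enrichment side.
#'
#' @param pvals Numeric vector in [0, 1].
#' @return Adjusted q values.
#' @export
bh <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop_invalid("p values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Per-kinase motif enrichment across regulated strata
#'
#' For every kinase, compares the fraction of sites with that kinase among
#' its predicted (top-k) kinases between the downregulated (resp.
#' upregulated) stratum and the unregulated stratum, using a one-sided
#' Fisher test per side, BH-adjusted across kinases within each side.
#'
#' @param predicted Sites x kinases logical matrix from [predict_kinases()].
#' @param regulation Named character vector (by site id) with levels
#'   down/up/unregulated/intermediate, or a classified differential table.
#' @return data.frame with one row per kinase: down/up 2x2 counts, p and q
#'   per side.
#' @export
kinase_enrichment <- function(predicted, regulation) {
  if (is.data.frame(regulation))
    regulation <- stats::setNames(regulation$regulation, regulation$site)
  sites <- rownames(predicted)
  regulation <- regulation[sites]
  down <- sites[!is.na(regulation) & regulation == "down"]
  up <- sites[!is.na(regulation) & regulation == "up"]
  unreg <- sites[!is.na(regulation) & regulation == "unregulated"]
  kin <- colnames(predicted)
  rows <- lapply(kin, function(k) {
    pred_sites <- sites[predicted[, k]]
    td <- build_table(pred_sites, down, unreg)
    tu <- build_table(pred_sites, up, unreg)
    data.frame(kinase = k,
               down_a = td[["a"]], down_b = td[["b"]],
               down_c = td[["c"]], down_d = td[["d"]],
               up_a = tu[["a"]], up_b = tu[["b"]],
               up_c = tu[["c"]], up_d = tu[["d"]],
               p_down = fisher_greater(td), p_up = fisher_greater(tu),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_down <- bh(out$p_down)
  out$q_up <- bh(out$p_up)
  attr(out, "strata_sizes") <- c(down = length(down), up = length(up),
                                 unregulated = length(unreg),
                                 intermediate = sum(!is.na(regulation) &
                                                      regulation == "intermediate"))
  out
}

#' Finalize kinase enrichment: exclusion, side selection, scatter coordinates
#'
#' Kinases significant (q <= `alpha`) on both the up- and downregulated
#' sides are excluded from downstream analysis. For each remaining kinase
#' the more significant side is selected by adjusted P (tie resolves to
#' down, flagged deterministic); `final_q` is the selected side's q. The
#' scatter coordinate `log2_freq_ratio` is
#' log2[(a/(a+b)) / (c/(c+d))] for the selected side, with a 0.5 pseudocount
#' added to every cell when a zero cell would make it undefined.
#'
#' @param records Output of [kinase_enrichment()].
#' @param alpha Significance level for exclusion/significance (default 0.1).
#' @return The records with `excluded`, `side`, `final_q`,
#'   `log2_freq_ratio`, `neg_log10_q` appended; attribute `scatter` holds
#'   the non-excluded scatter table.
#' @export
finalize_enrichment <- function(records, alpha = 0.1) {
  excluded <- records$q_down <= alpha & records$q_up <= alpha
  side <- ifelse(records$q_down <= records$q_up, "down", "up")
  side[excluded] <- "none"
  final_q <- ifelse(excluded, NA_real_, pmin(records$q_down, records$q_up))
  ratio <- function(a, b, cc, d) {
    zero <- a == 0 | cc == 0
    a <- a + 0.5 * zero; b <- b + 0.5 * zero
    cc <- cc + 0.5 * zero; d <- d + 0.5 * zero
    log2((a / (a + b)) / (cc / (cc + d)))
  }
  lfr <- ifelse(side == "down",
                ratio(records$down_a, records$down_b, records$down_c,
                      records$down_d),
                ratio(records$up_a, records$up_b, records$up_c, records$up_d))
  lfr[excluded] <- NA_real_
  records$excluded <- excluded
  records$side <- side
  records$final_q <- final_q
  records$log2_freq_ratio <- lfr
  records$neg_log10_q <- -log10(pmax(final_q, .Machine$double.xmin))
  scatter <- records[!records$excluded,
                     c("kinase", "side", "log2_freq_ratio", "neg_log10_q",
                       "final_q")]
  attr(records, "scatter") <- scatter
  records
}

#' pLogo-style position-residue motif statistics
#'
#' For every flank position (-5..+5, centre excluded) and residue, tests the
#' foreground count k out of n against the background frequency p of that
#' residue at that position (with a 0.5 pseudocount per residue). The height
#' is the signed log odds of the binomial tail probability:
#' `-log10 P(Bin(n, p) >= k)` when the residue is over-represented
#' (k/n > p), else `+log10 P(Bin(n, p) <= k)` (negative for depletion).
#'
#' @param foreground,background Non-empty character vectors of 11-character
#'   flanks.
#' @return data.frame with `position`, `residue`, `k`, `n`, `p`, `height`.
#' @export
plogo_stats <- function(foreground, background) {
  if (!length(foreground)) stop_invalid("foreground flank set is empty")
  if (!length(background)) stop_invalid("background flank set is empty")
  fg <- encode_flanks(foreground)
  bg <- encode_flanks(background)
  n_res <- length(AA_ALPHABET)
  rows <- vector("list", 10L * n_res)
  i <- 0L
  for (pos_j in seq_len(10L)) {
    fg_col <- fg[, pos_j]
    bg_col <- bg[, pos_j]
    n <- sum(fg_col <= n_res)        # padding positions are not counted
    n_bg <- sum(bg_col <= n_res)
    for (r in seq_len(n_res)) {
      k <- sum(fg_col == r)
      p <- (sum(bg_col == r) + 0.5) / (n_bg + 0.5 * n_res)
      height <- if (n == 0L) 0 else if (k / n > p)
        -stats::pbinom(k - 1, n, p, lower.tail = FALSE, log.p = TRUE) / log(10)
      else
        stats::pbinom(k, n, p, log.p = TRUE) / log(10)
      i <- i + 1L
      rows[[i]] <- data.frame(position = FLANK_POSITIONS[pos_j],
                              residue = AA_ALPHABET[r],
                              k = k, n = n, p = p, height = height,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
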