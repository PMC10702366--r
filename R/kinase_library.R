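# PSSM scoring of phosphosite flanking sequences, score-to-percentile
# conversion, per-site kinase ranking, top-k predicted-kinase calls, and
# putative-substrate selection.

#' Extract the +/-5-residue flanking window around a phosphosite
#'
#' Returns the 11-character window centred on the phosphoacceptor, padding
#' out-of-range positions with `"_"`. Only serine/threonine centres are
#' scoreable (the motif library covers S/T kinases); any other central
#' residue is an error.
#'
#' @param sequence Protein sequence (residue string, any case).
#' @param position 1-based position of the phosphoacceptor.
#' @return An 11-character flank string, uppercase.
#' @export
extract_flank <- function(sequence, position) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (position < 1L || position > n)
    stop_invalid("position %d outside sequence of length %d", position, n)
  center <- substr(sequence, position, position)
  if (!center %in% c("S", "T"))
    stop_invalid("residue at position %d is '%s'; only S/T sites are scoreable",
                 position, center)
  idx <- (position - 5L):(position + 5L)
  chars <- rep(PAD_CHAR, FLANK_WIDTH)
  inside <- idx >= 1L & idx <= n
  chars[inside] <- substring(sequence, idx[inside], idx[inside])
  paste(chars, collapse = "")
}

# log2-odds matrix for one PSSM: 10 positions x 21 (20 residues + padding,
# which scores 0 so termini are neutral).
pssm_logodds <- function(pssm) {
  cbind(log2(pssm * 20), `_` = 0)
}

#' Score a flanking sequence against one kinase PSSM
#'
#' The raw score is the summed log2 odds, over the ten off-centre positions,
#' of the observed residue's PSSM probability against the uniform 1/20
#' background. Padding positions contribute zero; the central S/T does not
#' contribute (matrices are defined on flanking positions only).
#'
#' @param pssm 10 x 20 probability matrix (rows = positions -5..-1,+1..+5,
#'   columns = residues).
#' @param flank 11-character flank with S/T centre.
#' @return Raw log2-odds score.
#' @export
score_flank <- function(pssm, flank) {
  check_flank(flank)
  idx <- encode_flanks(flank)
  lo <- pssm_logodds(pssm)
  sum(lo[cbind(seq_len(10L), as.vector(idx))])
}

#' Score many flanks against every kinase in a library
#'
#' @param library A `kinase_library`.
#' @param flanks Character vector of 11-character flanks.
#' @return Sites x kinases matrix of raw scores (rownames from `names(flanks)`
#'   if set).
#' @export
score_sites <- function(library, flanks) {
  stopifnot(inherits(library, "kinase_library"))
  if (!length(library$kinases)) stop_invalid("kinase library is empty")
  idx <- encode_flanks(flanks)
  pos <- rep(seq_len(10L), each = nrow(idx))
  flat <- cbind(pos, as.vector(idx))
  scores <- vapply(library$pssms, function(p) {
    lo <- pssm_logodds(p)
    rowSums(matrix(lo[flat], nrow = nrow(idx)))
  }, numeric(nrow(idx)))
  scores <- matrix(scores, nrow = nrow(idx),
                   dimnames = list(names(flanks), library$kinases))
  scores
}

#' Percentile of a score within a background sample
#'
#' Defined as `100 * (number of background values <= score) / background
#' size`, i.e. the empirical CDF in percent.
#'
#' @param score Numeric scalar or vector.
#' @param background Non-empty numeric sample.
#' @return Percentile(s) in [0, 100].
#' @export
percentile_of <- function(score, background) {
  if (!length(background)) stop_invalid("background sample is empty")
  bg <- sort(background)
  100 * findInterval(score, bg) / length(bg)
}

#' Convert a score matrix to per-kinase percentiles
#'
#' By default each kinase's background is the empirical distribution of that
#' kinase's scores over all scored sites in the current dataset; a
#' library-supplied background sample (see [library_backgrounds()])
#' overrides it when present.
#'
#' @param scores Sites x kinases score matrix from [score_sites()].
#' @param library Optional `kinase_library` carrying `backgrounds`.
#' @return Sites x kinases percentile matrix in [0, 100].
#' @export
score_percentiles <- function(scores, library = NULL) {
  bgs <- if (!is.null(library)) library$backgrounds else NULL
  out <- scores
  for (j in seq_len(ncol(scores))) {
    bg <- bgs[[colnames(scores)[j]]] %||% scores[, j]
    out[, j] <- percentile_of(scores[, j], bg)
  }
  out
}

#' Attach empirical background score samples to a kinase library
#'
#' Scores the supplied reference flanks with every kinase and stores the
#' per-kinase score distributions as the library's percentile backgrounds.
#'
#' @param library A `kinase_library`.
#' @param flanks Reference flank set (e.g. all scoreable sites in a study).
#' @return The library with `backgrounds` set.
#' @export
library_backgrounds <- function(library, flanks) {
  sc <- score_sites(library, flanks)
  library$backgrounds <- lapply(seq_len(ncol(sc)), function(j) sc[, j])
  names(library$backgrounds) <- colnames(sc)
  library
}

#' Rank kinases for one site and call the predicted set
#'
#' Kinases are ranked by percentile descending, with raw score as the
#' secondary key and kinase id (ascending) as the final tie-break; the
#' predicted kinases are those with rank <= k (the top-15-of-303 rule by
#' default).
#'
#' @param flank 11-character flank.
#' @param library A `kinase_library` with background samples (see
#'   [library_backgrounds()]).
#' @param k Number of top-ranked kinases called as predicted.
#' @return List with `scores`, `percentiles`, `ranks` (named numeric /
#'   integer vectors over kinases) and `predicted` (kinase ids).
#' @export
rank_and_predict <- function(flank, library, k = 15L) {
  stopifnot(inherits(library, "kinase_library"))
  n_kin <- length(library$kinases)
  if (!n_kin) stop_invalid("kinase library is empty")
  if (k < 1L || k > n_kin)
    stop_invalid("k must be in 1..%d", n_kin)
  if (is.null(library$backgrounds))
    stop_invalid("library has no background samples; call library_backgrounds()")
  sc <- score_sites(library, stats::setNames(flank, "site"))[1L, ]
  pc <- vapply(library$kinases, function(kin)
    percentile_of(sc[[kin]], library$backgrounds[[kin]]), numeric(1))
  ord <- order(-pc, -sc, library$kinases)
  ranks <- integer(n_kin)
  ranks[ord] <- seq_len(n_kin)
  names(ranks) <- library$kinases
  list(scores = sc, percentiles = pc, ranks = ranks,
       predicted = library$kinases[ord[seq_len(k)]])
}

#' Top-k predicted kinases for every site
#'
#' Vectorized over sites: ranks each site's kinases by percentile (raw score
#' secondary, kinase id tie-break) and marks the top k as predicted.
#'
#' @param percentiles Sites x kinases percentile matrix.
#' @param scores Matching raw-score matrix (secondary key).
#' @param k Top-k cutoff (default 15).
#' @return Sites x kinases logical matrix of predicted calls.
#' @export
predict_kinases <- function(percentiles, scores, k = 15L) {
  n_kin <- ncol(percentiles)
  if (k < 1L || k > n_kin) stop_invalid("k must be in 1..%d", n_kin)
  id_rank <- seq_len(n_kin)  # columns already in kinase-id order
  pred <- matrix(FALSE, nrow(percentiles), n_kin,
                 dimnames = dimnames(percentiles))
  for (i in seq_len(nrow(percentiles))) {
    ord <- order(-percentiles[i, ], -scores[i, ], id_rank)
    pred[i, ord[seq_len(k)]] <- TRUE
  }
  pred
}

#' Putative substrates of a kinase (percentile rule)
#'
#' Sites whose score percentile for the kinase strictly exceeds
#' `percentile_min` (default the >95th-percentile rule).
#'
#' @param percentiles Sites x kinases percentile matrix.
#' @param kinase Kinase id.
#' @param percentile_min Strict lower bound in [0, 100].
#' @return Character vector of site ids.
#' @export
putative_substrates <- function(percentiles, kinase, percentile_min = 95) {
  if (!kinase %in% colnames(percentiles))
    stop_invalid("unknown kinase id '%s'", kinase)
  if (percentile_min < 0 || percentile_min > 100)
    stop_invalid("percentile_min must be in [0, 100]")
  rownames(percentiles)[percentiles[, kinase] > percentile_min]
}

#' Deduplicate sites for kinase scoring
#'
#' Kinase prediction operates on non-duplicate, singly phosphorylated sites:
#' duplicates by (protein, position) collapse to the first entry and
#' multiply phosphorylated records are dropped.
#'
#' @param sites Site table with `protein`, `position`, `n_phospho`.
#' @return Deduplicated site table.
#' @export
dedup_sites <- function(sites) {
  keep <- sites$n_phospho == 1L
  s <- sites[keep, , drop = FALSE]
  s[!duplicated(paste(s$protein, s$position)), , drop = FALSE]
}
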