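# Synthetic-data generators: PSSM libraries, phosphosite flanks, 16-plex
# reporter designs, quantification tables with a known spiked kinase effect,
# and PSM-level reporter records with injected quality defects. Every
# downstream stage of the pipeline is testable against the ground truth these
# emit, without any external download.

#' Simulation configuration for a TMTpro-style phosphoproteomics experiment
#'
#' Captures the study conditions the generator emulates: a 16-channel TMTpro
#' plex carrying {WT, TBK1-null} x {untreated, MRT67307} groups in
#' quadruplicate, ~10^3-10^4 phosphosites with +/-5-residue flanks, lognormal
#' reporter noise, and a spiked kinase whose motif-matched sites are shifted
#' in the affected (TBK1-null) groups.
#'
#' @param n_sites Number of phosphosites to simulate.
#' @param n_channels Number of reporter channels (default 16, one TMTpro plex).
#' @param groups Named list mapping group label to channel indices; the
#'   indices must partition `1:n_channels`. Default: four groups of four
#'   channels, `WT_untreated`, `WT_MRT`, `KO_untreated`, `KO_MRT`.
#' @param target_kinase Kinase id whose motif-derived sites receive the
#'   spiked effect, or `NULL` for a null simulation.
#' @param affected_groups Group labels whose channels receive the effect;
#'   default the two TBK1-null groups (genotype-driven shift).
#' @param effect_log2 Log2 shift applied to target-kinase sites in the
#'   affected groups (default -2, a fourfold decrease).
#' @param motif_fraction Fraction of sites drawn from a kinase motif rather
#'   than the uniform background, in [0, 1].
#' @param noise_sd Standard deviation of additive Gaussian noise on log2
#'   abundances (lognormal on the linear scale).
#' @param baseline_log2_mean,baseline_log2_sd Per-site baseline log2
#'   abundance distribution.
#' @param artifact_rates Named list of per-defect probabilities for PSM-level
#'   defects: `low_isolation`, `low_sn`, `missing_channels`,
#'   `low_localization`.
#' @param seed Integer root seed; sub-operations derive fixed streams from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 2000L,
                       n_channels = 16L,
                       groups = NULL,
                       target_kinase = NULL,
                       affected_groups = NULL,
                       effect_log2 = -2,
                       motif_fraction = 0.5,
                       noise_sd = 0.25,
                       baseline_log2_mean = 10,
                       baseline_log2_sd = 1.5,
                       artifact_rates = list(low_isolation = 0, low_sn = 0,
                                             missing_channels = 0,
                                             low_localization = 0),
                       seed = 1L) {
  if (n_sites < 1L) stop_invalid("n_sites must be positive")
  if (n_channels < 2L) stop_invalid("n_channels must be at least 2")
  if (motif_fraction < 0 || motif_fraction > 1)
    stop_invalid("motif_fraction must be in [0, 1]")
  if (noise_sd < 0) stop_invalid("noise_sd must be nonnegative")
  if (is.null(groups)) {
    if (n_channels %% 4L != 0L)
      stop_invalid("default group layout needs n_channels divisible by 4")
    per <- n_channels %/% 4L
    groups <- split(seq_len(n_channels),
                    rep(c("WT_untreated", "WT_MRT", "KO_untreated", "KO_MRT"),
                        each = per))
    groups <- groups[c("WT_untreated", "WT_MRT", "KO_untreated", "KO_MRT")]
  }
  idx <- sort(unlist(groups, use.names = FALSE))
  if (!identical(as.integer(idx), seq_len(n_channels)))
    stop_invalid("group channel indices must partition 1..n_channels")
  if (is.null(affected_groups)) {
    affected_groups <- intersect(c("KO_untreated", "KO_MRT"), names(groups))
  }
  if (!all(affected_groups %in% names(groups)))
    stop_invalid("affected group label(s) not in groups: %s",
                 paste(setdiff(affected_groups, names(groups)), collapse = ", "))
  structure(list(n_sites = as.integer(n_sites),
                 n_channels = as.integer(n_channels),
                 groups = groups,
                 target_kinase = target_kinase,
                 affected_groups = affected_groups,
                 effect_log2 = effect_log2,
                 motif_fraction = motif_fraction,
                 noise_sd = noise_sd,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 artifact_rates = artifact_rates,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic kinase PSSM library
#'
#' Each kinase gets a position-specific scoring matrix over the ten flank
#' positions (-5..-1, +1..+5) and the 20-residue alphabet. Position rows are
#' drawn from a symmetric Dirichlet whose concentration is `1/sharpness`, so
#' larger `sharpness` yields peakier (more informative) motifs; as
#' `sharpness` grows, each position concentrates nearly all probability on a
#' single residue.
#'
#' @param n_kinases Number of kinases (>= 1).
#' @param sharpness Positive real controlling motif peakedness.
#' @param seed Integer seed; output is byte-identical for identical seeds.
#' @return A `kinase_library`: list with `kinases` (ids) and `pssms` (named
#'   list of 10 x 20 probability matrices, rows summing to 1, all entries
#'   positive). Backgrounds are unset until [library_backgrounds()].
#' @export
make_library <- function(n_kinases, sharpness = 5, seed = 1L) {
  if (!is.numeric(n_kinases) || n_kinases < 1)
    stop_invalid("n_kinases must be a positive integer")
  if (!is.numeric(sharpness) || sharpness <= 0)
    stop_invalid("sharpness must be positive")
  n_kinases <- as.integer(n_kinases)
  set.seed(derive_seed(seed, 101L))
  kinases <- sprintf("KIN%03d", seq_len(n_kinases))
  shape <- 1 / sharpness
  pssms <- lapply(kinases, function(k) {
    # Gamma(a) = Gamma(a+1) * U^(1/a): sampling on the log scale stays exact
    # for tiny shapes (very sharp motifs), where rgamma itself underflows.
    lg <- log(stats::rgamma(10L * 20L, shape = shape + 1)) +
      log(stats::runif(10L * 20L)) / shape
    lg <- matrix(lg, nrow = 10L,
                 dimnames = list(as.character(FLANK_POSITIONS), AA_ALPHABET))
    g <- exp(lg - apply(lg, 1L, max))
    g <- pmax(g, 1e-12)  # keep every probability strictly positive
    g / rowSums(g)
  })
  names(pssms) <- kinases
  structure(list(kinases = kinases, pssms = pssms, backgrounds = NULL),
            class = "kinase_library")
}

#' @export
print.kinase_library <- function(x, ...) {
  cat(sprintf("kinase_library: %d kinases, positions %s..%s (center excluded)%s\n",
              length(x$kinases), FLANK_POSITIONS[1],
              FLANK_POSITIONS[length(FLANK_POSITIONS)],
              if (is.null(x$backgrounds)) "" else ", with background samples"))
  invisible(x)
}

#' Generate synthetic phosphosites with flanking sequences
#'
#' A fraction `motif_fraction` of sites draw each off-center flank residue
#' from a randomly chosen kinase's PSSM row (the generating kinase is
#' recorded); the remainder draw residues uniformly. Central residues are S
#' or T with equal probability.
#'
#' @param n_sites Number of sites.
#' @param library A `kinase_library` (may be empty only if
#'   `motif_fraction == 0`).
#' @param motif_fraction Fraction of motif-derived sites, in [0, 1].
#' @param seed Integer seed.
#' @return data.frame with columns `site`, `protein`, `position`, `center`,
#'   `flank`, `generating_kinase` (NA for background sites), `n_phospho`.
#' @export
make_sites <- function(n_sites, library, motif_fraction = 0.5, seed = 1L) {
  if (motif_fraction < 0 || motif_fraction > 1)
    stop_invalid("motif_fraction must be in [0, 1]")
  has_lib <- inherits(library, "kinase_library") && length(library$kinases) > 0
  if (!has_lib && motif_fraction > 0)
    stop_invalid("motif_fraction > 0 requires a nonempty kinase library")
  n_sites <- as.integer(n_sites)
  set.seed(derive_seed(seed, 102L))
  is_motif <- stats::runif(n_sites) < motif_fraction
  gen <- rep(NA_character_, n_sites)
  if (any(is_motif))
    gen[is_motif] <- sample(library$kinases, sum(is_motif), replace = TRUE)
  center <- sample(c("S", "T"), n_sites, replace = TRUE)
  flank_mat <- matrix(PAD_CHAR, nrow = n_sites, ncol = FLANK_WIDTH)
  flank_mat[, CENTER_IDX] <- center
  off_cols <- setdiff(seq_len(FLANK_WIDTH), CENTER_IDX)
  bg <- !is_motif
  if (any(bg)) {
    flank_mat[bg, off_cols] <- sample(AA_ALPHABET, sum(bg) * 10L, replace = TRUE)
  }
  if (any(is_motif)) {
    for (k in unique(gen[is_motif])) {
      rows <- which(!is.na(gen) & gen == k)
      pssm <- library$pssms[[k]]
      for (j in seq_along(off_cols)) {
        flank_mat[rows, off_cols[j]] <-
          sample(AA_ALPHABET, length(rows), replace = TRUE, prob = pssm[j, ])
      }
    }
  }
  protein <- sprintf("PROT%05d", seq_len(n_sites))
  position <- sample(6:500, n_sites, replace = TRUE)
  data.frame(site = sprintf("%s_%s%d", protein, center, position),
             protein = protein,
             position = position,
             center = center,
             flank = apply(flank_mat, 1L, paste, collapse = ""),
             generating_kinase = gen,
             n_phospho = 1L,
             stringsAsFactors = FALSE)
}

#' Simulate a reporter quantification table with a spiked kinase effect
#'
#' Log2 abundance = per-site baseline + group effect + Gaussian noise.
#' Sites generated by `config$target_kinase` have `config$effect_log2`
#' added in the channels of the affected groups; linear-scale values are
#' `2^log2` and therefore strictly positive.
#'
#' @param sites Site table from [make_sites()].
#' @param config A [sim_config()].
#' @return List with `quant` (sites x channels matrix, linear scale) and
#'   `truth` (list: `target_kinase`, `affected_sites`, `effects` named by
#'   site, `affected_channels`).
#' @export
simulate_quant <- function(sites, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(sites)
  set.seed(derive_seed(config$seed, 103L))
  channels <- sprintf("ch%02d", seq_len(config$n_channels))
  baseline <- stats::rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
  log2mat <- matrix(baseline, nrow = n, ncol = config$n_channels)
  affected_ch <- sort(unlist(config$groups[config$affected_groups],
                             use.names = FALSE))
  affected <- if (is.null(config$target_kinase)) rep(FALSE, n) else
    !is.na(sites$generating_kinase) &
      sites$generating_kinase == config$target_kinase
  if (!is.null(config$target_kinase) && config$effect_log2 != 0 &&
      !config$target_kinase %in% sites$generating_kinase)
    warning("target_kinase generated no sites; effect is vacuous")
  if (config$effect_log2 == 0) affected <- rep(FALSE, n)
  if (any(affected))
    log2mat[affected, affected_ch] <- log2mat[affected, affected_ch] +
      config$effect_log2
  if (config$noise_sd > 0)
    log2mat <- log2mat + stats::rnorm(n * config$n_channels, 0, config$noise_sd)
  quant <- 2^log2mat
  dimnames(quant) <- list(sites$site, channels)
  effects <- rep(0, n)
  effects[affected] <- config$effect_log2
  names(effects) <- sites$site
  list(quant = quant,
       truth = list(target_kinase = config$target_kinase,
                    affected_sites = sites$site[affected],
                    effects = effects,
                    affected_channels = channels[affected_ch]))
}

#' Simulate a PSM-level reporter table with quality defects
#'
#' Applies the reagent impurity mixing matrix to each site's true channel
#' intensities and injects, independently per record and per defect type,
#' the quality problems the processing filters are designed to catch: low
#' isolation specificity (< 0.8), low summed signal-to-noise (< 160),
#' excessive missing channels (>= 12 of 16), and poor site localization
#' (AScore < 13).
#'
#' @param quant Sites x channels matrix of true (linear) intensities.
#' @param impurity Square mixing matrix (column j = observed distribution of
#'   reagent j's signal across channels); positive diagonal required.
#' @param artifact_rates Named list of per-defect probabilities (see
#'   [sim_config()]).
#' @param seed Integer seed.
#' @param sites Optional site table supplying protein/flank metadata.
#' @return data.frame of reporter records (one per site): channel columns,
#'   `isolation_specificity`, `summed_sn`, `n_missing_channels`,
#'   `localization_score`, `n_phospho`. Attribute `defect_counts` records how
#'   many records received each injected defect.
#' @export
simulate_psm_table <- function(quant, impurity,
                               artifact_rates = list(low_isolation = 0,
                                                     low_sn = 0,
                                                     missing_channels = 0,
                                                     low_localization = 0),
                               seed = 1L, sites = NULL) {
  n_ch <- ncol(quant)
  if (!is.matrix(impurity) || nrow(impurity) != n_ch || ncol(impurity) != n_ch)
    stop_invalid("impurity must be square with dimension = n_channels (%d)", n_ch)
  if (any(diag(impurity) <= 0))
    stop_invalid("impurity matrix diagonal must be positive")
  rates <- utils::modifyList(list(low_isolation = 0, low_sn = 0,
                                  missing_channels = 0, low_localization = 0),
                             as.list(artifact_rates))
  set.seed(derive_seed(seed, 104L))
  n <- nrow(quant)
  mixed <- t(impurity %*% t(quant))
  def_iso <- stats::runif(n) < rates$low_isolation
  def_sn <- stats::runif(n) < rates$low_sn
  def_miss <- stats::runif(n) < rates$missing_channels
  def_loc <- stats::runif(n) < rates$low_localization
  iso <- stats::runif(n, 0.8, 1)
  iso[def_iso] <- stats::runif(sum(def_iso), 0, 0.8 - 1e-6)
  loc <- stats::runif(n, 13, 60)
  loc[def_loc] <- stats::runif(sum(def_loc), 0, 13 - 1e-6)
  if (any(def_sn)) {
    target <- stats::runif(sum(def_sn), 10, 159)
    mixed[def_sn, ] <- mixed[def_sn, , drop = FALSE] *
      (target / rowSums(mixed[def_sn, , drop = FALSE]))
  }
  if (any(def_miss)) {
    for (i in which(def_miss)) {
      k <- sample(12:n_ch, 1L)
      mixed[i, sample.int(n_ch, k)] <- NA_real_
    }
  }
  rec <- as.data.frame(mixed, stringsAsFactors = FALSE)
  colnames(rec) <- colnames(quant)
  rec <- cbind(data.frame(record = sprintf("PSM%06d", seq_len(n)),
                          site = rownames(quant),
                          protein = if (!is.null(sites)) sites$protein else
                            sub("_[ST]\\d+$", "", rownames(quant)),
                          stringsAsFactors = FALSE),
               rec)
  rec$isolation_specificity <- iso
  rec$summed_sn <- rowSums(mixed, na.rm = TRUE)
  rec$n_missing_channels <- rowSums(is.na(mixed))
  rec$localization_score <- loc
  rec$n_phospho <- 1L
  attr(rec, "defect_counts") <- c(low_isolation = sum(def_iso),
                                  low_sn = sum(def_sn),
                                  missing_channels = sum(def_miss),
                                  low_localization = sum(def_loc))
  rec
}

#' Mildly non-diagonal TMT-style reagent impurity matrix
#'
#' Column j keeps `1 - leak_prev - leak_next` of reagent j's signal on the
#' diagonal and leaks the rest into the adjacent channels (lost off the ends,
#' so column sums are <= 1). Diagonally dominant, hence invertible.
#'
#' @param n_channels Number of channels.
#' @param leak_prev,leak_next Fractions leaking into channel j-1 / j+1.
#' @return n x n impurity matrix.
#' @export
default_impurity <- function(n_channels = 16L, leak_prev = 0.02,
                             leak_next = 0.03) {
  m <- diag(1 - leak_prev - leak_next, n_channels)
  for (j in seq_len(n_channels)) {
    if (j > 1L) m[j - 1L, j] <- leak_prev
    if (j < n_channels) m[j + 1L, j] <- leak_next
  }
  m
}

#' Build the channel design table implied by a simulation config
#'
#' @param config A [sim_config()].
#' @return data.frame with columns `channel`, `group`, `genotype`,
#'   `treatment`, `replicate`.
#' @export
design_from_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  channels <- sprintf("ch%02d", seq_len(config$n_channels))
  grp <- character(config$n_channels)
  for (g in names(config$groups)) grp[config$groups[[g]]] <- g
  geno <- ifelse(grepl("^KO", grp), "KO", "WT")
  treat <- ifelse(grepl("MRT", grp), "MRT67307", "untreated")
  rep_idx <- stats::ave(seq_along(grp), grp, FUN = seq_along)
  data.frame(channel = channels, group = grp, genotype = geno,
             treatment = treat, replicate = rep_idx,
             stringsAsFactors = FALSE)
}
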