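# Independent oracles used to cross-check the package implementations.
# These are deliberately written as direct textbook computations, sharing no
# code path with the functions they validate.

# One-sided Fisher p by exhaustive hypergeometric tail enumeration.
fisher_oracle <- function(a, b, cc, d) {
  m <- a + cc; n <- b + d; k <- a + b
  if (k == 0 || m == 0) return(1)
  hi <- min(k, m)
  if (a > hi) return(0)
  total <- choose(m + n, k)
  sum(vapply(a:hi, function(j) choose(m, j) * choose(n, k - j), 0)) / total
}

# Benjamini-Hochberg step-up, coded from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Random diagonally dominant (hence invertible) mixing matrix with
# nonnegative entries and column sums <= 1.
random_impurity <- function(n) {
  m <- matrix(stats::runif(n * n, 0, 0.3 / n), n, n)
  diag(m) <- stats::runif(n, 0.7, 0.95)
  m
}

# Small random flank with S/T center.
random_flanks <- function(n) {
  chars <- matrix(sample(phosmotif::AA_ALPHABET, n * 11, replace = TRUE), n, 11)
  chars[, 6] <- sample(c("S", "T"), n, replace = TRUE)
  apply(chars, 1, paste, collapse = "")
}

# Shared end-to-end run at the study conditions: 16-channel plex in
# quadruplicate, 2000 sites, 50 kinases, spiked kinase down-shifted by
# effect_log2 in the TBK1-null channels, contrasted 4 vs 4 within the
# untreated arm.
e2e_run <- function(seed, effect_log2 = -2, noise_sd = 0.25,
                    n_sites = 2000L, n_kinases = 50L,
                    target = "KIN007", motif_fraction = 0.5) {
  cfg <- phosmotif::run_config(
    mode = "simulate",
    sim = phosmotif::sim_config(n_sites = n_sites, target_kinase = target,
                                effect_log2 = effect_log2,
                                noise_sd = noise_sd,
                                motif_fraction = motif_fraction, seed = seed),
    n_kinases = n_kinases)
  phosmotif::run_pipeline(cfg)
}

# Rank of the target kinase among downregulated-enriched kinases ordered by
# final adjusted P (NA if excluded or not on the down side).
down_rank_of <- function(out, target) {
  e <- out$enrichment
  down <- e[!e$excluded & e$side == "down", ]
  down <- down[order(down$final_q, down$p_down, down$kinase), ]
  r <- match(target, down$kinase)
  list(rank = r, final_q = if (!is.na(r)) down$final_q[r] else NA_real_)
}
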