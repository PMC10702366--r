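#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard residues, uppercase. Flanking windows additionally use
#' `"_"` as an explicit terminus-padding character which is neutral under
#' scoring.
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname AA_ALPHABET
#' @export
PAD_CHAR <- "_"

# Flank positions relative to the phosphoacceptor: -5..-1, +1..+5 (center 0
# excluded; the central S/T does not contribute to motif scores).
FLANK_POSITIONS <- c(-5:-1, 1:5)
FLANK_WIDTH <- 11L
CENTER_IDX <- 6L

#' Derive a sub-stream seed from a root seed
#'
#' All stochastic operations consume a seed derived from the root seed and a
#' fixed per-operation stream id, so each generator stage is reproducible in
#' isolation while a single root seed still determines the whole run.
#'
#' @param seed Integer root seed.
#' @param stream Integer stream identifier (fixed per operation).
#' @return An integer seed in [0, 2^31).
#' @export
derive_seed <- function(seed, stream) {
  s <- (abs(as.numeric(seed)) %% 2147483647) * 48271 + as.numeric(stream) * 9973
  as.integer(s %% 2147483629)
}

# Row variances with NA handling; single-observation rows give NA.
row_vars <- function(x) {
  n <- rowSums(!is.na(x))
  m <- rowMeans(x, na.rm = TRUE)
  v <- rowSums((x - m)^2, na.rm = TRUE) / (n - 1)
  v[n < 2] <- NA_real_
  v
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Encode flanks (11-char strings) as an n x 10 matrix of indices into
# c(AA_ALPHABET, "_"), dropping the central residue. Index 21 = padding.
encode_flanks <- function(flanks) {
  chars <- matrix(unlist(strsplit(flanks, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(flanks), byrow = TRUE)
  off <- chars[, -CENTER_IDX, drop = FALSE]
  idx <- match(off, c(AA_ALPHABET, PAD_CHAR))
  if (anyNA(idx)) {
    bad <- unique(off[is.na(idx)])
    stop_invalid("invalid residue character(s) in flank: %s",
                 paste(bad, collapse = ", "))
  }
  matrix(idx, nrow = length(flanks))
}

check_flank <- function(flank) {
  if (!is.character(flank) || length(flank) != 1L || nchar(flank) != FLANK_WIDTH)
    stop_invalid("flank must be a single %d-character string", FLANK_WIDTH)
  center <- substr(flank, CENTER_IDX, CENTER_IDX)
  if (!center %in% c("S", "T"))
    stop_invalid("flank center must be S or T, got '%s'", center)
  invisible(flank)
}
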