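# Delimited-text readers/writers for every table the pipeline exchanges:
# quantification matrices, channel designs, PSSM libraries (long format),
# impurity matrices, and ground-truth tables. All files are
# tab-separated with a header row; missing values are empty cells.

#' Write / read a quantification table (rows x channels)
#'
#' First column `id` holds row identifiers; remaining columns are channels.
#' Missing values are written as empty cells.
#'
#' @param table Numeric matrix with row and column names.
#' @param path File path.
#' @return `read_quant_table` returns the matrix.
#' @export
write_quant_table <- function(table, path) {
  df <- data.frame(id = rownames(table), table, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_quant_table
#' @param path File path.
#' @export
read_quant_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "id")
    stop_invalid("%s: first column must be 'id', got '%s'", path, names(df)[1])
  if (anyDuplicated(df$id))
    stop_invalid("%s: duplicate row id(s): %s", path,
                 paste(utils::head(unique(df$id[duplicated(df$id)]), 5),
                       collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_invalid("%s: non-numeric channel values", path)
  rownames(m) <- df$id
  m
}

#' Write / read a channel design table
#' @param design data.frame with `channel`, `group`, `genotype`, `treatment`,
#'   `replicate`.
#' @param path File path.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("channel", "genotype", "treatment")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_invalid("%s: missing design column(s): %s", path,
                 paste(miss, collapse = ", "))
  if (anyDuplicated(df$channel))
    stop_invalid("%s: duplicate channel id(s)", path)
  df
}

#' Write / read a PSSM library in long format
#'
#' Long format: columns `kinase`, `position` (-5..-1, 1..5), `residue`,
#' `probability`. Optional per-kinase background samples are stored in a
#' companion attribute file only in memory; backgrounds are recomputed from
#' data via [library_backgrounds()].
#'
#' @param library A `kinase_library`.
#' @param path File path.
#' @export
write_pssm_library <- function(library, path) {
  rows <- lapply(library$kinases, function(k) {
    p <- library$pssms[[k]]
    data.frame(kinase = k,
               position = rep(FLANK_POSITIONS, times = ncol(p)),
               residue = rep(colnames(p), each = nrow(p)),
               probability = as.vector(p),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pssm_library
#' @export
read_pssm_library <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("kinase", "position", "residue", "probability")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_invalid("%s: missing PSSM column(s): %s", path,
                 paste(miss, collapse = ", "))
  bad <- which(!df$position %in% FLANK_POSITIONS)
  if (length(bad))
    stop_invalid("%s: line %d: invalid position %s", path, bad[1] + 1L,
                 df$position[bad[1]])
  bad <- which(!df$residue %in% AA_ALPHABET)
  if (length(bad))
    stop_invalid("%s: line %d: invalid residue '%s'", path, bad[1] + 1L,
                 df$residue[bad[1]])
  bad <- which(!is.finite(df$probability) | df$probability <= 0)
  if (length(bad))
    stop_invalid("%s: line %d: probability must be positive", path, bad[1] + 1L)
  kinases <- sort(unique(df$kinase))
  pssms <- lapply(kinases, function(k) {
    sub <- df[df$kinase == k, ]
    m <- matrix(NA_real_, 10L, length(AA_ALPHABET),
                dimnames = list(as.character(FLANK_POSITIONS), AA_ALPHABET))
    m[cbind(match(sub$position, FLANK_POSITIONS),
            match(sub$residue, AA_ALPHABET))] <- sub$probability
    if (anyNA(m))
      stop_invalid("%s: kinase %s: incomplete PSSM (missing cells)", path, k)
    rs <- rowSums(m)
    if (any(abs(rs - 1) > 1e-6))
      stop_invalid("%s: kinase %s: position rows must sum to 1", path, k)
    m / rs  # exact renormalization against round-tripped text precision
  })
  names(pssms) <- kinases
  structure(list(kinases = kinases, pssms = pssms, backgrounds = NULL),
            class = "kinase_library")
}

#' Write / read a square impurity matrix with channel headers
#' @param impurity Square numeric matrix.
#' @param path File path.
#' @export
write_impurity <- function(impurity, path) {
  if (is.null(colnames(impurity)))
    dimnames(impurity) <- list(sprintf("ch%02d", seq_len(nrow(impurity))),
                               sprintf("ch%02d", seq_len(ncol(impurity))))
  write_quant_table(impurity, path)
}

#' @rdname write_impurity
#' @export
read_impurity <- function(path) {
  m <- read_quant_table(path)
  if (nrow(m) != ncol(m)) stop_invalid("%s: impurity matrix must be square", path)
  m
}

#' Write ground-truth tables (affected sites and effects) keyed by site id
#' @param truth Ground-truth list from [simulate_quant()].
#' @param path File path.
#' @export
write_ground_truth <- function(truth, path) {
  df <- data.frame(site = names(truth$effects),
                   effect_log2 = unname(truth$effects),
                   affected = names(truth$effects) %in% truth$affected_sites,
                   target_kinase = truth$target_kinase %||% NA_character_,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
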