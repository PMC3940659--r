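#' Position-specific scoring matrix for hexapeptide scanning
#'
#' A 6 (position) x 20 (residue) real-valued matrix used additively: the
#' score of a hexapeptide window is the sum over positions of the weight of
#' the residue observed there. Trained amyloid-predictor matrices are not
#' bundled; any matrix in this shape can be plugged in, and
#' [pssm_from_motifs()] builds simple indicator matrices for testing and
#' simulation.
#'
#' @param weights numeric 6 x 20 matrix; columns must be named by the 20
#'   standard residues (any order; stored in alphabetical order).
#' @param thresholds named numeric vector of score cutoff presets, e.g.
#'   `c(best_overall = ..., custom = ...)`.
#' @return An object of class `pssm`.
#' @export
pssm <- function(weights, thresholds = numeric(0)) {
  weights <- as.matrix(weights)
  if (nrow(weights) != 6L)
    stop("a hexapeptide PSSM has exactly 6 position rows")
  if (is.null(colnames(weights)) || !setequal(colnames(weights), AA20))
    stop("PSSM columns must be named by the 20 standard residues")
  weights <- weights[, AA20, drop = FALSE]
  storage.mode(weights) <- "double"
  rownames(weights) <- paste0("p", 1:6)
  structure(list(weights = weights, thresholds = thresholds),
            class = "pssm")
}

#' Indicator PSSM from a motif list
#'
#' Weight 1 at position p for every residue occurring at position p of any
#' motif, 0 elsewhere; with threshold 6, exactly the position-wise
#' "chimeras" of the motif set score as hits. Used as the documented
#' fixture matrix of the synthetic cohorts.
#'
#' @param motifs character vector of 6-residue motifs.
#' @return A [pssm()] with a `planted` threshold preset of 6.
#' @examples
#' m <- pssm_from_motifs(c("KLVFFA", "GGVVIA"))
#' score_window(m, "KLVFFA")  # 6
#' @export
pssm_from_motifs <- function(motifs) {
  if (any(nchar(motifs) != 6L)) stop("motifs must be hexapeptides")
  w <- matrix(0, 6, 20, dimnames = list(paste0("p", 1:6), AA20))
  for (m in motifs) {
    aa <- strsplit(toupper(m), "")[[1]]
    if (anyNA(match(aa, AA20)))
      stop("motif contains a nonstandard residue: ", m)
    for (p in 1:6) w[p, aa[p]] <- 1
  }
  pssm(w, thresholds = c(planted = 6))
}

#' Read / write a PSSM in TSV form
#'
#' The exchange format is a tab-separated table of 6 rows by 20 columns
#' with the residue alphabet as header.
#'
#' @param path file path.
#' @return `read_pssm`: a [pssm()]; `write_pssm`: `path`, invisibly.
#' @export
read_pssm <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  pssm(as.matrix(df))
}

#' @rdname read_pssm
#' @param x a [pssm()].
#' @export
write_pssm <- function(x, path) {
  write.table(x$weights, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Score one hexapeptide window
#'
#' Additive position-wise sum `sum_p weights[p, window[p]]`. Windows
#' containing ambiguity letters are not scorable and return `NA` (callers
#' skip them).
#'
#' @param x a [pssm()].
#' @param hexamer a 6-residue string.
#' @return The numeric score, or `NA` for an unscorable window.
#' @export
score_window <- function(x, hexamer) {
  aa <- strsplit(toupper(hexamer), "")[[1]]
  if (length(aa) != 6L) stop("window must have exactly 6 residues")
  idx <- match(aa, AA20)
  if (anyNA(idx)) return(NA_real_)
  sum(x$weights[cbind(1:6, idx)])
}

#' Scan a protein for amyloidogenic regions
#'
#' Every hexapeptide window with score `>= threshold` (closed bound)
#' qualifies; residues covered by qualifying windows are unioned and each
#' maximal run becomes one AR interval (length necessarily >= 6).
#' Overlapping qualifying windows thus merge into a single region. The
#' per-region peak window score is kept as metadata.
#'
#' @param record one row of a protein record table.
#' @param x a [pssm()].
#' @param threshold numeric score cutoff, or the name of a threshold
#'   preset stored on the matrix.
#' @return A region table of kind AR with an extra `peak_score` column;
#'   zero rows (with a warning) for proteins shorter than 6 residues.
#' @export
scan_sequence <- function(record, x, threshold) {
  if (is.character(threshold)) {
    if (!threshold %in% names(x$thresholds))
      stop("no threshold preset named '", threshold, "'")
    threshold <- x$thresholds[[threshold]]
  }
  empty <- region_table(character(), character(), integer(), integer())
  empty$peak_score <- numeric(0)
  L <- nchar(record$sequence)
  if (L < 6L) {
    warning("protein ", record$id, " shorter than 6 residues: no AR scan")
    return(empty)
  }
  chars <- strsplit(record$sequence, "")[[1]]
  idx <- match(chars, AA20)
  n_win <- L - 5L
  scores <- rep(NA_real_, n_win)
  for (s in seq_len(n_win)) {
    w <- idx[s:(s + 5L)]
    if (!anyNA(w)) scores[s] <- sum(x$weights[cbind(1:6, w)])
  }
  hit <- !is.na(scores) & scores >= threshold
  if (!any(hit)) return(empty)
  mask <- logical(L)
  for (s in which(hit)) mask[s:(s + 5L)] <- TRUE
  r <- rle(mask)
  re <- cumsum(r$lengths); rs <- re - r$lengths + 1L
  starts <- rs[r$values]; ends <- re[r$values]
  rt <- region_table(rep(record$id, length(starts)), "AR", starts, ends)
  rt$subsequence <- substring(record$sequence, rt$start, rt$end)
  rt$peak_score <- vapply(seq_along(starts), function(i) {
    wins <- which(hit)
    wins <- wins[wins >= starts[i] & wins + 5L <= ends[i]]
    max(scores[wins])
  }, numeric(1))
  rt
}
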