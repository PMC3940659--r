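#' Build a protein record table
#'
#' The basic sequence container used throughout the package: one row per
#' protein with its identifier, upper-case amino-acid sequence, length and a
#' free-text source tag. Sequences may contain the ambiguity letters
#' X, B, Z, U, O (flagged in the `has_ambiguity` column) but no gap
#' characters.
#'
#' @param id character vector of unique identifiers.
#' @param sequence character vector of amino-acid sequences.
#' @param source free-text source tag(s) (e.g. `"disprot"`, `"synthetic"`),
#'   recycled to the number of records.
#' @param description optional per-record free text (FASTA description after
#'   the first whitespace).
#' @return A `data.frame` with columns `id`, `sequence`, `length`, `source`,
#'   `description`, `has_ambiguity`.
#' @examples
#' protein_records("Abeta42",
#'   "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA")
#' @export
protein_records <- function(id, sequence, source = "unknown",
                            description = NA_character_) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence))
    stop("'id' and 'sequence' must have the same length")
  if (anyDuplicated(id))
    stop("duplicate protein ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(grepl("[-.*]", sequence)))
    stop("gap or stop characters are not allowed in protein sequences")
  allowed <- paste0(c(AA20, AA_AMBIG), collapse = "")
  bad <- grepl(sprintf("[^%s]", allowed), sequence)
  if (any(bad))
    stop("non amino-acid letters in sequence(s): ",
         paste(head(id[bad], 5), collapse = ", "))
  data.frame(
    id = id,
    sequence = sequence,
    length = nchar(sequence),
    source = rep_len(as.character(source), length(id)),
    description = rep_len(as.character(description), length(id)),
    has_ambiguity = grepl(sprintf("[%s]", paste0(AA_AMBIG, collapse = "")),
                          sequence),
    stringsAsFactors = FALSE
  )
}

#' Read protein sequences from a FASTA file
#'
#' One record per FASTA entry, order preserved. The header token before the
#' first whitespace becomes the id; the remainder is kept as `description`.
#'
#' @param path path to a FASTA file.
#' @param source source tag stored on every record.
#' @return A protein record table (see [protein_records()]). An empty file
#'   yields a zero-row table with a warning.
#' @export
read_fasta <- function(path, source = "fasta") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  meaningful <- which(nzchar(trimws(lines)))
  if (length(meaningful) == 0L) {
    warning("empty FASTA file: ", path)
    return(protein_records(character(), character(), source))
  }
  if (!startsWith(trimws(lines[meaningful[1]]), ">"))
    stop("malformed FASTA: sequence line before any header at line ",
         meaningful[1], " of ", path)
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), NA_character_)
  protein_records(ids, as.character(aa), source = source,
                  description = desc)
}

#' Write protein records to a FASTA file
#'
#' Inverse of [read_fasta()]: `write_fasta(read_fasta(f))` reproduces the
#' sequences byte-identically (headers are id + description).
#'
#' @param records a protein record table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  aa <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  names(aa) <- ifelse(is.na(records$description), records$id,
                      paste(records$id, records$description))
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

REGION_KINDS <- c("AR", "LCR", "DISORDER", "OVERLAP")

#' Build and validate a region table
#'
#' Regions are 1-based inclusive intervals `[start, end]` on a protein,
#' typed as AR, LCR, DISORDER or OVERLAP. When the protein sequences are
#' known, missing subsequences are filled by slicing and provided
#' subsequences are checked against the sequence.
#'
#' @param protein_id,kind,start,end,subsequence region columns; `subsequence`
#'   may be `NULL`/`NA` and is then filled from `proteins` when sequences are
#'   available.
#' @param proteins a protein record table, or a `data.frame` with at least
#'   `id` and `length` columns (sequence-free validation, bounds only).
#' @return A `data.frame` with columns `protein_id`, `kind`, `start`, `end`,
#'   `length`, `subsequence`.
#' @export
region_table <- function(protein_id, kind, start, end, subsequence = NULL,
                         proteins = NULL) {
  n <- length(protein_id)
  kind <- toupper(as.character(kind))
  if (!all(kind %in% REGION_KINDS))
    stop("region kind must be one of ", paste(REGION_KINDS, collapse = ", "))
  start <- as.integer(start); end <- as.integer(end)
  if (anyNA(start) || anyNA(end)) stop("non-integer region bounds")
  if (is.null(subsequence)) subsequence <- rep(NA_character_, n)
  subsequence <- as.character(subsequence)
  bad <- which(start < 1L | start > end)
  if (length(bad))
    stop("invalid interval (need 1 <= start <= end) in row(s): ",
         paste(head(bad, 5), collapse = ", "))
  rt <- data.frame(protein_id = as.character(protein_id), kind = kind,
                   start = start, end = end, length = end - start + 1L,
                   subsequence = subsequence, stringsAsFactors = FALSE)
  if (!is.null(proteins)) rt <- validate_regions(rt, proteins)
  rt
}

# Bounds + subsequence validation of a region table against a protein set.
validate_regions <- function(rt, proteins) {
  unknown <- setdiff(rt$protein_id, proteins$id)
  if (length(unknown))
    stop("region rows reference unknown protein id(s): ",
         paste(head(unknown, 5), collapse = ", "))
  plen <- setNames(proteins$length, proteins$id)
  over <- which(rt$end > plen[rt$protein_id])
  if (length(over))
    stop("region end beyond protein length in row(s): ",
         paste(head(over, 5), collapse = ", "))
  has_seq <- "sequence" %in% names(proteins)
  if (has_seq) {
    pseq <- setNames(proteins$sequence, proteins$id)
    slice <- substring(pseq[rt$protein_id], rt$start, rt$end)
    given <- !is.na(rt$subsequence) & nzchar(rt$subsequence)
    mism <- which(given & rt$subsequence != slice)
    if (length(mism))
      stop("subsequence does not match protein sequence in row(s): ",
           paste(head(mism, 5), collapse = ", "),
           " (e.g. given '", rt$subsequence[mism[1]],
           "' vs sequence '", slice[mism[1]], "')")
    rt$subsequence[!given] <- slice[!given]
  }
  rownames(rt) <- NULL
  rt
}

#' Read a region table from TSV
#'
#' Expects a tab-separated file with header columns `protein_id`, `kind`,
#' `start`, `end` and optionally `subsequence`; rows are validated against
#' `proteins` (bounds, and subsequence identity when sequences are known).
#'
#' @param path TSV file path.
#' @inheritParams region_table
#' @return A validated region table.
#' @export
read_region_table <- function(path, proteins = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "kind", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("region TSV ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  region_table(df$protein_id, df$kind, df$start, df$end,
               if ("subsequence" %in% names(df)) df$subsequence else NULL,
               proteins = proteins)
}

#' Write a region table to TSV
#'
#' Fixed column order: protein_id, kind, start, end, length, subsequence.
#'
#' @param rt a region table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(rt, path) {
  cols <- c("protein_id", "kind", "start", "end", "length", "subsequence")
  out <- rt[, intersect(cols, names(rt)), drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-residue secondary-structure annotations
#'
#' FASTA-like records over the alphabet H (helix), E (sheet/strand),
#' C (coil); one annotation string per protein, which must match the
#' protein length when `proteins` is given.
#'
#' @param path FASTA-like file of H/E/C strings.
#' @param proteins optional protein record table for length validation.
#' @return A named character vector of annotation strings.
#' @export
read_ss_annotation <- function(path, proteins = NULL) {
  ss <- Biostrings::readBStringSet(path)
  out <- setNames(toupper(as.character(ss)), sub("\\s.*$", "", names(ss)))
  bad <- grepl("[^HEC]", out)
  if (any(bad))
    stop("secondary-structure annotation contains letters outside {H,E,C}: ",
         paste(head(names(out)[bad], 5), collapse = ", "))
  if (!is.null(proteins)) {
    common <- intersect(names(out), proteins$id)
    plen <- setNames(proteins$length, proteins$id)
    mism <- common[nchar(out[common]) != plen[common]]
    if (length(mism))
      stop("annotation length differs from protein length for: ",
           paste(head(mism, 5), collapse = ", "))
  }
  out
}
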