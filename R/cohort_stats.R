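#' Disorder fraction of a protein
#'
#' Percentage of residues inside disordered intervals:
#' 100 x disordered residues / protein length (intervals are merged first
#' so no residue is double-counted).
#'
#' @param disorder region table of kind DISORDER for one protein (zero rows
#'   allowed).
#' @param protein_length protein length in residues (> 0).
#' @return Numeric percentage in \[0, 100\].
#' @export
disorder_fraction <- function(disorder, protein_length) {
  content_percent(disorder, protein_length)
}

#' Disorder class of a protein
#'
#' Partition of the disorder-percentage axis into partially (PDP, 0-30%),
#' moderately (MDP, >30-70%) and largely (LDP, >70-100%) disordered
#' proteins. The boundaries are closed on the right so every real-valued
#' fraction maps to exactly one class (30 -> PDP, 30.5 -> MDP, 70 -> MDP,
#' 100 -> LDP).
#'
#' @param disorder_pct numeric vector of disorder percentages in \[0, 100\].
#' @return Character vector over `{"PDP", "MDP", "LDP"}`.
#' @export
classify_protein <- function(disorder_pct) {
  if (any(is.na(disorder_pct)) ||
      any(disorder_pct < 0 | disorder_pct > 100))
    stop("disorder_pct must lie in [0, 100]")
  ifelse(disorder_pct <= 30, "PDP",
         ifelse(disorder_pct <= 70, "MDP", "LDP"))
}

#' Per-protein summary metrics
#'
#' Assembles the per-protein summary table: region counts and contents,
#' AR x LCR overlap count, terminal AR counts, disorder percentage and
#' class, and the amyloidogenic flag (at least one AR).
#'
#' @param proteins a protein record table (or a `data.frame` with `id` and
#'   `length`).
#' @param ars,lcrs region tables of kinds AR and LCR covering any subset of
#'   the proteins.
#' @param disorder optional region table of kind DISORDER.
#' @param margin terminal window width for [terminal_counts()].
#' @return A `data.frame` with one row per protein: `protein_id`, `length`,
#'   `disorder_pct`, `class_label`, `ar_count`, `ar_pct`, `lcr_count`,
#'   `lcr_pct`, `overlap_count`, `n_terminal_ars`, `c_terminal_ars`,
#'   `amyloidogenic`.
#' @export
summarize_proteins <- function(proteins, ars, lcrs, disorder = NULL,
                               margin = 15L) {
  one <- function(i) {
    pid <- proteins$id[i]; L <- proteins$length[i]
    a <- merge_regions(ars[ars$protein_id == pid, , drop = FALSE])
    l <- merge_regions(lcrs[lcrs$protein_id == pid, , drop = FALSE])
    d_pct <- NA_real_
    if (!is.null(disorder))
      d_pct <- disorder_fraction(
        disorder[disorder$protein_id == pid, , drop = FALSE], L)
    tc <- terminal_counts(a, L, margin)
    data.frame(
      protein_id = pid, length = L, disorder_pct = d_pct,
      class_label = if (is.na(d_pct)) NA_character_
                    else classify_protein(d_pct),
      ar_count = nrow(a), ar_pct = content_percent(a, L),
      lcr_count = nrow(l), lcr_pct = content_percent(l, L),
      overlap_count = nrow(overlap_catalog(a, l)),
      n_terminal_ars = unname(tc["n_count"]),
      c_terminal_ars = unname(tc["c_count"]),
      amyloidogenic = nrow(a) >= 1L,
      stringsAsFactors = FALSE)
  }
  if (nrow(proteins) == 0L) {
    return(data.frame(protein_id = character(), length = integer(),
                      disorder_pct = numeric(),
                      class_label = character(), ar_count = integer(),
                      ar_pct = numeric(), lcr_count = integer(),
                      lcr_pct = numeric(), overlap_count = integer(),
                      n_terminal_ars = integer(),
                      c_terminal_ars = integer(),
                      amyloidogenic = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(proteins)), one))
  rownames(out) <- NULL
  out
}

#' Aggregate protein summaries by disorder class
#'
#' One row per disorder class plus a Total row: protein counts, number and
#' percentage of amyloidogenic proteins (those with at least one AR),
#' total region counts, mean contents and total overlap-region count.
#'
#' @param summaries a [summarize_proteins()] table with non-missing
#'   `class_label`.
#' @return A `data.frame` with columns `class_label`, `total_proteins`,
#'   `amyloidogenic_count`, `amyloidogenic_pct`, `ar_count`, `ar_pct_mean`,
#'   `lcr_count`, `lcr_pct_mean`, `overlap_region_count`; zero rows for
#'   empty input.
#' @export
summarize_class <- function(summaries) {
  empty <- data.frame(class_label = character(), total_proteins = integer(),
                      amyloidogenic_count = integer(),
                      amyloidogenic_pct = numeric(), ar_count = integer(),
                      ar_pct_mean = numeric(), lcr_count = integer(),
                      lcr_pct_mean = numeric(),
                      overlap_region_count = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(summaries) == 0L) return(empty)
  if (anyNA(summaries$class_label))
    stop("summaries without class labels (no disorder annotation?)")
  agg <- function(s, label) {
    data.frame(
      class_label = label, total_proteins = nrow(s),
      amyloidogenic_count = sum(s$amyloidogenic),
      amyloidogenic_pct = 100 * sum(s$amyloidogenic) / nrow(s),
      ar_count = sum(s$ar_count), ar_pct_mean = mean(s$ar_pct),
      lcr_count = sum(s$lcr_count), lcr_pct_mean = mean(s$lcr_pct),
      overlap_region_count = sum(s$overlap_count),
      stringsAsFactors = FALSE)
  }
  classes <- c("LDP", "MDP", "PDP")
  present <- classes[classes %in% summaries$class_label]
  rows <- lapply(present, function(cl)
    agg(summaries[summaries$class_label == cl, , drop = FALSE], cl))
  rows[[length(rows) + 1L]] <- agg(summaries, "Total")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Amino-acid composition profile
#'
#' Residue frequencies (percent, summing to 100) over a context: the whole
#' proteins, or only the residues inside the given regions. Ambiguity
#' letters are excluded from both numerator and denominator.
#'
#' @param records a protein record table.
#' @param regions optional region table restricting the context.
#' @return Named numeric vector of 20 percentages (alphabetical residue
#'   order).
#' @export
composition_profile <- function(records, regions = NULL) {
  if (is.null(regions)) {
    txt <- paste(records$sequence, collapse = "")
  } else {
    regions <- validate_regions(regions, records)
    txt <- paste(regions$subsequence, collapse = "")
  }
  chars <- strsplit(txt, "")[[1]]
  chars <- chars[chars %in% AA20]
  if (length(chars) == 0L)
    stop("no standard residues in the requested context")
  counts <- table(factor(chars, levels = AA20))
  setNames(100 * as.numeric(counts) / length(chars), AA20)
}

#' Secondary-structure preference of a context
#'
#' Percentages of residues labelled H (helix), E (sheet/strand) and C
#' (coil) inside the context. `mode = "residue"` (default) tallies
#' individual residues; `mode = "region"` assigns each region its majority
#' label (ties broken in H, E, C order) and reports the percentage of
#' regions preferring each conformation.
#'
#' @param ss named character vector of per-residue H/E/C strings, one per
#'   protein.
#' @param regions optional region table restricting the context; when
#'   `NULL`, whole proteins are used (residue mode only).
#' @param mode `"residue"` or `"region"`.
#' @return `c(helix_pct = , sheet_pct = , coil_pct = )`, summing to 100.
#' @export
ss_preference <- function(ss, regions = NULL,
                          mode = c("residue", "region")) {
  mode <- match.arg(mode)
  bad <- grepl("[^HEC]", ss)
  if (any(bad)) stop("unknown secondary-structure label (need H/E/C)")
  slice_labels <- function() {
    if (is.null(regions)) return(strsplit(paste(ss, collapse = ""), "")[[1]])
    unknown <- setdiff(regions$protein_id, names(ss))
    if (length(unknown))
      stop("no annotation for protein(s): ",
           paste(head(unknown, 5), collapse = ", "))
    if (any(regions$end > nchar(ss[regions$protein_id])))
      stop("region extends beyond its annotation string")
    strsplit(paste(substring(ss[regions$protein_id], regions$start,
                          regions$end), collapse = ""), "")[[1]]
  }
  if (mode == "residue") {
    lab <- slice_labels()
    n <- length(lab)
    if (n == 0L) stop("empty context")
    out <- 100 * c(sum(lab == "H"), sum(lab == "E"), sum(lab == "C")) / n
  } else {
    if (is.null(regions)) stop("region mode requires a region table")
    maj <- vapply(seq_len(nrow(regions)), function(i) {
      lab <- strsplit(substr(ss[regions$protein_id[i]], regions$start[i],
                             regions$end[i]), "")[[1]]
      counts <- c(H = sum(lab == "H"), E = sum(lab == "E"),
                  C = sum(lab == "C"))
      names(counts)[which.max(counts)]
    }, character(1))
    out <- 100 * c(sum(maj == "H"), sum(maj == "E"), sum(maj == "C")) /
      length(maj)
  }
  setNames(out, c("helix_pct", "sheet_pct", "coil_pct"))
}

# Chou-Fasman conformational propensities (helix Pa, sheet Pb).
CHOU_FASMAN <- data.frame(
  aa = c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V"),
  helix = c(1.42,0.98,0.67,1.01,0.70,1.11,1.51,0.57,1.00,1.08,
            1.21,1.16,1.45,1.13,0.57,0.77,0.83,1.08,0.69,1.06),
  sheet = c(0.83,0.93,0.89,0.54,1.19,1.10,0.37,0.75,0.87,1.60,
            1.30,0.74,1.05,1.38,0.55,0.75,1.19,1.37,1.47,1.70),
  stringsAsFactors = FALSE)

#' Chou-Fasman per-residue secondary-structure baseline
#'
#' A deterministic stand-in annotation when no external secondary-structure
#' prediction is supplied: each residue is labelled H when its helix
#' propensity exceeds 1.0 and is at least its sheet propensity, E when its
#' sheet propensity exceeds 1.0 and its helix one, and C otherwise
#' (ambiguity letters are labelled C). This single-residue argmax ignores
#' all nucleation/extension context and is meant only as a crude baseline.
#'
#' @param record one row of a protein record table.
#' @return A string over H/E/C of the same length as the sequence.
#' @examples
#' chou_fasman_baseline(protein_records("polyA", "AAAAA"))  # "HHHHH"
#' @export
chou_fasman_baseline <- function(record) {
  aa <- strsplit(record$sequence, "")[[1]]
  i <- match(aa, CHOU_FASMAN$aa)
  h <- CHOU_FASMAN$helix[i]; e <- CHOU_FASMAN$sheet[i]
  lab <- ifelse(is.na(i), "C",
         ifelse(h > 1 & h >= e, "H",
         ifelse(e > 1 & e > h, "E", "C")))
  paste(lab, collapse = "")
}
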