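# Core promoter element scanning and rule-based promoter typing.
#
# Elements are written as IUPAC degenerate consensus strings and searched in
# fixed TSS-relative windows (the window constrains the motif START offset;
# offset 0 is the base at the dominant TSS). TATA promoters tolerate one
# mismatch to STATAWAWR; all other elements require an exact degenerate match.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Core promoter element table
#'
#' The ten Drosophila core promoter elements used throughout the package,
#' with their IUPAC consensus and the TSS-relative window (inclusive, motif
#' start position) in which each is searched. `max_mismatches` is 1 for the
#' TATA box and 0 for everything else; enrichment-mode scans override the
#' TATA allowance to 0.
#'
#' @param enrichment_mode logical; if TRUE, all elements (including TATA)
#'   use zero mismatches, as for cluster-wise element enrichment.
#' @return data.table with columns name, consensus, window_start, window_end,
#'   max_mismatches.
#' @export
element_specs <- function(enrichment_mode = FALSE) {
  path <- system.file("extdata", "core_promoter_elements.tsv",
                      package = "promnex", mustWork = TRUE)
  specs <- data.table::fread(path)
  data.table::setnames(specs, c("name", "consensus", "window_start", "window_end"))
  specs[, max_mismatches := ifelse(name == "TATA" & !enrichment_mode, 1L, 0L)]
  specs[]
}

#' Count mismatches of a DNA sequence against an IUPAC consensus
#'
#' A position matches when the sequence base is a member of the IUPAC set of
#' the consensus code at that position (S = C/G, W = A/T, R = A/G, ...).
#'
#' @param seq DNA string over A/C/G/T, same length as `consensus`.
#' @param consensus IUPAC string.
#' @return integer number of mismatching positions.
#' @export
iupac_mismatches <- function(seq, consensus) {
  s <- strsplit(toupper(seq), "")[[1]]
  k <- strsplit(toupper(consensus), "")[[1]]
  if (length(s) != length(k))
    stop("sequence and consensus must have equal length")
  if (!all(s %in% c("A", "C", "G", "T")))
    stop("sequence must be over A/C/G/T")
  if (!all(k %in% names(IUPAC_SETS)))
    stop("invalid IUPAC code in consensus")
  sum(!mapply(function(b, code) b %in% IUPAC_SETS[[code]], s, k))
}

# Vectorised scan core: mismatch count of `consensus` at every start offset
# of `seq` (character vector of single bases).
.iupac_scan <- function(bases, consensus) {
  k <- strsplit(toupper(consensus), "")[[1]]
  L <- length(k)
  n <- length(bases) - L + 1L
  if (n < 1L) return(integer(0))
  mm <- integer(n)
  for (j in seq_len(L)) {
    ok <- bases[j:(j + n - 1L)] %in% IUPAC_SETS[[k[j]]]
    mm <- mm + !ok
  }
  mm
}

#' Scan a TSS-anchored promoter sequence for one element
#'
#' The promoter sequence must already be in sense orientation (minus-strand
#' promoters reverse-complemented) and anchored so that `tss_index` is the
#' 1-based string position of offset 0.
#'
#' @param promoter_seq DNA string.
#' @param spec one row of [element_specs()] (list or single-row data.frame
#'   with name, consensus, window_start, window_end, max_mismatches).
#' @param tss_index 1-based index of the TSS base within `promoter_seq`;
#'   defaults to the center position.
#' @return data.table of hits (element, start_offset, mismatches), sorted by
#'   mismatches then distance of the start from the window center.
#' @export
scan_element <- function(promoter_seq, spec, tss_index = NULL) {
  bases <- strsplit(toupper(promoter_seq), "")[[1]]
  if (is.null(tss_index)) tss_index <- (length(bases) + 1L) %/% 2L
  L <- nchar(spec$consensus)
  starts <- spec$window_start:spec$window_end
  idx <- tss_index + starts
  if (min(idx) < 1L || max(idx) + L - 1L > length(bases))
    stop("promoter sequence does not cover the scan window for ", spec$name)
  mm_all <- .iupac_scan(bases, spec$consensus)
  mm <- mm_all[idx]
  keep <- which(mm <= spec$max_mismatches)
  hits <- data.table::data.table(
    element = rep(spec$name, length(keep)),
    start_offset = starts[keep],
    mismatches = mm[keep]
  )
  center <- (spec$window_start + spec$window_end) / 2
  data.table::setorderv(
    hits[, dist_center := abs(start_offset - center)],
    c("mismatches", "dist_center"))
  hits[, dist_center := NULL]
  hits[]
}

#' Scan a promoter against the full element table
#'
#' @inheritParams scan_element
#' @param specs element table from [element_specs()].
#' @return data.table of all hits across elements.
#' @export
scan_all_elements <- function(promoter_seq, specs = element_specs(),
                              tss_index = NULL) {
  hits <- lapply(seq_len(nrow(specs)), function(i)
    scan_element(promoter_seq, as.list(specs[i]), tss_index))
  data.table::rbindlist(hits)
}

#' Classify a promoter from its element hits
#'
#' Rule set: a TATA hit labels the promoter TATA and a TCT hit labels it TCT,
#' regardless of other elements. DPR requires at least one of MTE/DPE/PB and
#' none of TATA, TCT, Ohler1/6/7 or DRE. HK requires at least one of DRE or
#' Ohler1/6/7 and none of TATA, MTE, DPE, PB or TCT. The exclusive label
#' resolves multiple labels by the priority TATA > TCT > DPR > HK.
#'
#' @param hits data.table of hits with an `element` column (from
#'   [scan_all_elements()]).
#' @return list with `labels` (character vector, possibly empty) and
#'   `exclusive_label` (one of TATA/TCT/DPR/HK/unclassified).
#' @export
classify_promoter <- function(hits) {
  present <- unique(hits$element)
  has <- function(...) any(c(...) %in% present)
  labels <- character(0)
  if (has("TATA")) labels <- c(labels, "TATA")
  if (has("TCT"))  labels <- c(labels, "TCT")
  dpr_core <- c("MTE", "DPE", "PB")
  hk_core  <- c("DRE", "Ohler1", "Ohler6", "Ohler7")
  if (has(dpr_core) && !has("TATA", "TCT", hk_core))
    labels <- c(labels, "DPR")
  if (has(hk_core) && !has("TATA", "TCT", dpr_core))
    labels <- c(labels, "HK")
  priority <- c("TATA", "TCT", "DPR", "HK")
  exclusive <- priority[priority %in% labels][1]
  if (is.na(exclusive)) exclusive <- "unclassified"
  list(labels = labels, exclusive_label = exclusive)
}

#' Classify a set of TSS-anchored promoter sequences
#'
#' @param seqs named character vector of sense-oriented promoter sequences.
#' @param specs element table.
#' @return data.table (promoter_id, labels comma-joined, exclusive_label).
#' @export
classify_promoters <- function(seqs, specs = element_specs()) {
  res <- lapply(names(seqs), function(id) {
    cl <- classify_promoter(scan_all_elements(seqs[[id]], specs))
    data.table::data.table(promoter_id = id,
                           labels = paste(cl$labels, collapse = ","),
                           exclusive_label = cl$exclusive_label)
  })
  data.table::rbindlist(res)
}

#' Build a position weight matrix over a TSS-relative region
#'
#' Per-position base probabilities (no pseudocount) from aligned
#' TSS-anchored sequences, with per-position information content
#' IC = 2 + sum_b p_b log2 p_b (0*log0 := 0).
#'
#' @param seqs character vector of equal-length TSS-anchored sequences.
#' @param region integer vector of TSS-relative offsets (e.g. -40:-20).
#' @param tss_index 1-based TSS position within the sequences; defaults to
#'   the center.
#' @return list with `matrix` (positions x ACGT probabilities), `ic`
#'   (bits per position) and `region`.
#' @export
build_pwm <- function(seqs, region, tss_index = NULL) {
  if (length(seqs) < 1) stop("need at least one sequence")
  n <- nchar(seqs[1])
  if (is.null(tss_index)) tss_index <- (n + 1L) %/% 2L
  idx <- tss_index + region
  if (min(idx) < 1L || max(idx) > n) stop("region outside sequences")
  mat <- matrix(0, nrow = length(region), ncol = 4,
                dimnames = list(region, c("A", "C", "G", "T")))
  chars <- do.call(rbind, strsplit(toupper(seqs), ""))
  for (j in seq_along(region)) {
    tab <- table(factor(chars[, idx[j]], levels = c("A", "C", "G", "T")))
    mat[j, ] <- as.numeric(tab) / length(seqs)
  }
  ic <- apply(mat, 1, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  list(matrix = mat, ic = ic, region = region)
}

#' Expand an IUPAC consensus into one concrete instance
#'
#' Each degenerate code is replaced by a uniformly sampled member of its set.
#' Used by the synthetic promoter generator to plant motifs.
#'
#' @param consensus IUPAC string.
#' @return DNA string over A/C/G/T.
#' @export
expand_iupac <- function(consensus) {
  k <- strsplit(toupper(consensus), "")[[1]]
  paste(vapply(k, function(code) {
    s <- IUPAC_SETS[[code]]
    s[sample.int(length(s), 1L)]
  }, character(1)), collapse = "")
}
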