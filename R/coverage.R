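# Stranded base-resolution stop-base coverage.
#
# Coverage is stored sparsely as a data.table keyed by (chrom, pos, strand)
# with real-valued counts; `pos` is 0-based and records the 5'-most aligned
# base of each deduplicated read (the exonuclease stop base). All missing
# positions are zero, never NA.

#' Construct a stranded coverage object
#'
#' @param dt data.table with columns chrom, pos (0-based integer),
#'   strand ("+"/"-"), count (non-negative real). Duplicate keys are summed.
#' @return object of class `stranded_coverage`.
#' @export
stranded_coverage <- function(dt) {
  dt <- data.table::as.data.table(dt)[, .(chrom, pos, strand, count)]
  if (any(dt$count < 0)) stop("coverage values must be non-negative")
  if (!all(dt$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  dt <- dt[, .(count = sum(count)), by = .(chrom, pos, strand)]
  data.table::setkey(dt, chrom, strand, pos)
  structure(list(cov = dt, total_signal = sum(dt$count)),
            class = "stranded_coverage")
}

#' @export
print.stranded_coverage <- function(x, ...) {
  cat("stranded_coverage:", nrow(x$cov), "positions,",
      length(unique(x$cov$chrom)), "chromosomes, total signal",
      format(x$total_signal), "\n")
  invisible(x)
}

#' Stop-base coverage from aligned reads with barcode deduplication
#'
#' Reads sharing identical coordinates, strand and barcodes (fixed + random)
#' count once. The stop base is the 5'-most aligned position: `start` for
#' plus-strand reads, `end - 1` for minus-strand reads (0-based half-open
#' coordinates).
#'
#' @param reads data.frame/data.table with columns chrom, start, end, strand,
#'   fixed_barcode, random_barcode (barcode columns optional; missing
#'   barcodes are treated as one group).
#' @return `stranded_coverage` of integer stop-base counts.
#' @export
stop_base_coverage <- function(reads) {
  dt <- data.table::as.data.table(reads)
  if (!all(c("chrom", "start", "end", "strand") %in% names(dt)))
    stop("reads need chrom, start, end, strand columns")
  if (any(dt$start >= dt$end)) stop("malformed read: start >= end")
  if (!all(dt$strand %in% c("+", "-"))) stop("unknown strand value")
  if (is.null(dt$fixed_barcode)) dt[, fixed_barcode := ""]
  if (is.null(dt$random_barcode)) dt[, random_barcode := ""]
  dedup <- unique(dt, by = c("chrom", "start", "end", "strand",
                             "fixed_barcode", "random_barcode"))
  dedup[, pos := ifelse(strand == "+", start, end - 1L)]
  stranded_coverage(dedup[, .(count = as.numeric(.N)),
                          by = .(chrom, pos, strand)])
}

#' Reads-per-million normalization
#'
#' Scales every value by 1e6 / total signal so the grand total becomes 1e6.
#'
#' @param cov `stranded_coverage`.
#' @return RPM-scaled `stranded_coverage`.
#' @export
rpm_normalize <- function(cov) {
  stopifnot(inherits(cov, "stranded_coverage"))
  if (cov$total_signal <= 0) stop("cannot RPM-normalize empty coverage")
  dt <- data.table::copy(cov$cov)
  dt[, count := count * 1e6 / cov$total_signal]
  stranded_coverage(dt)
}

#' Pool RPM-normalized replicates by per-position averaging
#'
#' Missing positions are treated as zero, so the pooled value at a position
#' is the sum across replicates divided by the number of replicates.
#'
#' @param covs list of `stranded_coverage`, each already RPM-normalized.
#' @return pooled `stranded_coverage`.
#' @export
pool_replicates <- function(covs) {
  if (length(covs) < 1) stop("need at least one replicate")
  stopifnot(all(vapply(covs, inherits, logical(1), "stranded_coverage")))
  dt <- data.table::rbindlist(lapply(covs, function(x) x$cov))
  pooled <- dt[, .(count = sum(count) / length(covs)),
               by = .(chrom, pos, strand)]
  stranded_coverage(pooled)
}

#' Look up coverage values at specific positions
#'
#' @param cov `stranded_coverage`.
#' @param chrom chromosome name.
#' @param positions 0-based positions.
#' @param strand "+" or "-".
#' @return numeric vector (zeros where no signal).
#' @keywords internal
coverage_at <- function(cov, chrom, positions, strand) {
  lookup <- data.table::data.table(chrom = chrom, strand = strand,
                                   pos = as.numeric(positions))
  sub <- cov$cov[lookup, on = c("chrom", "strand", "pos")]
  v <- sub$count
  v[is.na(v)] <- 0
  v
}

#' TSS-anchored profile matrix
#'
#' Extracts a promoters x offsets matrix per strand plane from stranded
#' coverage, flipping minus-strand promoters into TSS-sense orientation:
#' for a minus-strand TSS, offset o reads genomic position TSS - o and the
#' strand planes are swapped, so "sense-positive" is always the
#' transcribed-strand-upstream footprint.
#'
#' @param cov `stranded_coverage`.
#' @param tss data.frame with columns chrom, pos (0-based TSS base),
#'   name, strand.
#' @param w window half-width in bp; offsets run -w..+w.
#' @return object of class `profile_matrix`: list(promoter_ids, offsets,
#'   sense_pos, sense_neg, w).
#' @export
extract_profile_matrix <- function(cov, tss, w) {
  if (w < 1) stop("window half-width must be >= 1")
  tss <- data.table::as.data.table(tss)
  if (!all(tss$strand %in% c("+", "-"))) stop("TSS records must carry strand")
  offsets <- -w:w
  n <- nrow(tss)
  sp <- matrix(0, n, length(offsets),
               dimnames = list(tss$name, offsets))
  sn <- sp
  for (i in seq_len(n)) {
    if (tss$strand[i] == "+") {
      gpos <- tss$pos[i] + offsets
      sp[i, ] <- coverage_at(cov, tss$chrom[i], gpos, "+")
      sn[i, ] <- coverage_at(cov, tss$chrom[i], gpos, "-")
    } else {
      gpos <- tss$pos[i] - offsets
      sp[i, ] <- coverage_at(cov, tss$chrom[i], gpos, "-")
      sn[i, ] <- coverage_at(cov, tss$chrom[i], gpos, "+")
    }
  }
  structure(list(promoter_ids = tss$name, offsets = offsets,
                 sense_pos = sp, sense_neg = sn, w = w),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("profile_matrix:", length(x$promoter_ids), "promoters x offsets [",
      -x$w, ",", x$w, "]\n")
  invisible(x)
}

#' Subset a profile matrix by promoter
#' @param x `profile_matrix`.
#' @param ids promoter ids or logical/integer index.
#' @return `profile_matrix`.
#' @export
subset_profiles <- function(x, ids) {
  if (is.character(ids)) ids <- match(ids, x$promoter_ids)
  structure(list(promoter_ids = x$promoter_ids[ids], offsets = x$offsets,
                 sense_pos = x$sense_pos[ids, , drop = FALSE],
                 sense_neg = x$sense_neg[ids, , drop = FALSE], w = x$w),
            class = "profile_matrix")
}
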