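# File I/O: FASTA (Biostrings), BED6, stranded bedGraph pairs, CTSS tables.
# Coordinates are 0-based half-open in BED/bedGraph, 1-based in CTSS TSVs.

#' Write promoter sequences to FASTA
#' @param seqs named character vector of DNA sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a stranded coverage object as a bedGraph pair
#'
#' One bedGraph per strand, single-base intervals, 0-based half-open.
#'
#' @param cov `stranded_coverage`.
#' @param prefix file prefix; writes `<prefix>_pos.bedGraph` and
#'   `<prefix>_neg.bedGraph`.
#' @export
write_bedgraph_pair <- function(cov, prefix) {
  for (s in c("+", "-")) {
    sub <- cov$cov[strand == s][order(chrom, pos)]
    out <- sub[, .(chrom, start = pos, end = pos + 1L, value = count)]
    f <- paste0(prefix, if (s == "+") "_pos.bedGraph" else "_neg.bedGraph")
    data.table::fwrite(out, f, sep = "\t", col.names = FALSE)
  }
  invisible(prefix)
}

#' Read a stranded bedGraph pair
#' @param prefix as in [write_bedgraph_pair()].
#' @return `stranded_coverage`.
#' @export
read_bedgraph_pair <- function(prefix) {
  parts <- lapply(c("+", "-"), function(s) {
    f <- paste0(prefix, if (s == "+") "_pos.bedGraph" else "_neg.bedGraph")
    if (!file.exists(f) || file.size(f) == 0)
      return(data.table::data.table(chrom = character(), pos = integer(),
                                    strand = character(), count = numeric()))
    dt <- data.table::fread(f, header = FALSE,
                            col.names = c("chrom", "start", "end", "value"))
    # expand multi-base intervals to single bases
    dt[, .(pos = seq.int(start, end - 1L), count = value, strand = s),
       by = .(chrom, rid = seq_len(nrow(dt)))][
         , .(chrom, pos, strand, count)]
  })
  stranded_coverage(data.table::rbindlist(parts))
}

#' Write TSS records as BED6
#'
#' @param tss data.frame with chrom, pos (0-based TSS base), name, strand and
#'   optionally score.
#' @param path output file.
#' @export
write_tss_bed <- function(tss, path) {
  dt <- data.table::as.data.table(tss)
  if (is.null(dt$score)) dt[, score := 0]
  out <- dt[, .(chrom, start = pos, end = pos + 1L, name, score, strand)]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED6 TSS file
#' @param path BED file.
#' @return data.table (chrom, pos, name, score, strand).
#' @export
read_tss_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand"))
  dt[, .(chrom, pos = start, name, score, strand)]
}

#' Write per-replicate CTSS count tables
#'
#' Tab-delimited with header: chrom, pos (1-based), strand, then one count
#' column per replicate.
#'
#' @param ctss data.table with chrom, pos, strand and count columns.
#' @param path output file.
#' @export
write_ctss <- function(ctss, path) {
  data.table::fwrite(ctss, path, sep = "\t")
  invisible(path)
}

#' Read a CTSS table
#' @param path CTSS TSV.
#' @export
read_ctss <- function(path) data.table::fread(path)
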