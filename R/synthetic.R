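# Synthetic promoters with planted ground truth.
#
# Each synthetic promoter occupies its own chromosome (named after the
# promoter) with the TSS at the exact center of an odd-length span. Promoter
# classes are planted by writing a concrete expansion of the class-defining
# IUPAC consensus into its TSS-relative window; "scrubbed" mode re-samples
# the background until no accidental zero-mismatch occurrence of any other
# class-defining element (one mismatch for TATA) survives in its window, so
# the rule-based classifier must recover the planted class exactly.
#
# Stranded footprints are simulated as symmetric Gaussians around each
# protein-DNA contact midpoint: positive-strand stop bases upstream at
# (m - strand_offset), negative-strand stop bases downstream at
# (m + strand_offset). About half the promoters are emitted on the minus
# strand to exercise strand flipping throughout the pipeline.

#' Synthetic study configuration
#'
#' @param n_promoters_per_class promoters per class (>= 1).
#' @param promoter_span odd promoter length in bp; TSS at the center.
#' @param classes promoter classes to generate.
#' @param reads_per_factor stop bases simulated per promoter per factor.
#' @param strand_offset half-distance in bp between the paired
#'   positive/negative strand peaks flanking a contact.
#' @param peak_sd Gaussian spread of stop bases around each strand peak (bp).
#' @param cage_tags_per_promoter CAGE tag scale; a promoter with
#'   cage_expression e receives round(e * cage_tags_per_promoter) tags.
#' @param cage_kernel_sd spread of CAGE tags around the TSS (bp).
#' @param background_rate fraction of stop bases placed uniformly at random.
#' @param minus_strand_frac fraction of promoters emitted on the minus strand.
#' @param seed integer root seed; every generator is deterministic given it.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_promoters_per_class = 100,
                             promoter_span = 601,
                             classes = c("TATA", "DPR", "TCT", "HK"),
                             reads_per_factor = 1000,
                             strand_offset = 4,
                             peak_sd = 2,
                             cage_tags_per_promoter = 1000,
                             cage_kernel_sd = 1,
                             background_rate = 0,
                             minus_strand_frac = 0.5,
                             seed = 1) {
  if (n_promoters_per_class < 1) stop("n_promoters_per_class must be >= 1")
  if (promoter_span %% 2 == 0) stop("promoter_span must be odd")
  if (peak_sd <= 0) stop("peak_sd must be positive")
  if (background_rate < 0 || background_rate > 1)
    stop("background_rate must be in [0,1]")
  structure(list(n_promoters_per_class = as.integer(n_promoters_per_class),
                 promoter_span = as.integer(promoter_span),
                 classes = classes,
                 reads_per_factor = as.integer(reads_per_factor),
                 strand_offset = strand_offset, peak_sd = peak_sd,
                 cage_tags_per_promoter = cage_tags_per_promoter,
                 cage_kernel_sd = cage_kernel_sd,
                 background_rate = background_rate,
                 minus_strand_frac = minus_strand_frac,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# class -> planting recipe; prohibited = elements whose presence would change
# the exclusive classification of the planted class
.class_recipes <- function() {
  list(
    TATA = list(plant = "TATA", prohibited = character(0)),
    DPR  = list(plant = c("INR", "DPR_core"),
                prohibited = c("TATA", "TCT", "Ohler1", "Ohler6", "Ohler7",
                               "DRE")),
    TCT  = list(plant = "TCT", prohibited = "TATA"),
    HK   = list(plant = "HK_core",
                prohibited = c("TATA", "TCT", "MTE", "DPE", "PB"))
  )
}

#' Default factor -> class -> contact-midpoint map
#'
#' TBP contacts are class-specific (a sharp upstream contact near -18 at
#' TATA promoters, a downstream contact near +28 at DPR promoters, an
#' initiator-proximal contact at TCT promoters, diffuse multi-site contacts
#' at HK promoters). The generic "TFIID" subunit carries the canonical
#' five-footprint geometry (-30, -18, +10, +19, +32) at every class, and
#' "polii" pauses at +40.
#'
#' @return nested named list factor -> class -> numeric midpoints.
#' @export
default_contact_map <- function() {
  list(
    TBP = list(TATA = -18, DPR = 28, TCT = 0, HK = c(-40, -20, 0, 20, 40)),
    TFIID = list(TATA = c(-30, -18, 10, 19, 32),
                 DPR = c(-30, -18, 10, 19, 32),
                 TCT = c(-30, -18, 10, 19, 32),
                 HK = c(-30, -18, 10, 19, 32)),
    polii = list(TATA = 40, DPR = 40, TCT = 40, HK = 40)
  )
}

.revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

# plant one element expansion into a base vector at a sampled window start
.plant <- function(bases, spec, tss_index) {
  start <- sample(spec$window_start:spec$window_end, 1L)
  inst <- strsplit(expand_iupac(spec$consensus), "")[[1]]
  idx <- (tss_index + start):(tss_index + start + length(inst) - 1L)
  bases[idx] <- inst
  list(bases = bases, element = spec$name, start = start)
}

#' Generate promoter sequences with planted core promoter elements
#'
#' @param config `synthetic_config`.
#' @param scrubbed logical; re-sample background until no accidental
#'   occurrence of a class-incompatible element survives (capped at 1000
#'   attempts per promoter).
#' @param contact_map factor contact map, see [default_contact_map()].
#' @return list with `seqs` (named character vector, genomic orientation),
#'   `tss` (data.table chrom/pos/name/strand) and `truth` (data.table with
#'   promoter_id, class_label, strand, tss_pos, planted_elements,
#'   cage_expression, half_life_min, and a `contacts` list-column mapping
#'   factor to TSS-relative contact midpoints).
#' @export
generate_promoter_sequences <- function(config, scrubbed = TRUE,
                                        contact_map = default_contact_map()) {
  recipes <- .class_recipes()
  unknown <- setdiff(config$classes, names(recipes))
  if (length(unknown)) stop("unknown class name: ", paste(unknown, collapse = ","))
  specs <- element_specs()
  span <- config$promoter_span
  tss_index <- (span + 1L) %/% 2L
  # widest window must fit
  need <- max(specs$window_end + nchar(specs$consensus)) + 1L
  if (tss_index + need > span || tss_index + min(specs$window_start) < 1L)
    stop("promoter_span too small to contain the widest element window")

  set.seed(config$seed)
  seqs <- character(0); rows <- list()
  for (cls in config$classes) {
    rec <- recipes[[cls]]
    for (i in seq_len(config$n_promoters_per_class)) {
      id <- sprintf("%s_%03d", cls, i)
      minus <- stats::runif(1) < config$minus_strand_frac
      for (attempt in seq_len(1000L)) {
        bases <- sample(c("A", "C", "G", "T"), span, replace = TRUE)
        planted <- list()
        for (p in rec$plant) {
          nm <- switch(p,
            DPR_core = sample(c("MTE", "DPE", "PB"), 1L),
            HK_core  = sample(c("DRE", "Ohler1", "Ohler6", "Ohler7"), 1L),
            p)
          res <- .plant(bases, as.list(specs[name == nm]), tss_index)
          bases <- res$bases
          planted[[length(planted) + 1L]] <- c(res$element, res$start)
        }
        if (!scrubbed || length(rec$prohibited) == 0) break
        sq <- paste(bases, collapse = "")
        dirty <- any(vapply(rec$prohibited, function(nm)
          nrow(scan_element(sq, as.list(specs[name == nm]), tss_index)) > 0,
          logical(1)))
        if (!dirty) break
        if (attempt == 1000L)
          stop("scrubbing failed after 1000 attempts for ", id)
      }
      sense <- paste(bases, collapse = "")
      seqs[id] <- if (minus) .revcomp(sense) else sense
      rows[[id]] <- data.table::data.table(
        promoter_id = id, class_label = cls,
        strand = if (minus) "-" else "+",
        tss_pos = tss_index - 1L,  # 0-based genomic TSS, center of the span
        planted_elements = paste(vapply(planted, function(x)
          paste0(x[1], ":", x[2]), character(1)), collapse = ";"),
        cage_expression = stats::rlnorm(1, meanlog = 0, sdlog = 0.5),
        half_life_min = stats::rlnorm(1, meanlog = log(15), sdlog = 0.8))
    }
  }
  truth <- data.table::rbindlist(rows)
  truth[, contacts := lapply(class_label, function(cl)
    lapply(contact_map, function(fm) fm[[cl]]))]
  tss <- truth[, .(chrom = promoter_id, pos = tss_pos, name = promoter_id,
                   strand = strand)]
  list(seqs = seqs, tss = tss, truth = truth)
}

#' Sense-oriented promoter sequences
#'
#' Reverse-complements minus-strand promoters so that every sequence reads
#' in the direction of transcription with the TSS at the center.
#'
#' @param seqs named genomic-orientation sequences.
#' @param truth truth table with promoter_id and strand.
#' @return named character vector.
#' @export
promoter_sense_sequences <- function(seqs, truth) {
  out <- seqs[truth$promoter_id]
  minus <- truth$strand == "-"
  out[minus] <- .revcomp(out[minus])
  out
}

# sense-relative (offset, strand) -> genomic (pos, strand) for one promoter
.to_genomic <- function(offsets, sense_strand, tss_pos, promoter_strand) {
  if (promoter_strand == "+") {
    list(pos = tss_pos + offsets, strand = sense_strand)
  } else {
    list(pos = tss_pos - offsets,
         strand = ifelse(sense_strand == "+", "-", "+"))
  }
}

#' Simulate stranded stop-base footprints for one factor
#'
#' For each contact midpoint m, positive-strand stops are drawn from
#' Normal(m - strand_offset, peak_sd) and negative-strand stops from
#' Normal(m + strand_offset, peak_sd), rounded to integer offsets and
#' clamped to the promoter span. Signal reads are split as evenly as
#' possible across contacts and strands; a `background_rate` fraction of
#' reads falls uniformly over the span on a random strand.
#'
#' @param truth truth table from [generate_promoter_sequences()].
#' @param config `synthetic_config`.
#' @param factor factor name present in the truth contact map.
#' @param contacts optional override: named list class -> midpoints, or a
#'   numeric vector used for every promoter.
#' @param peak_sd,reads optional per-call overrides of config values. Both
#'   may be named lists keyed by class for class-specific shapes/levels.
#' @return `stranded_coverage` in genomic coordinates.
#' @export
simulate_stranded_footprints <- function(truth, config, factor,
                                         contacts = NULL,
                                         peak_sd = NULL, reads = NULL) {
  set.seed(config$seed + 1000L + sum(utf8ToInt(factor)))
  half <- (config$promoter_span - 1L) %/% 2L
  per_class <- function(x, cls, default) {
    if (is.null(x)) return(default)
    if (is.list(x)) return(x[[cls]])
    x
  }
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    cls <- truth$class_label[i]
    cm <- if (!is.null(contacts)) {
      if (is.list(contacts)) contacts[[cls]] else contacts
    } else truth$contacts[[i]][[factor]]
    if (is.null(cm)) stop("unknown factor: ", factor)
    sd_i <- per_class(peak_sd, cls, config$peak_sd)
    n_i <- per_class(reads, cls, config$reads_per_factor)
    n_bg <- round(config$background_rate * n_i)
    n_sig <- n_i - n_bg
    # split signal across contacts, remainder to the first contacts
    base <- n_sig %/% length(cm)
    n_per <- rep(base, length(cm))
    extra <- n_sig - base * length(cm)
    if (extra > 0) n_per[seq_len(extra)] <- n_per[seq_len(extra)] + 1L
    off <- integer(0); str <- character(0)
    for (j in seq_along(cm)) {
      n_pos <- ceiling(n_per[j] / 2); n_neg <- n_per[j] - n_pos
      off <- c(off,
               round(stats::rnorm(n_pos, cm[j] - config$strand_offset, sd_i)),
               round(stats::rnorm(n_neg, cm[j] + config$strand_offset, sd_i)))
      str <- c(str, rep("+", n_pos), rep("-", n_neg))
    }
    if (n_bg > 0) {
      off <- c(off, sample.int(2L * half + 1L, n_bg, replace = TRUE) - half - 1L)
      str <- c(str, sample(c("+", "-"), n_bg, replace = TRUE))
    }
    off <- pmin(pmax(off, -half), half)
    g <- .to_genomic(off, str, truth$tss_pos[i], truth$strand[i])
    rows[[i]] <- data.table::data.table(chrom = truth$promoter_id[i],
                                        pos = g$pos, strand = g$strand)
  }
  dt <- data.table::rbindlist(rows)
  stranded_coverage(dt[, .(count = as.numeric(.N)),
                       by = .(chrom, pos, strand)])
}

#' Simulate replicated CAGE CTSS tables
#'
#' Tags are multinomial around the TSS with a Gaussian kernel of sd
#' `cage_kernel_sd`; each promoter receives
#' round(cage_expression * cage_tags_per_promoter) tags per replicate, with
#' independent noise between the two replicates. CTSS positions are 1-based
#' and carry the promoter's strand.
#'
#' @param truth truth table.
#' @param config `synthetic_config`.
#' @param n_replicates number of replicates (default 2).
#' @return data.table (chrom, pos, strand, count_rep1, ..., count_repN).
#' @export
simulate_cage <- function(truth, config, n_replicates = 2) {
  if (any(truth$cage_expression <= 0)) stop("cage_expression must be > 0")
  reps <- lapply(seq_len(n_replicates), function(r) {
    set.seed(config$seed + 20000L + r)
    rows <- lapply(seq_len(nrow(truth)), function(i) {
      n <- round(truth$cage_expression[i] * config$cage_tags_per_promoter)
      off <- round(stats::rnorm(n, 0, config$cage_kernel_sd))
      g <- .to_genomic(off, rep("+", n), truth$tss_pos[i], truth$strand[i])
      data.table::data.table(chrom = truth$promoter_id[i], pos = g$pos + 1L,
                             strand = truth$strand[i])
    })
    data.table::rbindlist(rows)[, .(count = .N), by = .(chrom, pos, strand)]
  })
  out <- reps[[1]]
  data.table::setnames(out, "count", "count_rep1")
  for (r in seq_len(n_replicates)[-1]) {
    nm <- paste0("count_rep", r)
    data.table::setnames(reps[[r]], "count", nm)
    out <- merge(out, reps[[r]], by = c("chrom", "pos", "strand"), all = TRUE)
  }
  for (cn in grep("^count_rep", names(out), value = TRUE))
    data.table::set(out, which(is.na(out[[cn]])), cn, 0L)
  data.table::setorder(out, chrom, strand, pos)
  out[]
}

#' Simulate a paused Pol II decay time course
#'
#' Expected signal at time t is s0 * 2^(-t / half_life). In noiseless mode
#' the expected (real-valued) read mass is deposited exactly at the paired
#' strand peaks flanking the pause contact; with Poisson noise, an integer
#' read count is drawn per timepoint and stop bases are sampled as in
#' [simulate_stranded_footprints()].
#'
#' @param truth truth table (must carry positive half_life_min).
#' @param timepoints minutes, must include 0.
#' @param config `synthetic_config`.
#' @param noise "none" or "poisson".
#' @param factor factor whose contact defines the pause position
#'   (default "polii").
#' @return named list of `stranded_coverage`, one per timepoint.
#' @export
simulate_pausing_timecourse <- function(truth, timepoints, config,
                                        noise = c("none", "poisson"),
                                        factor = "polii") {
  noise <- match.arg(noise)
  if (!0 %in% timepoints) stop("timepoints must include 0")
  if (any(truth$half_life_min <= 0)) stop("half_life_min must be positive")
  half <- (config$promoter_span - 1L) %/% 2L
  out <- list()
  for (t in timepoints) {
    set.seed(config$seed + 30000L + as.integer(t))
    rows <- list()
    for (i in seq_len(nrow(truth))) {
      m <- truth$contacts[[i]][[factor]][1]
      s_t <- config$reads_per_factor * 2^(-t / truth$half_life_min[i])
      if (noise == "none") {
        off <- c(m - config$strand_offset, m + config$strand_offset)
        g <- .to_genomic(off, c("+", "-"), truth$tss_pos[i], truth$strand[i])
        rows[[i]] <- data.table::data.table(
          chrom = truth$promoter_id[i], pos = g$pos, strand = g$strand,
          count = s_t / 2)
      } else {
        n <- stats::rpois(1, s_t)
        n_pos <- ceiling(n / 2); n_neg <- n - n_pos
        off <- c(round(stats::rnorm(n_pos, m - config$strand_offset,
                                    config$peak_sd)),
                 round(stats::rnorm(n_neg, m + config$strand_offset,
                                    config$peak_sd)))
        off <- pmin(pmax(off, -half), half)
        g <- .to_genomic(off, c(rep("+", n_pos), rep("-", n_neg)),
                         truth$tss_pos[i], truth$strand[i])
        rows[[i]] <- data.table::data.table(
          chrom = truth$promoter_id[i], pos = g$pos, strand = g$strand
        )[, .(count = as.numeric(.N)), by = .(chrom, pos, strand)]
      }
    }
    out[[as.character(t)]] <- stranded_coverage(data.table::rbindlist(rows))
  }
  out
}

#' Write the planted-truth table as TSV
#'
#' Contact maps are serialized as `factor=pos1,pos2;factor2=...`.
#'
#' @param truth truth table.
#' @param path output file.
#' @export
write_truth <- function(truth, path) {
  out <- data.table::copy(truth)
  out[, contacts := vapply(contacts, function(cm)
    paste(vapply(names(cm), function(f)
      paste0(f, "=", paste(cm[[f]], collapse = ",")), character(1)),
      collapse = ";"), character(1))]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
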