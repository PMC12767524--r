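# Average stranded metaprofiles, footprint contact-midpoint detection from
# paired strand peaks, min-max normalization, and PCA-based grouping of
# factor profiles into modules.

#' Average stranded profile across promoters
#'
#' @param matrix `profile_matrix`.
#' @param factor optional factor label carried through to the result.
#' @return list of class `average_profile`: factor, offsets,
#'   positive_strand, negative_strand.
#' @export
average_profile <- function(matrix, factor = NA_character_) {
  if (length(matrix$promoter_ids) == 0) stop("empty profile matrix")
  structure(list(factor = factor, offsets = matrix$offsets,
                 positive_strand = colMeans(matrix$sense_pos),
                 negative_strand = colMeans(matrix$sense_neg)),
            class = "average_profile")
}

# local maxima above a height floor, greedily enforcing min separation
.find_peaks <- function(y, offsets, min_height_frac, min_separation) {
  floor_h <- min_height_frac * max(y)
  n <- length(y)
  left <- c(-Inf, y[-n]); right <- c(y[-1], -Inf)
  cand <- which(y >= left & y > right & y >= floor_h)
  cand <- cand[order(-y[cand])]
  kept <- integer(0)
  for (i in cand) {
    if (all(abs(offsets[i] - offsets[kept]) >= min_separation))
      kept <- c(kept, i)
  }
  kept <- sort(kept)
  data.table::data.table(offset = offsets[kept], height = y[kept])
}

#' Detect footprint contact midpoints from paired strand peaks
#'
#' Candidate peaks are local maxima of each strand profile at or above
#' `min_height_frac` of that strand's maximum, at least `min_separation` bp
#' apart. Each positive-strand peak pairs with the nearest negative-strand
#' peak strictly downstream within `max_pair_distance` (ties to the higher
#' negative peak); the contact midpoint is the mean of the two peak offsets
#' (half-integers preserved). Unpaired peaks are reported with NA partners.
#'
#' @param profile `average_profile`.
#' @param min_height_frac fraction of the strand maximum (0.2).
#' @param min_separation minimum peak spacing in bp (3).
#' @param max_pair_distance maximum pos->neg peak distance in bp (40).
#' @return data.table (pos_peak_offset, neg_peak_offset, midpoint,
#'   pos_height, neg_height) sorted by midpoint; unpaired rows carry NAs.
#' @export
detect_footprint_midpoints <- function(profile, min_height_frac = 0.2,
                                       min_separation = 3,
                                       max_pair_distance = 40) {
  if (all(profile$positive_strand == 0) && all(profile$negative_strand == 0))
    stop("all-zero profile")
  pp <- .find_peaks(profile$positive_strand, profile$offsets,
                    min_height_frac, min_separation)
  np <- .find_peaks(profile$negative_strand, profile$offsets,
                    min_height_frac, min_separation)
  used_neg <- rep(FALSE, nrow(np))
  rows <- list()
  for (i in seq_len(nrow(pp))) {
    d <- np$offset - pp$offset[i]
    ok <- which(d > 0 & d <= max_pair_distance & !used_neg)
    if (length(ok)) {
      best <- ok[order(d[ok], -np$height[ok])][1]
      used_neg[best] <- TRUE
      rows[[length(rows) + 1]] <- data.table::data.table(
        pos_peak_offset = pp$offset[i], neg_peak_offset = np$offset[best],
        midpoint = (pp$offset[i] + np$offset[best]) / 2,
        pos_height = pp$height[i], neg_height = np$height[best])
    } else {
      rows[[length(rows) + 1]] <- data.table::data.table(
        pos_peak_offset = pp$offset[i], neg_peak_offset = NA_real_,
        midpoint = NA_real_, pos_height = pp$height[i],
        neg_height = NA_real_)
    }
  }
  for (j in which(!used_neg)) {
    rows[[length(rows) + 1]] <- data.table::data.table(
      pos_peak_offset = NA_real_, neg_peak_offset = np$offset[j],
      midpoint = NA_real_, pos_height = NA_real_, neg_height = np$height[j])
  }
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, midpoint, na.last = TRUE)
  out[]
}

#' Min-max normalization to [0, 1]
#'
#' Constant input returns all zeros with attribute `constant = TRUE`.
#'
#' @param x numeric vector, length >= 2.
#' @return normalized vector.
#' @export
minmax_normalize <- function(x) {
  if (length(x) < 2) stop("need at least 2 values")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    out <- rep(0, length(x))
    attr(out, "constant") <- TRUE
    warning("constant input to minmax_normalize; returning zeros")
    return(out)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Group factor profiles into modules by PCA + k-means
#'
#' Each factor's concatenated (positive, negative) strand vectors are
#' min-max normalized, stacked into a factors x features matrix, and
#' subjected to PCA (centered, not variance-scaled). Module ids come from
#' seeded k-means on the first two principal-component coordinates; labels
#' are arbitrary, only the partition is meaningful.
#'
#' @param profiles named list of `average_profile` (>= n_modules entries).
#' @param n_modules number of modules (4).
#' @param seed RNG seed for k-means.
#' @return list(assignments = data.table(factor, module_id), scores = PC
#'   coordinate matrix, explained = per-component explained-variance
#'   ratios).
#' @export
pca_modules <- function(profiles, n_modules = 4, seed = 1) {
  if (length(profiles) < n_modules)
    stop("need at least as many factors as modules")
  feats <- t(vapply(profiles, function(p)
    minmax_normalize(c(p$positive_strand, p$negative_strand)),
    numeric(2 * length(profiles[[1]]$offsets))))
  rownames(feats) <- names(profiles)
  pc <- stats::prcomp(feats, center = TRUE, scale. = FALSE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  set.seed(seed)
  km <- stats::kmeans(scores, centers = n_modules, nstart = 50)
  list(assignments = data.table::data.table(factor = names(profiles),
                                            module_id = km$cluster),
       scores = pc$x, explained = explained)
}
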