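# Summaries of tracks and features over a labeled genome segmentation:
# per-label signal distributions, replication timing, AT content, Jaccard
# overlap between segmentations, and feature-overlap annotation.

#' Construct a labeled genome segmentation
#'
#' @param chrom,start,end interval coordinates (0-based half-open), sorted
#'   and non-overlapping.
#' @param label a label per interval (e.g. "M0".."M11").
#' @return a \code{segmentation} data.frame.
#' @export
segmentation <- function(chrom, start, end, label) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), label = as.character(label),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  validate_intervals(df, where = "segmentation", allow_overlap = FALSE)
  if (any(is.na(df$label))) stop("every interval must be labeled")
  structure(df, class = c("segmentation", "data.frame"))
}

#' Read a BED4 segmentation file
#' @param path BED file with chrom, start, end, label columns.
#' @return a \code{\link{segmentation}}.
#' @export
read_segmentation <- function(path) {
  df <- read_bed(path, n_cols = 4L,
                 col_names = c("chrom", "start", "end", "label"))
  segmentation(df$chrom, df$start, df$end, df$label)
}

#' Write a segmentation as BED4
#' @param seg a \code{\link{segmentation}}.
#' @param path output file.
#' @export
write_segmentation <- function(seg, path) {
  write_bed(as.data.frame(seg)[, c("chrom", "start", "end", "label")], path)
}

# Per-interval base-weighted track means for one segmentation.
interval_track_means <- function(track, seg) {
  iv <- as.data.frame(seg)
  iv$interval_id <- seq_len(nrow(iv))
  average_over_intervals(track, iv)
}

#' Per-label signal distribution of one or more tracks
#'
#' For every (label, track) pair: the base-weighted mean signal over all
#' bases of the label, and the SD across the per-interval means of that
#' label (interval-level SD, as drawn as error bars on segmentation
#' heatmaps). Optional row-relative min-max or z-score rescaling for
#' display.
#'
#' @param tracks a \code{\link{binned_track}} or named list of tracks
#'   (samples).
#' @param seg a \code{\link{segmentation}}.
#' @param rescale "none" (default), "minmax" or "zscore" row-relative
#'   rescaling of the mean matrix.
#' @return list(mean, sd): label x sample matrices. Labels with no covered
#'   bases yield NA rows.
#' @export
signal_distribution <- function(tracks, seg, rescale = c("none", "minmax", "zscore")) {
  rescale <- match.arg(rescale)
  if (inherits(tracks, "binned_track")) tracks <- list(track = tracks)
  labels <- sort(unique(seg$label))
  mean_m <- sd_m <- matrix(NA_real_, nrow = length(labels),
                           ncol = length(tracks),
                           dimnames = list(labels, names(tracks)))
  for (j in seq_along(tracks)) {
    per_int <- interval_track_means(tracks[[j]], seg)
    w <- per_int$covered_bp
    m <- per_int$mean
    for (l in labels) {
      i <- which(seg$label == l & w > 0)
      if (!length(i)) next
      mean_m[l, j] <- sum(m[i] * w[i]) / sum(w[i])
      sd_m[l, j] <- if (length(i) > 1) sd(m[i]) else 0
    }
  }
  if (rescale == "minmax") {
    rng <- apply(mean_m, 1, function(r) diff(range(r, na.rm = TRUE)))
    mean_m <- (mean_m - apply(mean_m, 1, min, na.rm = TRUE)) /
      ifelse(rng > 0, rng, 1)
  } else if (rescale == "zscore") {
    mu <- rowMeans(mean_m, na.rm = TRUE)
    s <- apply(mean_m, 1, sd, na.rm = TRUE)
    mean_m <- (mean_m - mu) / ifelse(s > 0, s, 1)
  }
  list(mean = mean_m, sd = sd_m)
}

#' Per-label replication timing statistics
#'
#' Two-stage summary matching the bigWigAverageOverBed-then-aggregate
#' procedure: first the base-weighted mean RT score of every interval, then
#' the mean and SD across the intervals of each label. Intervals with no RT
#' coverage are excluded and counted.
#'
#' @param seg a \code{\link{segmentation}}.
#' @param rt_track a \code{\link{binned_track}} with units "RT_score".
#' @return data.frame (label, mean_rt, sd_rt, n_intervals, n_excluded).
#' @export
segment_rt <- function(seg, rt_track) {
  per_int <- interval_track_means(rt_track, seg)
  rows <- lapply(sort(unique(seg$label)), function(l) {
    i <- which(seg$label == l)
    covered <- i[per_int$covered_bp[i] > 0]
    m <- per_int$mean[covered]
    data.frame(label = l,
               mean_rt = if (length(m)) mean(m) else NA_real_,
               sd_rt = if (length(m) > 1) sd(m) else if (length(m) == 1) 0 else NA_real_,
               n_intervals = length(covered),
               n_excluded = length(i) - length(covered),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-label AT content
#'
#' (A+T)/(A+C+G+T) over all bases of each label; N bases are excluded from
#' both numerator and denominator. All-N labels give NA.
#'
#' @param seg a \code{\link{segmentation}}.
#' @param genome a named \code{Biostrings::DNAStringSet}.
#' @return data.frame (label, at_fraction, n_bases).
#' @export
segment_at_content <- function(seg, genome) {
  counts <- matrix(0, nrow = length(unique(seg$label)), ncol = 4,
                   dimnames = list(sort(unique(seg$label)), BASES))
  for (r in seq_len(nrow(seg))) {
    sq <- Biostrings::subseq(genome[[seg$chrom[r]]],
                             seg$start[r] + 1L, seg$end[r])
    f <- Biostrings::letterFrequency(sq, BASES)
    counts[seg$label[r], ] <- counts[seg$label[r], ] + as.numeric(f)
  }
  tot <- rowSums(counts)
  data.frame(label = rownames(counts),
             at_fraction = ifelse(tot > 0,
                                  (counts[, "A"] + counts[, "T"]) / tot,
                                  NA_real_),
             n_bases = tot, row.names = NULL, stringsAsFactors = FALSE)
}

#' Jaccard index between two interval sets
#'
#' |intersection bp| / |union bp| after merging book-ended/overlapping
#' intervals within each set (the convention of the standard genome
#' arithmetic utilities). In matrix mode the index is computed for every
#' label pair.
#'
#' @param segA,segB \code{\link{segmentation}}s or plain chrom/start/end
#'   data.frames.
#' @param per_label_pair if TRUE, return a labelA x labelB matrix.
#' @return scalar, or matrix in per-label-pair mode. Empty sets give 0 with
#'   a warning.
#' @export
jaccard <- function(segA, segB, per_label_pair = FALSE) {
  jac <- function(a, b) {
    if (nrow(a) == 0 || nrow(b) == 0) {
      warning("empty interval set: Jaccard = 0 by convention")
      return(0)
    }
    gg <- same_levels(GenomicRanges::reduce(df_to_granges(a)),
                      GenomicRanges::reduce(df_to_granges(b)))
    inter <- sum(IRanges::width(GenomicRanges::intersect(gg[[1]], gg[[2]])))
    uni <- sum(IRanges::width(GenomicRanges::union(gg[[1]], gg[[2]])))
    if (uni == 0) 0 else inter / uni
  }
  if (!per_label_pair) return(jac(segA, segB))
  la <- sort(unique(segA$label)); lb <- sort(unique(segB$label))
  m <- matrix(NA_real_, length(la), length(lb), dimnames = list(la, lb))
  for (i in la) for (j in lb)
    m[i, j] <- jac(segA[segA$label == i, , drop = FALSE],
                   segB[segB$label == j, , drop = FALSE])
  m
}

#' Fraction of each label covered by a feature set
#'
#' Per label: the fraction of its bases covered by at least one feature
#' base (features are merged first, so the result is invariant to splitting
#' feature intervals).
#'
#' @param seg a \code{\link{segmentation}}.
#' @param features data.frame chrom/start/end (0-based half-open).
#' @return data.frame (label, overlap_fraction, label_bp, covered_bp).
#' @export
annotate_overlap <- function(seg, features) {
  fgr <- GenomicRanges::reduce(df_to_granges(features))
  rows <- lapply(sort(unique(seg$label)), function(l) {
    sgr <- GenomicRanges::reduce(df_to_granges(seg[seg$label == l, , drop = FALSE]))
    label_bp <- sum(IRanges::width(sgr))
    gg <- same_levels(sgr, fgr)
    cov_bp <- sum(IRanges::width(GenomicRanges::intersect(gg[[1]], gg[[2]])))
    data.frame(label = l, overlap_fraction = cov_bp / label_bp,
               label_bp = label_bp, covered_bp = cov_bp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
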