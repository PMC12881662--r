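# Binned enrichment tracks and their rescaling to absolute uracil
# probability tracks (p-tracks).

#' Construct a binned genomic track
#'
#' A binned track holds per-bin values over 0-based half-open genomic
#' intervals, sorted and non-overlapping within each chromosome. Units are
#' one of \code{"ratio"} (enrichment over input), \code{"U_per_Mb"}
#' (absolute uracil probability, uracils per million base pairs) or
#' \code{"RT_score"} (replication timing; higher = earlier).
#'
#' @param chrom,start,end interval coordinates (0-based half-open).
#' @param value finite numeric per-bin values; \code{ratio} and
#'   \code{U_per_Mb} values must be non-negative.
#' @param units one of \code{"ratio"}, \code{"U_per_Mb"}, \code{"RT_score"}.
#' @return a \code{binned_track}: a data.frame with columns
#'   \code{chrom,start,end,value} and a \code{units} attribute.
#' @export
binned_track <- function(chrom, start, end, value,
                         units = c("ratio", "U_per_Mb", "RT_score")) {
  units <- match.arg(units)
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   value = as.numeric(value), stringsAsFactors = FALSE)
  o <- order(df$chrom, df$start)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  validate_intervals(df, where = "binned_track", allow_overlap = FALSE)
  if (any(!is.finite(df$value)))
    stop("binned_track: non-finite values")
  if (units != "RT_score" && any(df$value < 0))
    stop("binned_track: negative value not allowed with units '", units, "'")
  structure(df, units = units, class = c("binned_track", "data.frame"))
}

#' @export
print.binned_track <- function(x, ...) {
  cat("binned_track:", nrow(x), "bins,", attr(x, "units"), "units\n")
  print.data.frame(head(as.data.frame(x), 6))
  invisible(x)
}

track_units <- function(track) attr(track, "units")

bin_widths <- function(track) track$end - track$start

# Length-weighted mean of a track's values.
track_mean <- function(track) {
  w <- bin_widths(track)
  sum(track$value * w) / sum(w)
}

#' Read a bedGraph file into a binned track
#'
#' Four whitespace-separated columns (chrom, start, end, value; 0-based
#' half-open). Bins must be sorted and non-overlapping within chromosome;
#' the first offending line is named otherwise.
#'
#' @param path bedGraph file.
#' @inheritParams binned_track
#' @return a \code{\link{binned_track}}.
#' @export
read_bedgraph <- function(path, units = c("ratio", "U_per_Mb", "RT_score")) {
  units <- match.arg(units)
  df <- read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE,
                   comment.char = "#")
  if (ncol(df) < 4) stop("bedGraph needs 4 columns: ", path)
  names(df)[1:4] <- c("chrom", "start", "end", "value")
  validate_intervals(df, where = path, sorted = TRUE, allow_overlap = FALSE)
  binned_track(df$chrom, df$start, df$end, df$value, units = units)
}

#' Write a binned track as bedGraph
#'
#' Lossless round trip with \code{\link{read_bedgraph}}: values are written
#' with full precision using R's default decimal formatting.
#'
#' @param track a \code{\link{binned_track}}.
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  lines <- paste(track$chrom, format(track$start, scientific = FALSE, trim = TRUE),
                 format(track$end, scientific = FALSE, trim = TRUE),
                 vapply(track$value, function(v)
                   format(v, scientific = FALSE, trim = TRUE, digits = 15),
                   character(1)),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Remove bins overlapping excluded regions
#'
#' Drops every bin that overlaps a blacklist or hard-mask interval; the
#' remaining bins are untouched. This mirrors the cleaning applied to
#' enrichment tracks before rescaling, where ENCODE-style blacklisted and
#' assembly hard-masked regions are excluded.
#'
#' @param track a \code{\link{binned_track}}.
#' @param blacklist,hardmask data.frames with chrom/start/end (0-based
#'   half-open), or \code{NULL}.
#' @return the cleaned track; errors if nothing remains.
#' @export
clean_track <- function(track, blacklist = NULL, hardmask = NULL) {
  excl <- rbind(
    if (!is.null(blacklist) && nrow(blacklist)) blacklist[, c("chrom", "start", "end")],
    if (!is.null(hardmask) && nrow(hardmask)) hardmask[, c("chrom", "start", "end")]
  )
  if (is.null(excl) || nrow(excl) == 0) return(track)
  validate_intervals(excl, where = "exclusion intervals", allow_overlap = TRUE)
  hits <- overlaps(df_to_granges(track), df_to_granges(excl))
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop) == nrow(track))
    stop("clean_track: all bins removed, nothing left to normalize")
  out <- track[setdiff(seq_len(nrow(track)), drop), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, units = track_units(track),
            class = c("binned_track", "data.frame"))
}

#' Rescale an enrichment ratio track to a uracil probability track
#'
#' Multiplies the cleaned ratio track by the single scalar that makes its
#' length-weighted mean equal the independently measured global uracil
#' content of the sample (uracils per million base pairs, e.g. ~700 for
#' raltitrexed-treated cells). Excluded regions are assumed to carry the
#' genome-mean uracil frequency and are simply not written; normalization is
#' over the retained bins only. The result is invariant to any positive
#' rescaling of the input ratios.
#'
#' @param ratio_track cleaned \code{\link{binned_track}} with units
#'   \code{"ratio"}.
#' @param content global uracil content, U per million bp (> 0).
#' @return a \code{binned_track} with units \code{"U_per_Mb"} whose
#'   length-weighted mean equals \code{content}.
#' @export
rescale_to_ptrack <- function(ratio_track, content) {
  stopifnot(is.numeric(content), length(content) == 1L, content > 0)
  if (track_units(ratio_track) != "ratio")
    stop("rescale_to_ptrack expects a ratio track")
  m <- track_mean(ratio_track)
  if (m == 0) stop("rescale_to_ptrack: all-zero ratio track, scale undefined")
  binned_track(ratio_track$chrom, ratio_track$start, ratio_track$end,
               ratio_track$value * (content / m), units = "U_per_Mb")
}

#' Average a track over arbitrary intervals
#'
#' Base-pair-weighted mean of the track values over the overlap of each
#' interval with the track bins (average-over-covered-bases semantics, as in
#' bigWigAverageOverBed). Bases with no track coverage are excluded from the
#' mean, not counted as zero; \code{covered_bp} reports how many bases
#' contributed. Intervals with zero coverage get \code{NA} means.
#'
#' @param track a \code{\link{binned_track}}.
#' @param intervals data.frame with chrom/start/end and optionally
#'   \code{interval_id}; 0-based half-open.
#' @return data.frame (interval_id, mean, covered_bp), one row per input
#'   interval in input order.
#' @export
average_over_intervals <- function(track, intervals) {
  validate_intervals(intervals, where = "intervals", allow_overlap = TRUE)
  ids <- intervals$interval_id %||% seq_len(nrow(intervals))
  igr <- df_to_granges(intervals)
  tgr <- df_to_granges(track)
  hits <- overlaps(igr, tgr)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(igr)[q], GenomicRanges::ranges(tgr)[s]))
  wsum <- tapply(ov, q, sum)
  vsum <- tapply(ov * track$value[s], q, sum)
  covered <- numeric(nrow(intervals))
  means <- rep(NA_real_, nrow(intervals))
  idx <- as.integer(names(wsum))
  covered[idx] <- wsum
  means[idx] <- vsum / wsum
  data.frame(interval_id = ids, mean = means, covered_bp = covered,
             stringsAsFactors = FALSE)
}
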