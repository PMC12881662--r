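# Internal helpers shared across modules.

#' @importFrom methods is
#' @importFrom stats rnorm rbeta rlnorm runif sd setNames p.adjust pt
#' @importFrom utils read.table write.table head tail
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 0-based half-open (chrom, start, end) data.frame -> GRanges (1-based closed).
df_to_granges <- function(df, keep = character()) {
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
  for (k in keep) S4Vectors::mcols(gr)[[k]] <- df[[k]]
  gr
}

# findOverlaps with harmonized seqlevels (avoids noisy cross-level warnings
# when one set mentions chromosomes the other does not).
overlaps <- function(gr1, gr2, select = "all") {
  lv <- union(GenomeInfoDb::seqlevels(gr1), GenomeInfoDb::seqlevels(gr2))
  GenomeInfoDb::seqlevels(gr1) <- lv
  GenomeInfoDb::seqlevels(gr2) <- lv
  GenomicRanges::findOverlaps(gr1, gr2, select = select)
}

# Harmonize seqlevels of two GRanges, returning a list of the pair.
same_levels <- function(gr1, gr2) {
  lv <- union(GenomeInfoDb::seqlevels(gr1), GenomeInfoDb::seqlevels(gr2))
  GenomeInfoDb::seqlevels(gr1) <- lv
  GenomeInfoDb::seqlevels(gr2) <- lv
  list(gr1, gr2)
}

granges_to_df <- function(gr, keep = character()) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  for (k in keep) df[[k]] <- S4Vectors::mcols(gr)[[k]]
  df
}

# Read a whitespace-delimited BED-like file into a 0-based data.frame.
read_bed <- function(path, n_cols = 3L,
                     col_names = c("chrom", "start", "end", "name", "score", "strand")) {
  df <- read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE,
                   comment.char = "#")
  if (ncol(df) < n_cols)
    stop("expected at least ", n_cols, " columns in ", path)
  names(df)[seq_len(min(ncol(df), length(col_names)))] <-
    col_names[seq_len(min(ncol(df), length(col_names)))]
  validate_intervals(df, where = path, allow_overlap = TRUE)
  df
}

write_bed <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Check interval frame sanity: numeric bounds, start < end, optional
# sorted/non-overlapping requirement (within chromosome).
validate_intervals <- function(df, where = "intervals", sorted = FALSE,
                               allow_overlap = TRUE) {
  if (!all(c("chrom", "start", "end") %in% names(df)))
    stop(where, ": missing chrom/start/end columns")
  if (any(!is.finite(df$start)) || any(!is.finite(df$end)))
    stop(where, ": non-finite coordinates")
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop(where, ": start >= end at line ", bad[1])
  if (sorted || !allow_overlap) {
    o <- order(df$chrom, df$start)
    if (sorted && !identical(o, seq_len(nrow(df)))) {
      first <- which(o != seq_len(nrow(df)))[1]
      stop(where, ": intervals not sorted (first offending line ", first, ")")
    }
    dfo <- df[o, , drop = FALSE]
    same <- dfo$chrom[-1] == dfo$chrom[-nrow(dfo)]
    ovl <- which(same & dfo$start[-1] < dfo$end[-nrow(dfo)])
    if (!allow_overlap && length(ovl))
      stop(where, ": overlapping intervals (first offending line ",
           o[ovl[1] + 1L], ")")
  }
  invisible(df)
}

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Reverse complement for plain character vectors (any length, ACGTN).
revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(COMPLEMENT[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

SBS_TYPES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

# Canonical 96-channel names, COSMIC-style ordering: substitution class
# outermost, then 5' base, then 3' base, alphabetical.
sbs96_channels <- function() {
  out <- character(0)
  for (s in SBS_TYPES)
    for (p5 in BASES)
      for (p3 in BASES)
        out <- c(out, paste0(p5, "[", s, "]", p3))
  out
}

# 1,536-channel names: substitution, then 5' dinucleotide, then 3' dinucleotide.
sbs1536_channels <- function() {
  dinucs <- as.vector(t(outer(BASES, BASES, paste0)))
  out <- character(0)
  for (s in SBS_TYPES)
    for (p5 in dinucs)
      for (p3 in dinucs)
        out <- c(out, paste0(p5, "[", s, "]", p3))
  out
}

# The 78 strand-agnostic doublet categories. Ten canonical reference
# doublets; alternates differ from the reference at both positions;
# reverse-complement-palindromic references collapse alternate pairs.
DBS_REFS <- c("AC", "AT", "CC", "CG", "CT", "GC", "TA", "TC", "TG", "TT")

dbs78_channels <- function() {
  out <- character(0)
  for (r in DBS_REFS) {
    r1 <- substr(r, 1, 1); r2 <- substr(r, 2, 2)
    alts <- as.vector(t(outer(setdiff(BASES, r1), setdiff(BASES, r2), paste0)))
    if (revcomp_chr(r) == r) {
      alts <- unique(vapply(alts, function(a) min(a, revcomp_chr(a)),
                            character(1), USE.NAMES = FALSE))
    }
    out <- c(out, paste0(r, ">", sort(alts)))
  }
  out
}

# Map an observed ref/alt doublet onto its canonical 78-set label.
canonical_dbs <- function(ref, alt) {
  flip <- !(ref %in% DBS_REFS)
  ref[flip] <- revcomp_chr(ref[flip])
  alt[flip] <- revcomp_chr(alt[flip])
  pal <- revcomp_chr(ref) == ref
  alt[pal] <- pmin(alt[pal], revcomp_chr(alt[pal]))
  paste0(ref, ">", alt)
}
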