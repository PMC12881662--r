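# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately use per-base / per-character enumeration,
# not the package's interval or string machinery.

suppressPackageStartupMessages({
  library(Biostrings)
})

make_track <- function(values, bin = 100, chrom = "chr1", units = "ratio") {
  n <- length(values)
  binned_track(rep(chrom, n), (0:(n - 1)) * bin, (1:n) * bin, values,
               units = units)
}

# Per-base accumulation oracle for interval means over a binned track.
oracle_interval_mean <- function(track, chrom, start, end) {
  vals <- rep(NA_real_, end - start)
  for (i in seq_len(nrow(track))) {
    if (track$chrom[i] != chrom) next
    lo <- max(start, track$start[i]); hi <- min(end, track$end[i])
    if (lo < hi) vals[(lo - start + 1):(hi - start)] <- track$value[i]
  }
  covered <- sum(!is.na(vals))
  list(mean = if (covered) mean(vals, na.rm = TRUE) else NA_real_,
       covered_bp = covered)
}

# Per-base Jaccard oracle over explicit logical vectors.
oracle_jaccard <- function(a, b, genome_len = 10000, chrom = "chr1") {
  cov <- function(df) {
    v <- logical(genome_len)
    for (i in seq_len(nrow(df)))
      if (df$chrom[i] == chrom) v[(df$start[i] + 1):df$end[i]] <- TRUE
    v
  }
  va <- cov(a); vb <- cov(b)
  if (!any(va | vb)) return(0)
  sum(va & vb) / sum(va | vb)
}

# O(n^3) brute-force hairpin enumeration: try every (loop_start, loop_len,
# stem_len) triple explicitly with string comparison of the arms.
oracle_hairpins <- function(seq, min_stem = 4, loop_min = 3, loop_max = 6,
                            wobble = FALSE) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  pair <- function(x, y) {
    ok <- comp[x] == y
    if (wobble) ok <- ok | (x == "G" & y == "T") | (x == "T" & y == "G")
    ok
  }
  res <- list()
  for (i in 1:n) for (L in loop_min:loop_max) {
    best <- 0
    for (k in 1:n) {
      if (i - k < 1 || i + L - 1 + k > n) break
      if (!all(pair(s[(i - k):(i - 1)], rev(s[(i + L):(i + L - 1 + k)]))))
        break
      best <- k
    }
    if (best >= min_stem)
      res[[length(res) + 1]] <- data.frame(loop_start = i, loop_len = L,
                                           stem_len = best,
                                           loop_end = i + L - 1)
  }
  if (!length(res))
    return(data.frame(loop_start = integer(0), loop_len = integer(0),
                      stem_len = integer(0), loop_end = integer(0)))
  do.call(rbind, res)
}

# String-matching oracle for 96-channel assignment: look the trinucleotide
# up in the raw genome string, reverse-complement by hand when the
# reference base is a purine.
oracle_channel96 <- function(chrom, pos0, alt, genome_chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  s <- genome_chars[[chrom]]
  tri <- s[(pos0):(pos0 + 2)]          # pos0 is 0-based => center at pos0+1
  ref <- tri[2]
  if (ref %in% c("G", "A")) {
    tri <- rev(unname(comp[tri]))
    ref <- tri[2]
    alt <- unname(comp[alt])
  }
  paste0(tri[1], "[", ref, ">", alt, "]", tri[3])
}

# Hand-computed Welch statistic (independent of stats::t.test).
oracle_welch_p <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * pt(-abs(t), df)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Deterministic toy genome used by variant/spectra tests.
toy_genome <- function(seed = 42, len = 50000) {
  set.seed(seed)
  g <- Biostrings::DNAStringSet(c(chr1 = random_dna(len),
                                  chr2 = random_dna(len)))
  g
}

genome_chars <- function(genome)
  lapply(as.list(as.character(genome)), function(s) strsplit(s, "")[[1]])
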