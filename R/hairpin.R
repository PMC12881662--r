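# Stem-loop (hairpin) potential in the local sequence context of
# substitutions: APOBEC3A/B preferentially deaminate cytosines presented in
# short hairpin loops, so loop-located C>T calls are tallied separately.

#' Extract the +/- flank sequence context of each variant
#'
#' Returns the uppercase (2*flank + 1)-nt window centered on the reference
#' base of each single-base substitution. Variants closer than \code{flank}
#' to a chromosome end, or whose window contains N, are skipped and
#' counted.
#'
#' @param vset a \code{\link{variant_set}} (SNV records only are used).
#' @param genome a named \code{Biostrings::DNAStringSet}.
#' @param flank half-window size in nt (default 15).
#' @return data.frame (chrom, pos, ref, alt, context, center) where
#'   \code{center} is the 1-based index of the variant base within
#'   \code{context}; skipped records are absent, their number in attribute
#'   \code{n_skipped}.
#' @export
extract_context <- function(vset, genome, flank = 15) {
  v <- vset[is_snv(vset), , drop = FALSE]
  chrlen <- setNames(Biostrings::width(genome), names(genome))
  p1 <- v$pos + 1L
  ok <- p1 - flank >= 1L & p1 + flank <= chrlen[v$chrom]
  ctx <- rep(NA_character_, nrow(v))
  for (ch in unique(v$chrom[ok])) {
    i <- which(ok & v$chrom == ch)
    ctx[i] <- toupper(as.character(Biostrings::extractAt(
      genome[[ch]], IRanges::IRanges(p1[i] - flank, p1[i] + flank))))
  }
  ok <- ok & !is.na(ctx) & !grepl("N", ctx)
  out <- data.frame(chrom = v$chrom[ok], pos = v$pos[ok], ref = v$ref[ok],
                    alt = v$alt[ok], context = ctx[ok],
                    center = flank + 1L, stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- nrow(v) - nrow(out)
  out
}

#' Enumerate stem-loop structures in a sequence window
#'
#' Finds every hairpin whose stem arms are exact reverse-complement matches
#' of length >= \code{min_stem} flanking a loop of \code{loop_min} to
#' \code{loop_max} nt, anywhere in the window. Stems are reported at their
#' maximal extension per (loop position, loop length), so sub-stems are not
#' double counted. Pairing is Watson-Crick by default; \code{wobble = TRUE}
#' additionally allows G:T pairs.
#'
#' @param seq a character string over A/C/G/T.
#' @param min_stem minimum stem length, nt (default 4).
#' @param loop_min,loop_max loop length bounds, nt (defaults 3 and 6).
#' @param wobble allow G:T wobble pairs (default FALSE).
#' @return data.frame (loop_start, loop_len, stem_len, loop_end); local
#'   1-based coordinates, loop spans [loop_start, loop_end].
#' @export
find_hairpins <- function(seq, min_stem = 4, loop_min = 3, loop_max = 6,
                          wobble = FALSE) {
  s <- strsplit(toupper(seq), "")[[1]]
  if (!all(s %in% BASES)) stop("sequence must be over A/C/G/T")
  n <- length(s)
  pairs_ok <- function(x, y) {
    wc <- COMPLEMENT[x] == y
    if (!wobble) return(wc)
    wc | (x == "G" & y == "T") | (x == "T" & y == "G")
  }
  out <- list()
  for (L in loop_min:loop_max) {
    # loop occupies [i, i+L-1]; arms pair (i-1-t, i+L+t)
    for (i in seq_len(n)) {
      if (i - min_stem < 1 || i + L - 1 + min_stem > n) next
      k <- 0L
      while (i - 1L - k >= 1L && i + L + k <= n &&
             pairs_ok(s[i - 1L - k], s[i + L + k])) k <- k + 1L
      if (k >= min_stem)
        out[[length(out) + 1]] <- c(i, L, k)
    }
  }
  if (!length(out))
    return(data.frame(loop_start = integer(0), loop_len = integer(0),
                      stem_len = integer(0), loop_end = integer(0)))
  m <- do.call(rbind, out)
  data.frame(loop_start = m[, 1], loop_len = m[, 2], stem_len = m[, 3],
             loop_end = m[, 1] + m[, 2] - 1L)
}

#' Is the variant base inside a predicted loop?
#'
#' @param center_idx 1-based index of the variant base in the window.
#' @param hairpins output of \code{\link{find_hairpins}} on the same window.
#' @return TRUE iff the center lies within the loop span of any hairpin.
#' @export
classify_loop_position <- function(center_idx, hairpins) {
  nrow(hairpins) > 0 &&
    any(hairpins$loop_start <= center_idx & center_idx <= hairpins$loop_end)
}

#' C-to-T percentages in all, loop-located and clustered contexts
#'
#' For each context set (all SBS; SBS whose variant base falls in a
#' predicted hairpin loop; SBS belonging to mutation clusters) the
#' percentage of C>T transitions among all substitutions of that set is
#' reported. Empty context sets give \code{NA}.
#'
#' @param vset a classified \code{\link{variant_set}}.
#' @param genome a named \code{DNAStringSet}.
#' @param cluster_table output of \code{\link{cluster_variants}} on the same
#'   set (its \code{variants} element), or NULL to skip the clustered
#'   context.
#' @param flank,min_stem,loop_min,loop_max,wobble hairpin parameters, see
#'   \code{\link{find_hairpins}}.
#' @return list(pct_ctot_all, pct_ctot_loop, pct_ctot_clustered, n_all,
#'   n_loop, n_clustered).
#' @export
loop_context_fractions <- function(vset, genome, cluster_table = NULL,
                                   flank = 15, min_stem = 4, loop_min = 3,
                                   loop_max = 6, wobble = FALSE) {
  if (!"sbs_type" %in% names(vset)) stop("run classify_sbs() first")
  pct <- function(sub) {
    if (nrow(sub) == 0) return(NA_real_)
    100 * mean(sub$sbs_type == "C>T")
  }
  ctx <- extract_context(vset, genome, flank = flank)
  in_loop <- vapply(seq_len(nrow(ctx)), function(i) {
    hp <- find_hairpins(ctx$context[i], min_stem = min_stem,
                        loop_min = loop_min, loop_max = loop_max,
                        wobble = wobble)
    classify_loop_position(ctx$center[i], hp)
  }, logical(1))
  key <- function(d) paste(d$chrom, d$pos)
  loop_keys <- key(ctx)[in_loop]
  loop_set <- vset[key(vset) %in% loop_keys, , drop = FALSE]
  clustered_set <- NULL
  if (!is.null(cluster_table)) {
    cl <- cluster_table[!is.na(cluster_table$cluster_id), , drop = FALSE]
    clustered_set <- vset[key(vset) %in% key(cl), , drop = FALSE]
  }
  list(pct_ctot_all = pct(vset),
       pct_ctot_loop = pct(loop_set),
       pct_ctot_clustered = if (is.null(clustered_set)) NA_real_
                            else pct(clustered_set),
       n_all = nrow(vset), n_loop = nrow(loop_set),
       n_clustered = if (is.null(clustered_set)) NA_integer_
                     else nrow(clustered_set))
}
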