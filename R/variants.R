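# Somatic variant sets: VCF reading/filtering, substitution classification,
# allele-frequency-weighted spectra fractions, intermutational distances,
# cluster detection, and stratification by replication timing / segments.

#' Construct a variant set
#'
#' @param chrom,pos chromosome and 0-based position of the substituted base
#'   (VCF positions are 1-based and converted on read).
#' @param ref,alt reference and alternate alleles (upper case).
#' @param af allele frequency in [0, 1]; \code{NA} allowed (such records are
#'   excluded from weighted statistics).
#' @param filter character vector of FILTER labels per record
#'   (";"-separated string, e.g. "PASS" or "germline;slippage").
#' @return a \code{variant_set} data.frame, sorted by chrom then pos.
#' @export
variant_set <- function(chrom, pos, ref, alt, af = NA_real_, filter = "PASS") {
  df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   ref = toupper(as.character(ref)),
                   alt = toupper(as.character(alt)),
                   af = as.numeric(af), filter = as.character(filter),
                   stringsAsFactors = FALSE)
  if (any(!is.na(df$af) & (df$af < 0 | df$af > 1)))
    stop("allele frequency outside [0, 1]")
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("variant_set", "data.frame"))
}

as_variant_set <- function(df) {
  structure(df[order(df$chrom, df$pos), , drop = FALSE],
            class = c("variant_set", "data.frame"))
}

is_snv <- function(vset) nchar(vset$ref) == 1 & nchar(vset$alt) == 1 &
  vset$ref %in% BASES & vset$alt %in% BASES

#' Read a VCF into a variant set
#'
#' Uses \pkg{VariantAnnotation}; multi-allelic records are split into
#' per-allele records before anything else. Allele frequency is taken from
#' INFO/AF when present, else FORMAT/AF of the first sample, else derived
#' from FORMAT/AD as alt/(ref+alt); records without any AF source keep
#' \code{NA}.
#'
#' @param path VCF 4.x file (plain text or bgzipped).
#' @return a \code{\link{variant_set}}.
#' @export
read_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  af <- rep(NA_real_, length(vcf))
  info <- VariantAnnotation::info(vcf)
  if ("AF" %in% names(info)) {
    v <- info$AF
    if (is.list(v) || methods::is(v, "List"))
      v <- vapply(v, function(x) if (length(x)) as.numeric(x[1]) else NA_real_,
                  numeric(1))
    af <- as.numeric(v)
  } else {
    gen <- VariantAnnotation::geno(vcf)
    if ("AF" %in% names(gen)) {
      v <- gen$AF[, 1]
      if (is.list(v))
        v <- vapply(v, function(x) if (length(x)) as.numeric(x[1]) else NA_real_,
                    numeric(1))
      af <- as.numeric(v)
    } else if ("AD" %in% names(gen)) {
      ad <- gen$AD
      if (is.array(ad) && length(dim(ad)) == 3) {
        # expand() turns Number=R fields into variant x sample x allele
        ref_d <- as.numeric(ad[, 1, 1]); alt_d <- as.numeric(ad[, 1, 2])
        tot <- ref_d + alt_d
        af <- ifelse(!is.na(tot) & tot > 0, alt_d / tot, NA_real_)
      } else {
        af <- vapply(ad[, 1], function(x) {
          if (length(x) >= 2 && sum(x[1:2]) > 0) x[2] / (x[1] + x[2])
          else NA_real_
        }, numeric(1))
      }
    }
  }
  filt <- as.character(rr$FILTER)
  filt[is.na(filt) | filt == "."] <- "PASS"
  variant_set(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr) - 1L,
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    af = af,
    filter = filt
  )
}

#' Filter variants by FILTER labels
#'
#' A record is removed iff its FILTER label set intersects
#' \code{excluded_labels}; PASS records are always retained. This reproduces
#' post-calling filtering where weak-evidence, artifact, slippage, germline
#' and base-quality calls are discarded.
#'
#' @param vset a \code{\link{variant_set}}.
#' @param excluded_labels labels whose presence excludes a record.
#' @return the filtered \code{variant_set}.
#' @export
filter_variants <- function(vset,
                            excluded_labels = c("weak_evidence", "normal_artifact",
                                                "slippage", "germline", "base_qual")) {
  labels <- strsplit(vset$filter, ";", fixed = TRUE)
  drop <- vapply(labels, function(l) any(l %in% excluded_labels), logical(1))
  n_missing_af <- sum(!drop & is.na(vset$af))
  if (n_missing_af > 0)
    message("filter_variants: ", n_missing_af,
            " retained record(s) without allele frequency")
  as_variant_set(vset[!drop, , drop = FALSE])
}

#' Classify single-base substitutions on the pyrimidine strand
#'
#' Purine-reference records are mapped by reverse complement (G>A becomes
#' C>T) so exactly six substitution classes remain; tri- (+/-1) and
#' penta-nucleotide (+/-2) contexts are reported on the pyrimidine strand.
#' A reference-allele mismatch with the genome raises an error, guarding
#' against coordinate-convention drift. Contexts running off a chromosome
#' end, or containing N, yield \code{NA} contexts (the type is still
#' assigned).
#'
#' @param vset a \code{\link{variant_set}} (non-SNV records are ignored
#'   with a message and excluded from the result).
#' @param genome a named \code{Biostrings::DNAStringSet}.
#' @return the SNV subset of \code{vset} with added columns \code{sbs_type}
#'   ("C>A".."T>G"), \code{tri} ("A[C>T]G" style), \code{penta}, and
#'   \code{channel96} (identical to \code{tri}).
#' @export
classify_sbs <- function(vset, genome) {
  snv <- is_snv(vset)
  n_skip <- sum(!snv)
  if (n_skip > 0)
    message("classify_sbs: ", n_skip, " non-SNV record(s) excluded")
  v <- vset[snv, , drop = FALSE]
  if (nrow(v) == 0) return(as_variant_set(cbind(v, sbs_type = character(0),
                                                tri = character(0),
                                                penta = character(0))))
  chrlen <- setNames(Biostrings::width(genome), names(genome))
  ref_g <- character(nrow(v))
  tri_raw <- penta_raw <- rep(NA_character_, nrow(v))
  for (ch in unique(v$chrom)) {
    i <- which(v$chrom == ch)
    seq <- genome[[ch]]
    p1 <- v$pos[i] + 1L  # 1-based center
    ref_g[i] <- as.character(Biostrings::extractAt(
      seq, IRanges::IRanges(p1, p1)))
    ok3 <- p1 - 1L >= 1L & p1 + 1L <= chrlen[ch]
    tri_raw[i[ok3]] <- as.character(Biostrings::extractAt(
      seq, IRanges::IRanges(p1[ok3] - 1L, p1[ok3] + 1L)))
    ok5 <- p1 - 2L >= 1L & p1 + 2L <= chrlen[ch]
    penta_raw[i[ok5]] <- as.character(Biostrings::extractAt(
      seq, IRanges::IRanges(p1[ok5] - 2L, p1[ok5] + 2L)))
  }
  if (any(ref_g != v$ref))
    stop("classify_sbs: reference allele mismatch with genome at ",
         v$chrom[ref_g != v$ref][1], ":", v$pos[ref_g != v$ref][1],
         " (0-based); check coordinate conventions")
  purine <- v$ref %in% c("A", "G")
  ref_p <- ifelse(purine, COMPLEMENT[v$ref], v$ref)
  alt_p <- ifelse(purine, COMPLEMENT[v$alt], v$alt)
  tri <- ifelse(purine & !is.na(tri_raw), revcomp_chr(tri_raw), tri_raw)
  penta <- ifelse(purine & !is.na(penta_raw), revcomp_chr(penta_raw), penta_raw)
  tri[!is.na(tri) & grepl("N", tri)] <- NA
  penta[!is.na(penta) & grepl("N", penta)] <- NA
  v$sbs_type <- paste0(ref_p, ">", alt_p)
  v$tri <- ifelse(is.na(tri), NA,
                  paste0(substr(tri, 1, 1), "[", v$sbs_type, "]",
                         substr(tri, 3, 3)))
  v$penta <- ifelse(is.na(penta), NA,
                    paste0(substr(penta, 1, 2), "[", v$sbs_type, "]",
                           substr(penta, 4, 5)))
  as_variant_set(v)
}

#' Allele-frequency-weighted fractions of the six substitution types
#'
#' The occurrence of a type is the sum of allele frequencies over its
#' records; fractions divide by the total occurrence and sum to one.
#' Records with missing AF are excluded from the weighted statistics and
#' counted. With \code{weighted = FALSE} every record counts 1, reducing to
#' plain count fractions.
#'
#' @param vset a classified \code{\link{variant_set}} (needs
#'   \code{sbs_type}; run \code{\link{classify_sbs}} first).
#' @param weighted weight records by allele frequency (default TRUE).
#' @return data.frame (sbs_type, occurrence, fraction) over the six classes
#'   in canonical order.
#' @export
weighted_sbs_fractions <- function(vset, weighted = TRUE) {
  if (!"sbs_type" %in% names(vset))
    stop("run classify_sbs() first")
  w <- if (weighted) vset$af else rep(1, nrow(vset))
  keep <- !is.na(w)
  if (weighted && sum(!keep) > 0)
    message("weighted_sbs_fractions: ", sum(!keep),
            " record(s) without AF excluded")
  if (!any(keep)) stop("no records with allele frequency")
  occ <- tapply(w[keep], factor(vset$sbs_type[keep], levels = SBS_TYPES), sum)
  occ[is.na(occ)] <- 0
  data.frame(sbs_type = SBS_TYPES, occurrence = as.numeric(occ),
             fraction = as.numeric(occ) / sum(occ), stringsAsFactors = FALSE)
}

#' Intermutational distances between neighboring same-type events
#'
#' Gaps between consecutive substitutions of the given type on the same
#' chromosome, in input coordinate units (bp). Chromosomes with fewer than
#' two events contribute none. Short-IMD modes (a few to tens of bp)
#' indicate kataegis-like clustering.
#'
#' @param vset a classified \code{\link{variant_set}}.
#' @param type_filter substitution type to consider (default "C>T"); use
#'   \code{NULL} for all records.
#' @return data.frame (chrom, pos_from, pos_to, imd), sorted.
#' @export
intermutational_distances <- function(vset, type_filter = "C>T") {
  v <- vset
  if (!is.null(type_filter)) {
    if (!"sbs_type" %in% names(v)) stop("run classify_sbs() first")
    v <- v[v$sbs_type %in% type_filter, , drop = FALSE]
  }
  v <- v[order(v$chrom, v$pos), , drop = FALSE]
  out <- lapply(split(v, v$chrom), function(d) {
    if (nrow(d) < 2) return(NULL)
    data.frame(chrom = d$chrom[-1], pos_from = d$pos[-nrow(d)],
               pos_to = d$pos[-1], imd = diff(d$pos),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(chrom = character(0), pos_from = numeric(0),
                      pos_to = numeric(0), imd = numeric(0))
  rownames(out) <- NULL
  out
}

#' Detect clustered mutations by an intermutational-distance run scan
#'
#' Maximal runs of consecutive same-chromosome variants whose successive
#' gaps are all <= \code{max_imd}, of length >= \code{min_size}. Membership
#' is deterministic. The threshold is a tool parameter, not a biological
#' constant: kataegis-like clusters show gaps of a few to several tens of
#' nucleotides.
#'
#' @param vset a \code{\link{variant_set}} (pre-filter by type if desired,
#'   or pass \code{type_filter}).
#' @param max_imd maximum gap within a cluster (bp, default 100).
#' @param min_size minimum number of variants per cluster (default 2).
#' @param type_filter optional substitution type restriction (needs
#'   \code{sbs_type}).
#' @return list with \code{variants} (input rows with \code{cluster_id},
#'   \code{NA} when unclustered) and \code{clusters} (cluster_id, chrom,
#'   start, end, n).
#' @export
cluster_variants <- function(vset, max_imd = 100, min_size = 2,
                             type_filter = NULL) {
  v <- vset
  if (!is.null(type_filter)) {
    if (!"sbs_type" %in% names(v)) stop("run classify_sbs() first")
    v <- v[v$sbs_type %in% type_filter, , drop = FALSE]
  }
  v <- v[order(v$chrom, v$pos), , drop = FALSE]
  if (nrow(v) == 0)
    return(list(variants = v,
                clusters = data.frame(cluster_id = integer(0), chrom = character(0),
                                      start = numeric(0), end = numeric(0),
                                      n = integer(0))))
  new_run <- c(TRUE, v$chrom[-1] != v$chrom[-nrow(v)] |
                 diff(v$pos) > max_imd)
  run_id <- cumsum(new_run)
  run_size <- table(run_id)
  keep_run <- as.integer(names(run_size)[run_size >= min_size])
  v$cluster_id <- ifelse(run_id %in% keep_run,
                         match(run_id, keep_run), NA_integer_)
  cl <- v[!is.na(v$cluster_id), , drop = FALSE]
  clusters <- if (nrow(cl)) {
    agg <- lapply(split(cl, cl$cluster_id), function(d)
      data.frame(cluster_id = d$cluster_id[1], chrom = d$chrom[1],
                 start = min(d$pos), end = max(d$pos) + 1,
                 n = nrow(d), stringsAsFactors = FALSE))
    out <- do.call(rbind, agg); rownames(out) <- NULL; out
  } else data.frame(cluster_id = integer(0), chrom = character(0),
                    start = numeric(0), end = numeric(0), n = integer(0))
  list(variants = v, clusters = clusters)
}

#' Detect double-base substitutions and label their 78 canonical categories
#'
#' Two single-base substitutions at adjacent positions (1-bp offset) on the
#' same chromosome are merged left-to-right greedily into one doublet;
#' explicit 2-bp MNP records are accepted as doublets directly. Categories
#' are strand-agnostic: a doublet and its reverse complement map to the same
#' label (GG>AA collapses to CC>TT).
#'
#' @param vset a \code{\link{variant_set}}.
#' @return data.frame (chrom, pos, ref, alt, af, dbs78) with one row per
#'   doublet; \code{af} is the mean of the constituent AFs for merged pairs.
#' @export
detect_dbs <- function(vset) {
  v <- vset[order(vset$chrom, vset$pos), , drop = FALSE]
  mnp <- nchar(v$ref) == 2 & nchar(v$alt) == 2
  snv <- is_snv(v)
  s <- v[snv, , drop = FALSE]
  out <- list()
  if (nrow(s) >= 2) {
    used <- rep(FALSE, nrow(s))
    adjacent <- which(s$chrom[-1] == s$chrom[-nrow(s)] & diff(s$pos) == 1)
    for (i in adjacent) {
      if (used[i] || used[i + 1]) next  # greedy left-to-right pairing
      used[c(i, i + 1)] <- TRUE
      out[[length(out) + 1]] <- data.frame(
        chrom = s$chrom[i], pos = s$pos[i],
        ref = paste0(s$ref[i], s$ref[i + 1]),
        alt = paste0(s$alt[i], s$alt[i + 1]),
        af = mean(c(s$af[i], s$af[i + 1])), stringsAsFactors = FALSE)
    }
    n_rem <- sum(!used[unique(c(adjacent, adjacent + 1))])
    if (n_rem > 0)
      message("detect_dbs: ", n_rem,
              " adjacent record(s) left unpaired by greedy pairing")
  }
  if (any(mnp))
    out[[length(out) + 1]] <-
      v[mnp, c("chrom", "pos", "ref", "alt", "af"), drop = FALSE]
  if (!length(out))
    return(data.frame(chrom = character(0), pos = numeric(0),
                      ref = character(0), alt = character(0),
                      af = numeric(0), dbs78 = character(0)))
  d <- do.call(rbind, out)
  d <- d[order(d$chrom, d$pos), , drop = FALSE]
  d$dbs78 <- canonical_dbs(d$ref, d$alt)
  rownames(d) <- NULL
  d
}

#' Stratify variants by replication timing
#'
#' Assigns each variant to the replication-timing stratum of its bin:
#' early (score > upper threshold), middle (between the thresholds,
#' inclusive), late (score < lower threshold); variants falling outside the
#' track are reported as unassigned. Per-stratum AF-weighted substitution
#' fractions are computed where possible.
#'
#' @param vset a classified \code{\link{variant_set}}.
#' @param rt_track a \code{\link{binned_track}} with units "RT_score".
#' @param thresholds c(upper, lower), default c(2.5, -2.5); boundary values
#'   belong to "middle".
#' @return list with \code{variants} (added \code{rt_stratum} column),
#'   \code{counts} (named early/middle/late/unassigned) and
#'   \code{fractions} (stratum x sbs_type fraction table, NA rows where a
#'   stratum has no weighted records).
#' @export
stratify_by_rt <- function(vset, rt_track, thresholds = c(2.5, -2.5)) {
  up <- max(thresholds); lo <- min(thresholds)
  vgr <- GenomicRanges::GRanges(vset$chrom,
                                IRanges::IRanges(vset$pos + 1L, vset$pos + 1L))
  hits <- overlaps(vgr, df_to_granges(rt_track), select = "first")
  score <- rep(NA_real_, nrow(vset))
  score[!is.na(hits)] <- rt_track$value[hits[!is.na(hits)]]
  stratum <- rep("unassigned", nrow(vset))
  stratum[!is.na(score) & score > up] <- "early"
  stratum[!is.na(score) & score <= up & score >= lo] <- "middle"
  stratum[!is.na(score) & score < lo] <- "late"
  v <- vset
  v$rt_stratum <- stratum
  strata <- c("early", "middle", "late", "unassigned")
  counts <- setNames(vapply(strata, function(s) sum(stratum == s), numeric(1)),
                     strata)
  fractions <- lapply(c("early", "middle", "late"), function(s) {
    sub <- v[stratum == s, , drop = FALSE]
    if (nrow(sub) == 0 || all(is.na(sub$af)))
      return(setNames(rep(NA_real_, 6), SBS_TYPES))
    fr <- weighted_sbs_fractions(sub)
    setNames(fr$fraction, fr$sbs_type)
  })
  fractions <- do.call(rbind, fractions)
  rownames(fractions) <- c("early", "middle", "late")
  list(variants = v, counts = counts, fractions = fractions)
}

#' Per-segment C-to-T fraction table
#'
#' Assigns variants to labeled genome segments by position and computes the
#' AF-weighted C>T fraction (and full six-type fractions) per label. Labels
#' with zero weighted occurrence get \code{NA}; variants covered by no
#' segment are counted as unassigned.
#'
#' @param vset a classified \code{\link{variant_set}}.
#' @param segmentation a \code{\link{segmentation}} (chrom, start, end,
#'   label).
#' @return list with \code{table} (label, n, ctot_fraction) and
#'   \code{unassigned} count.
#' @export
fractions_by_segment <- function(vset, segmentation) {
  vgr <- GenomicRanges::GRanges(vset$chrom,
                                IRanges::IRanges(vset$pos + 1L, vset$pos + 1L))
  hits <- overlaps(vgr, df_to_granges(segmentation), select = "first")
  lab <- rep(NA_character_, nrow(vset))
  lab[!is.na(hits)] <- segmentation$label[hits[!is.na(hits)]]
  labels <- sort(unique(segmentation$label))
  rows <- lapply(labels, function(l) {
    sub <- vset[!is.na(lab) & lab == l, , drop = FALSE]
    ctot <- NA_real_
    if (nrow(sub) > 0 && any(!is.na(sub$af)) && sum(sub$af, na.rm = TRUE) > 0) {
      fr <- weighted_sbs_fractions(sub)
      ctot <- fr$fraction[fr$sbs_type == "C>T"]
    }
    data.frame(label = l, n = nrow(sub), ctot_fraction = ctot,
               stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows), unassigned = sum(is.na(lab)))
}
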