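# Synthetic-data generators with known ground truth. They emulate the
# statistical structure of drug-induced uracil-DNA-seq studies --
# segmentation-correlated enrichment with replicate noise, replication
# timing profiles, APOBEC-like TC-context C>T variants with short
# intermutational distances and CC>TT doublets -- so that every downstream
# stage of the package is testable without external data. Generator
# parameters are fixtures, not claims about any particular experiment.

GENE_CLASSES <- c("protein_coding", "pseudogene", "lncRNA", "miRNA", "IG",
                  "TR", "snRNA", "snoRNA", "sRNA", "other")

#' Generate a random genome
#'
#' I.i.d. bases at the requested GC fraction; optionally a fraction of each
#' chromosome is hard-masked as runs of N, emitted as BED-style intervals.
#' Identical seed and parameters give byte-identical output.
#'
#' @param chrom_lengths named integer vector, chromosome -> length in bp
#'   (each >= 10,000).
#' @param gc_fraction genome GC content in [0, 1] (default 0.41,
#'   human-like).
#' @param hardmask_fraction approximate fraction of each chromosome masked
#'   as N runs (default 0).
#' @param seed RNG seed.
#' @param mask_run_len length of each masked run, bp (default 1000).
#' @param out_dir optional directory: writes genome.fa, chrom.sizes and
#'   hardmask.bed.
#' @return list(genome = DNAStringSet, chrom_sizes = data.frame,
#'   hardmask = data.frame chrom/start/end).
#' @export
generate_genome <- function(chrom_lengths, gc_fraction = 0.41,
                            hardmask_fraction = 0, seed = 1,
                            mask_run_len = 1000, out_dir = NULL) {
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == ""))
    stop("chrom_lengths must be named")
  if (any(chrom_lengths < 10000))
    stop("chromosome lengths must be >= 10,000 bp")
  stopifnot(gc_fraction >= 0, gc_fraction <= 1,
            hardmask_fraction >= 0, hardmask_fraction <= 1)
  with_seed(seed, {
    probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
               G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
    seqs <- character(length(chrom_lengths))
    masks <- list()
    for (k in seq_along(chrom_lengths)) {
      n <- chrom_lengths[k]
      s <- sample(BASES, n, replace = TRUE, prob = probs)
      if (hardmask_fraction > 0) {
        n_runs <- ceiling(hardmask_fraction * n / mask_run_len)
        starts <- sort(sample.int(n - mask_run_len, n_runs))
        iv <- IRanges::reduce(IRanges::IRanges(starts, width = mask_run_len))
        for (r in seq_along(iv))
          s[IRanges::start(iv)[r]:IRanges::end(iv)[r]] <- "N"
        masks[[length(masks) + 1]] <- data.frame(
          chrom = names(chrom_lengths)[k],
          start = IRanges::start(iv) - 1L, end = IRanges::end(iv),
          stringsAsFactors = FALSE)
      }
      seqs[k] <- paste(s, collapse = "")
    }
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- names(chrom_lengths)
    hardmask <- if (length(masks)) do.call(rbind, masks)
                else data.frame(chrom = character(0), start = numeric(0),
                                end = numeric(0))
    chrom_sizes <- data.frame(chrom = names(chrom_lengths),
                              length = as.integer(chrom_lengths),
                              stringsAsFactors = FALSE)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      Biostrings::writeXStringSet(genome, file.path(out_dir, "genome.fa"))
      write.table(chrom_sizes, file.path(out_dir, "chrom.sizes"),
                  sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
      write_bed(hardmask, file.path(out_dir, "hardmask.bed"))
    }
    list(genome = genome, chrom_sizes = chrom_sizes, hardmask = hardmask)
  })
}

#' Generate non-overlapping gene annotations with class labels
#'
#' Gene bodies are placed uniformly, non-overlapping on the body level,
#' leaving room for the strand-aware upstream promoter within the
#' chromosome. Class labels follow GENCODE-style biotypes drawn at the
#' given weights.
#'
#' @param genome DNAStringSet (or named lengths) defining the chromosomes.
#' @param n_genes number of genes.
#' @param length_range gene body length bounds, bp (default 2--10 kb).
#' @param promoter_len upstream promoter length, bp (default 1000).
#' @param class_weights named weights over gene classes (default uniform
#'   over the ten standard biotypes).
#' @param seed RNG seed.
#' @param out_dir optional directory: writes genes.bed (BED6 + class).
#' @return data.frame (gene_id, chrom, start, end, strand, class_label),
#'   0-based half-open, sorted.
#' @export
generate_genes <- function(genome, n_genes, length_range = c(2000, 10000),
                           promoter_len = 1000, class_weights = NULL,
                           seed = 1, out_dir = NULL) {
  chrom_lengths <- if (methods::is(genome, "DNAStringSet"))
    setNames(Biostrings::width(genome), names(genome)) else genome
  if (is.null(class_weights))
    class_weights <- setNames(rep(1, length(GENE_CLASSES)), GENE_CLASSES)
  if (n_genes * (length_range[1] + promoter_len) > sum(chrom_lengths))
    stop("generate_genes: could not place ", n_genes,
         " non-overlapping genes on this genome")
  with_seed(seed, {
    occ_s <- occ_e <- lapply(chrom_lengths, function(...) numeric(0))
    chroms <- starts <- ends <- strands <- vector("character", 0)
    tries <- 0L
    max_tries <- 50L * n_genes
    i <- 0L
    while (i < n_genes) {
      if ((tries <- tries + 1L) > max_tries)
        stop("generate_genes: could not place ", n_genes,
             " non-overlapping genes on this genome")
      chrom <- sample(names(chrom_lengths), 1, prob = chrom_lengths)
      len <- sample(length_range[1]:length_range[2], 1)
      strand <- sample(c("+", "-"), 1)
      lo <- if (strand == "+") promoter_len else 0L
      hi <- chrom_lengths[chrom] - len - (if (strand == "-") promoter_len else 0L)
      if (hi <= lo) next
      start <- sample(lo:hi, 1)
      if (any(occ_s[[chrom]] < start + len & occ_e[[chrom]] > start)) next
      occ_s[[chrom]] <- c(occ_s[[chrom]], start)
      occ_e[[chrom]] <- c(occ_e[[chrom]], start + len)
      i <- i + 1L
      chroms[i] <- chrom; starts[i] <- start; ends[i] <- start + len
      strands[i] <- strand
    }
    genes <- data.frame(chrom = chroms, start = as.numeric(starts),
                        end = as.numeric(ends), strand = strands,
                        stringsAsFactors = FALSE)
    genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
    genes$gene_id <- sprintf("GENE%05d", seq_len(n_genes))
    genes$class_label <- sample(names(class_weights), n_genes, replace = TRUE,
                                prob = class_weights)
    genes <- genes[, c("gene_id", "chrom", "start", "end", "strand",
                       "class_label")]
    rownames(genes) <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_bed(genes[, c("chrom", "start", "end", "gene_id", "class_label",
                          "strand")],
                file.path(out_dir, "genes.bed"))
    }
    genes
  })
}

#' Generate a labeled genome segmentation
#'
#' Tiles each chromosome with segments of approximately exponential length
#' and assigns labels at random, emulating an unsupervised segmentation
#' (e.g. 12 labels at 100-bp resolution).
#'
#' @param chrom_lengths named integer vector.
#' @param labels label names (default "M0".."M11").
#' @param mean_seg_len mean segment length, bp (default 20,000).
#' @param bin segment boundaries are rounded to this resolution (default
#'   100 bp).
#' @param seed RNG seed.
#' @return a \code{\link{segmentation}} covering the genome.
#' @export
generate_segmentation <- function(chrom_lengths, labels = paste0("M", 0:11),
                                  mean_seg_len = 20000, bin = 100, seed = 1) {
  with_seed(seed, {
    out <- list()
    for (ch in names(chrom_lengths)) {
      pos <- 0
      n <- chrom_lengths[ch]
      while (pos < n) {
        len <- max(bin, bin * round(stats::rexp(1, 1 / mean_seg_len) / bin))
        end <- min(n, pos + len)
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = pos, end = end,
          label = sample(labels, 1), stringsAsFactors = FALSE)
        pos <- end
      }
    }
    df <- do.call(rbind, out)
    # merge touching runs of the same label so intervals are maximal
    keep <- c(TRUE, !(df$label[-1] == df$label[-nrow(df)] &
                        df$chrom[-1] == df$chrom[-nrow(df)] &
                        df$start[-1] == df$end[-nrow(df)]))
    grp <- cumsum(keep)
    merged <- do.call(rbind, lapply(split(df, grp), function(d)
      data.frame(chrom = d$chrom[1], start = min(d$start), end = max(d$end),
                 label = d$label[1], stringsAsFactors = FALSE)))
    segmentation(merged$chrom, merged$start, merged$end, merged$label)
  })
}

# Assign each bin (by midpoint) the label of the covering segment.
bin_labels <- function(bins, seg) {
  mid <- floor((bins$start + bins$end) / 2)
  mgr <- GenomicRanges::GRanges(bins$chrom, IRanges::IRanges(mid + 1L, mid + 1L))
  hit <- overlaps(mgr, df_to_granges(seg), select = "first")
  lab <- rep(NA_character_, nrow(bins))
  lab[!is.na(hit)] <- seg$label[hit[!is.na(hit)]]
  lab
}

tile_bins <- function(chrom_lengths, bin) {
  out <- lapply(names(chrom_lengths), function(ch) {
    starts <- seq(0, chrom_lengths[ch] - 1, by = bin)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin, chrom_lengths[ch]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Generate per-replicate uracil enrichment tracks with known rates
#'
#' Each bin's uracil rate is the mean rate of its segment label times a
#' lognormal replicate noise factor (unit mean, coefficient of variation
#' \code{replicate_cv}). The per-replicate global uracil content scalar is
#' the length-weighted mean rate over all bins, so rescaling the emitted
#' ratio track with it recovers the per-bin rates.
#'
#' @param seg a \code{\link{segmentation}}.
#' @param label_rate_means named vector, label -> mean rate (U per Mb,
#'   > 0). Labels absent from the map (or bins not covered by any segment)
#'   get rate 0 with a warning.
#' @param chrom_lengths named integer vector.
#' @param replicate_cv lognormal noise coefficient of variation (default
#'   0.2).
#' @param n_replicates number of replicate tracks (default 2).
#' @param bin bin width, bp (default 100).
#' @param seed RNG seed.
#' @param out_dir optional directory: writes rep<i>.ratio.bedGraph files.
#' @return list(tracks = list of ratio \code{\link{binned_track}}s,
#'   contents = per-replicate global content, truth = data.frame of per-bin
#'   rates per replicate).
#' @export
generate_enrichment_tracks <- function(seg, label_rate_means, chrom_lengths,
                                       replicate_cv = 0.2, n_replicates = 2,
                                       bin = 100, seed = 1, out_dir = NULL) {
  stopifnot(all(label_rate_means > 0))
  bins <- tile_bins(chrom_lengths, bin)
  lab <- bin_labels(bins, seg)
  base_rate <- unname(label_rate_means[lab])
  uncov <- is.na(base_rate)
  if (any(uncov)) {
    warning(sum(uncov), " bin(s) not covered by the segmentation; rate 0")
    base_rate[uncov] <- 0
  }
  sdlog <- sqrt(log(1 + replicate_cv^2))
  w <- bins$end - bins$start
  with_seed(seed, {
    tracks <- list(); contents <- numeric(n_replicates)
    truth <- bins
    for (r in seq_len(n_replicates)) {
      noise <- if (replicate_cv > 0)
        rlnorm(nrow(bins), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      else rep(1, nrow(bins))
      rate <- base_rate * noise
      contents[r] <- sum(rate * w) / sum(w)
      tracks[[r]] <- binned_track(bins$chrom, bins$start, bins$end, rate,
                                  units = "ratio")
      truth[[paste0("rate_rep", r)]] <- rate
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        write_bedgraph(tracks[[r]],
                       file.path(out_dir, sprintf("rep%d.ratio.bedGraph", r)))
      }
    }
    names(tracks) <- paste0("rep", seq_len(n_replicates))
    names(contents) <- names(tracks)
    list(tracks = tracks, contents = contents, truth = truth)
  })
}

#' Generate a replication timing track over a segmentation
#'
#' Per-bin score = segment label mean + Gaussian noise. Higher scores mean
#' earlier replication (E/L Repli-seq convention).
#'
#' @param seg a \code{\link{segmentation}}.
#' @param label_rt_means named vector, label -> mean RT score.
#' @param chrom_lengths named integer vector.
#' @param noise_sd Gaussian noise SD (default 0).
#' @param bin bin width, bp (default 100).
#' @param seed RNG seed.
#' @param out_dir optional directory: writes rt.bedGraph.
#' @return a \code{\link{binned_track}} with units "RT_score".
#' @export
generate_rt_track <- function(seg, label_rt_means, chrom_lengths,
                              noise_sd = 0, bin = 100, seed = 1,
                              out_dir = NULL) {
  bins <- tile_bins(chrom_lengths, bin)
  lab <- bin_labels(bins, seg)
  mu <- unname(label_rt_means[lab])
  mu[is.na(mu)] <- 0
  with_seed(seed, {
    val <- mu + if (noise_sd > 0) rnorm(nrow(bins), 0, noise_sd) else 0
    tr <- binned_track(bins$chrom, bins$start, bins$end, val,
                       units = "RT_score")
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_bedgraph(tr, file.path(out_dir, "rt.bedGraph"))
    }
    tr
  })
}

# Trinucleotide position index of a genome: for every internal position
# with an unambiguous context, the pyrimidine-strand trinucleotide key
# ("ACA" means A[C]A on the pyrimidine strand).
trinuc_index <- function(genome) {
  out <- list()
  for (ch in names(genome)) {
    s <- strsplit(as.character(genome[[ch]]), "")[[1]]
    n <- length(s)
    if (n < 3) next
    tri <- paste0(s[1:(n - 2)], s[2:(n - 1)], s[3:n])
    center <- s[2:(n - 1)]
    pyr <- center %in% c("C", "T")
    rc <- paste0(chartr("ACGT", "TGCA", s[3:n]),
                 chartr("ACGT", "TGCA", s[2:(n - 1)]),
                 chartr("ACGT", "TGCA", s[1:(n - 2)]))
    key <- ifelse(pyr, tri, rc)
    ok <- !grepl("N", tri, fixed = TRUE)
    out[[ch]] <- data.frame(pos = which(ok) , key = key[ok],
                            stringsAsFactors = FALSE)  # pos is 0-based center
  }
  out
}

channel_parts <- function(channel) {
  # "A[C>T]G" -> context key "ACG", ref "C", alt "T"
  list(key = paste0(substr(channel, 1, 1), substr(channel, 3, 3),
                    substr(channel, 7, 7)),
       ref = substr(channel, 3, 3), alt = substr(channel, 5, 5))
}

#' Generate a somatic variant set with a known substitution spectrum
#'
#' Sites are drawn by matching the reference trinucleotide context of the
#' genome to channels sampled from a mixture of 96-channel component
#' spectra, so the emitted truth table's channel counts are exactly
#' reproduced by \code{\link{sbs96_matrix}} on the output. A fraction of
#' the C>T events is placed in kataegis-like clusters: runs of 2--6
#' consecutive C>T events with successive gaps drawn uniformly in
#' [2, cluster_imd]. Allele frequencies follow a Beta distribution
#' (default Beta(2, 8), low-frequency somatic-like). The VCF is sorted with
#' FILTER=PASS and INFO/AF.
#'
#' @param genome a named \code{DNAStringSet}.
#' @param n_variants total number of substitutions.
#' @param spectrum_mix named weights over components (sum to 1).
#' @param component_spectra 96 x k matrix of probability spectra (rows in
#'   canonical channel order, columns named like \code{spectrum_mix}).
#' @param cluster_fraction fraction of C>T events placed in clusters
#'   (default 0).
#' @param cluster_imd maximum within-cluster gap, bp (default 100).
#' @param af_shape Beta parameters for allele frequencies (default
#'   c(2, 8)).
#' @param seed RNG seed.
#' @param out_dir optional directory: writes variants.vcf and
#'   variant_truth.tsv.
#' @return list(vset = \code{\link{variant_set}}, truth = data.frame with
#'   chrom, pos, ref, alt, af, sbs_type, channel96, in_cluster, component).
#' @export
generate_variants <- function(genome, n_variants, spectrum_mix,
                              component_spectra, cluster_fraction = 0,
                              cluster_imd = 100, af_shape = c(2, 8),
                              seed = 1, out_dir = NULL) {
  stopifnot(abs(sum(spectrum_mix) - 1) < 1e-6,
            all(names(spectrum_mix) %in% colnames(component_spectra)))
  channels <- sbs96_channels()
  stopifnot(nrow(component_spectra) == 96)
  idx <- trinuc_index(genome)
  pool <- do.call(rbind, lapply(names(idx), function(ch)
    data.frame(chrom = ch, pos = idx[[ch]]$pos, key = idx[[ch]]$key,
               stringsAsFactors = FALSE)))
  with_seed(seed, {
    # component and channel per variant
    comp <- sample(names(spectrum_mix), n_variants, replace = TRUE,
                   prob = spectrum_mix)
    chan <- vapply(comp, function(cp)
      sample(channels, 1, prob = component_spectra[, cp]), character(1),
      USE.NAMES = FALSE)
    parts <- channel_parts(chan)
    is_ct <- substr(chan, 3, 5) == "C>T"
    n_clustered <- round(cluster_fraction * sum(is_ct))
    clustered_slot <- rep(FALSE, n_variants)
    if (n_clustered > 0)
      clustered_slot[sample(which(is_ct), n_clustered)] <- TRUE

    used <- logical(nrow(pool))

    # clustered C>T events: walk runs over cytosine-context positions
    cg_idx <- which(substr(pool$key, 2, 2) == "C")
    cg_by_chrom <- split(cg_idx, pool$chrom[cg_idx])
    cg_by_chrom <- lapply(cg_by_chrom, function(ix) ix[order(pool$pos[ix])])
    cluster_rows <- integer(0)
    remaining <- n_clustered
    guard <- 0L
    while (remaining > 0) {
      if ((guard <- guard + 1L) > 50L * max(1L, n_clustered))
        stop("generate_variants: unable to place clustered events; ",
             "genome too small or cluster_imd too tight")
      size <- max(2L, min(remaining, sample(2:6, 1)))
      ch <- sample(names(cg_by_chrom), 1)
      cand <- cg_by_chrom[[ch]]          # pool row ids, position-sorted
      cpos <- pool$pos[cand]
      if (length(cand) < size) next
      run <- sample.int(length(cand) - size + 1L, 1)  # indices into cand
      ok <- TRUE
      for (s in seq_len(size - 1)) {
        cur <- cpos[run[length(run)]]
        gap <- sample(2:cluster_imd, 1)
        j <- findInterval(cur + gap - 1L, cpos) + 1L
        if (j > length(cand) || cpos[j] > cur + cluster_imd) { ok <- FALSE; break }
        run <- c(run, j)
      }
      if (!ok || anyDuplicated(run) || any(used[cand[run]])) next
      used[cand[run]] <- TRUE
      cluster_rows <- c(cluster_rows, cand[run])
      remaining <- remaining - length(run)
    }
    cluster_df <- pool[cluster_rows, , drop = FALSE]

    # isolated events: sample positions per required context key
    iso_chan <- chan[!clustered_slot]
    iso_comp <- comp[!clustered_slot]
    iso_keys <- channel_parts(iso_chan)$key
    iso_pick <- integer(length(iso_chan))
    pool_by_key <- split(seq_len(nrow(pool)), pool$key)
    for (k in unique(iso_keys)) {
      need <- which(iso_keys == k)
      avail <- pool_by_key[[k]]
      if (is.null(avail))
        stop("generate_variants: context ", k, " absent from genome")
      avail <- avail[!used[avail]]
      if (length(avail) < length(need))
        stop("generate_variants: not enough ", k, " sites (need ",
             length(need), ", have ", length(avail), ")")
      pick <- if (length(avail) == 1) avail else sample(avail, length(need))
      used[pick] <- TRUE
      iso_pick[need] <- pick
    }
    iso_df <- pool[iso_pick, , drop = FALSE]

    # assemble truth: clustered events take their genuine genome context
    mk_record <- function(df, chan_vec, comp_vec, in_cluster) {
      if (nrow(df) == 0)
        return(NULL)
      key <- df$key
      center <- character(nrow(df))
      for (ch in unique(df$chrom)) {
        i <- which(df$chrom == ch)
        center[i] <- as.character(Biostrings::extractAt(
          genome[[ch]], IRanges::IRanges(df$pos[i] + 1L, df$pos[i] + 1L)))
      }
      pyr <- center %in% c("C", "T")
      if (is.null(chan_vec)) {    # clustered: genuine C>T channel
        chan_vec <- paste0(substr(key, 1, 1), "[", substr(key, 2, 2), ">T]",
                           substr(key, 3, 3))
      }
      alt_p <- substr(chan_vec, 5, 5)
      data.frame(chrom = df$chrom, pos = df$pos,
                 ref = center,
                 alt = ifelse(pyr, alt_p, unname(COMPLEMENT[alt_p])),
                 sbs_type = substr(chan_vec, 3, 5),
                 channel96 = chan_vec,
                 in_cluster = in_cluster,
                 component = comp_vec,
                 stringsAsFactors = FALSE)
    }
    truth <- rbind(
      mk_record(iso_df, iso_chan, iso_comp, FALSE),
      mk_record(cluster_df, NULL,
                rep("clustered", nrow(cluster_df)), TRUE))
    truth$af <- rbeta(nrow(truth), af_shape[1], af_shape[2])
    truth <- truth[order(truth$chrom, truth$pos), , drop = FALSE]
    rownames(truth) <- NULL
    vset <- variant_set(truth$chrom, truth$pos, truth$ref, truth$alt,
                        af = truth$af, filter = "PASS")
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_vcf(vset, file.path(out_dir, "variants.vcf"),
                chrom_lengths = setNames(Biostrings::width(genome),
                                         names(genome)))
      write.table(truth, file.path(out_dir, "variant_truth.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(vset = vset, truth = truth)
  })
}

#' Write a variant set as a minimal sorted VCF 4.2
#'
#' Site-only records with INFO/AF and the record's FILTER string; FILTER
#' and contig definitions are emitted in the header so the file round-trips
#' through standard VCF readers.
#'
#' @param vset a \code{\link{variant_set}}.
#' @param path output file.
#' @param chrom_lengths named vector for contig header lines.
#' @export
write_vcf <- function(vset, path, chrom_lengths = NULL) {
  labels <- setdiff(unique(unlist(strsplit(vset$filter, ";"))), "PASS")
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
           sprintf("##FILTER=<ID=%s,Description=\"%s\">", labels, labels),
           if (!is.null(chrom_lengths))
             sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
                     as.integer(chrom_lengths)),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  v <- vset[order(vset$chrom, vset$pos), , drop = FALSE]
  recs <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                  v$chrom, as.integer(v$pos) + 1L, v$ref, v$alt, v$filter,
                  ifelse(is.na(v$af), ".", sprintf("AF=%.6g", v$af)))
  writeLines(c(hdr, recs), path)
  invisible(path)
}
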