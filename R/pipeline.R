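# End-to-end demonstration run on synthetic data: simulate -> tracks ->
# U-scores -> variants -> spectra -> hairpins -> segment statistics, with a
# manifest recording parameters, seed and per-stage row counts.

#' Default pipeline configuration
#'
#' All analysis parameters with their standard defaults: 1,000-bp core
#' promoter, top-2,000 gene-class enrichment, fold-change gate 1.5 and raw
#' p gate 0.05 for differential uracilation, replication-timing strata at
#' 2.5 / -2.5, 100-bp cluster IMD threshold, 4-nt minimum stem with 3--6-nt
#' loops over a +/-15-nt window, and the standard excluded FILTER labels.
#'
#' @param ... overrides for any default.
#' @return named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1,
    chrom_lengths = c(chr1 = 400000, chr2 = 300000),
    gc_fraction = 0.41,
    n_genes = 120,
    promoter_len = 1000,
    n_segment_labels = 6,
    mean_seg_len = 20000,
    bin = 100,
    base_rate = 700,          # U per Mb, drug-treated scale
    replicate_cv = 0.1,
    n_replicates = 2,
    boost_label = "M1",
    boost_fold = 2,
    rt_noise_sd = 0.3,
    n_variants = 2000,
    ctot_weight = 0.6,
    cluster_fraction = 0.15,
    cluster_imd = 100,
    max_imd = 100,
    min_cluster_size = 2,
    af_shape = c(2, 8),
    top_n = 120 %/% 2,        # scaled to the synthetic gene count
    fc_thresh = 1.5,
    p_thresh = 0.05,
    rt_thresholds = c(2.5, -2.5),
    flank = 15,
    min_stem = 4,
    loop_range = c(3, 6),
    excluded_labels = c("weak_evidence", "normal_artifact", "slippage",
                        "germline", "base_qual")
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Synthetic reference components for spectrum refitting
#'
#' A TC-context-biased C>T component (APOBEC-like, SBS2-flavored) and a
#' flat background, as a 96 x 2 probability matrix in canonical channel
#' order. These are synthetic stand-ins for published deaminase spectra,
#' which are figure-derived and not bundled.
#'
#' @return 96 x 2 numeric matrix with columns "apobec" and "background".
#' @export
synthetic_components <- function() {
  channels <- sbs96_channels()
  apobec <- ifelse(substr(channels, 1, 1) == "T" &
                     substr(channels, 3, 5) == "C>T", 1, 0)
  apobec <- apobec / sum(apobec)
  flat <- rep(1 / 96, 96)
  m <- cbind(apobec = apobec, background = flat)
  rownames(m) <- channels
  m
}

#' Run the full synthetic demonstration pipeline
#'
#' Executes simulate, tracks, uscore, variants, spectra, hairpin and
#' segments stages on generated data and writes TSV outputs plus a
#' manifest JSON (seed, parameter echo, per-stage row counts). Rerunning
#' with the same seed reproduces all outputs.
#'
#' @param config list from \code{\link{default_config}} (or a YAML file
#'   path readable by \pkg{yaml}).
#' @param out_dir output directory (default: a temporary directory).
#' @return invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("uraseq_run_")) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- utils::modifyList(default_config(), yaml::read_yaml(config))
  }
  cfg <- config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  # -- simulate ------------------------------------------------------------
  gen <- generate_genome(cfg$chrom_lengths, cfg$gc_fraction, seed = cfg$seed)
  genes <- generate_genes(gen$genome, cfg$n_genes,
                          promoter_len = cfg$promoter_len,
                          seed = cfg$seed + 1)
  labels <- paste0("M", seq_len(cfg$n_segment_labels) - 1)
  seg <- generate_segmentation(cfg$chrom_lengths, labels = labels,
                               mean_seg_len = cfg$mean_seg_len,
                               bin = cfg$bin, seed = cfg$seed + 2)
  rates_b <- setNames(rep(cfg$base_rate, length(labels)), labels)
  rates_a <- rates_b
  rates_a[cfg$boost_label] <- rates_a[cfg$boost_label] * cfg$boost_fold
  trkA <- generate_enrichment_tracks(seg, rates_a, cfg$chrom_lengths,
                                     cfg$replicate_cv, cfg$n_replicates,
                                     cfg$bin, seed = cfg$seed + 3)
  trkB <- generate_enrichment_tracks(seg, rates_b, cfg$chrom_lengths,
                                     cfg$replicate_cv, cfg$n_replicates,
                                     cfg$bin, seed = cfg$seed + 4)
  rt_means <- setNames(seq(3, -3, length.out = length(labels)), labels)
  rt <- generate_rt_track(seg, rt_means, cfg$chrom_lengths,
                          noise_sd = cfg$rt_noise_sd, bin = cfg$bin,
                          seed = cfg$seed + 5)
  comp <- synthetic_components()
  mix <- c(apobec = cfg$ctot_weight, background = 1 - cfg$ctot_weight)
  vars <- generate_variants(gen$genome, cfg$n_variants, mix, comp,
                            cluster_fraction = cfg$cluster_fraction,
                            cluster_imd = cfg$cluster_imd,
                            af_shape = cfg$af_shape, seed = cfg$seed + 6)
  counts$simulate <- list(genes = nrow(genes), segments = nrow(seg),
                          variants = nrow(vars$vset))

  # -- tracks --------------------------------------------------------------
  ptracks <- c(
    lapply(seq_along(trkA$tracks), function(i)
      rescale_to_ptrack(trkA$tracks[[i]], trkA$contents[i])),
    lapply(seq_along(trkB$tracks), function(i)
      rescale_to_ptrack(trkB$tracks[[i]], trkB$contents[i])))
  names(ptracks) <- c(paste0("A_rep", seq_along(trkA$tracks)),
                      paste0("B_rep", seq_along(trkB$tracks)))
  counts$tracks <- list(ptracks = length(ptracks))

  # -- uscore --------------------------------------------------------------
  gi <- build_gene_intervals(genes, promoter_len = cfg$promoter_len,
                             chrom_lengths = cfg$chrom_lengths)
  us_rel <- lapply(c(trkA$tracks, trkB$tracks), function(tr)
    compute_uscores(tr, gi, relative = TRUE))
  us_mat <- do.call(cbind, lapply(us_rel, `[[`, "uscore"))
  rownames(us_mat) <- us_rel[[1]]$gene_id
  nA <- length(trkA$tracks)
  diff_res <- differential_uscore(us_mat[, seq_len(nA), drop = FALSE],
                                  us_mat[, nA + seq_along(trkB$tracks),
                                         drop = FALSE],
                                  fc_thresh = cfg$fc_thresh,
                                  p_thresh = cfg$p_thresh)
  us_abs <- compute_uscores(ptracks[[1]], gi)
  cls <- setNames(genes$class_label, genes$gene_id)
  enr <- class_enrichment(us_abs, cls, top_n = cfg$top_n)
  tsv(diff_res, "differential_uscore.tsv")
  tsv(enr, "class_enrichment.tsv")
  counts$uscore <- list(genes_scored = sum(!is.na(us_abs$uscore)),
                        significant = sum(diff_res$significant))

  # -- variants ------------------------------------------------------------
  vset <- filter_variants(vars$vset, cfg$excluded_labels)
  vset <- classify_sbs(vset, gen$genome)
  fr <- weighted_sbs_fractions(vset)
  imd <- intermutational_distances(vset, type_filter = "C>T")
  clu <- cluster_variants(vset, max_imd = cfg$max_imd,
                          min_size = cfg$min_cluster_size,
                          type_filter = "C>T")
  strat <- stratify_by_rt(vset, rt, thresholds = cfg$rt_thresholds)
  per_seg <- fractions_by_segment(vset, seg)
  tsv(fr, "sbs_fractions.tsv")
  tsv(imd, "imd.tsv")
  tsv(clu$clusters, "clusters.tsv")
  tsv(per_seg$table, "ctot_by_segment.tsv")
  counts$variants <- list(filtered = nrow(vset), clusters = nrow(clu$clusters))

  # -- spectra -------------------------------------------------------------
  s96 <- sbs96_matrix(vset)
  s1536 <- sbs1536_matrix(vset)
  dbs <- detect_dbs(vset)
  d78 <- dbs78_matrix(dbs)
  refit <- refit_spectrum(spectrum_vector(as.numeric(s96), "SBS96"), comp)
  tsv(data.frame(channel = names(s96), value = as.numeric(s96)),
      "spectrum_sbs96.tsv")
  tsv(data.frame(component = names(refit$weights),
                 weight = refit$weights,
                 contribution = refit$contributions),
      "refit.tsv")
  counts$spectra <- list(sbs96_total = sum(s96), dbs = nrow(dbs),
                         refit_cosine = round(refit$cosine, 6))

  # -- hairpin -------------------------------------------------------------
  loopfr <- loop_context_fractions(vset, gen$genome, clu$variants,
                                   flank = cfg$flank,
                                   min_stem = cfg$min_stem,
                                   loop_min = cfg$loop_range[1],
                                   loop_max = cfg$loop_range[2])
  tsv(data.frame(context = c("all", "loop", "clustered"),
                 pct_ctot = c(loopfr$pct_ctot_all, loopfr$pct_ctot_loop,
                              loopfr$pct_ctot_clustered)),
      "loop_context.tsv")
  counts$hairpin <- list(n_loop = loopfr$n_loop)

  # -- segments ------------------------------------------------------------
  sig <- signal_distribution(ptracks, seg)
  segrt <- segment_rt(seg, rt)
  at <- segment_at_content(seg, gen$genome)
  jac_self <- jaccard(seg, seg)
  tsv(segrt, "segment_rt.tsv")
  tsv(at, "segment_at.tsv")
  counts$segments <- list(labels = nrow(segrt), jaccard_self = jac_self)

  manifest <- list(
    package = "uraseq",
    version = as.character(utils::packageVersion("uraseq")),
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), "chrom_lengths")],
    chrom_lengths = as.list(cfg$chrom_lengths),
    stages = names(counts),
    row_counts = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(out_dir = out_dir, manifest = manifest, genes = genes,
                 segmentation = seg, ptracks = ptracks, uscores = us_mat,
                 differential = diff_res, class_enrichment = enr,
                 fractions = fr, imd = imd, clusters = clu,
                 rt_strata = strat, per_segment = per_seg,
                 spectrum96 = s96, spectrum1536 = s1536, dbs78 = d78,
                 refit = refit, loop_context = loopfr,
                 signal_distribution = sig, segment_rt = segrt,
                 at_content = at))
}
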