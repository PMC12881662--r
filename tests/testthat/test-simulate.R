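# Ground-truth generators: determinism, stated composition, and
# round-trip agreement with the downstream readers and classifiers.

test_that("genome generation honors lengths, GC content and determinism", {
  g <- generate_genome(c(chr1 = 1e6, chr2 = 1e6), gc_fraction = 0.41, seed = 7)
  expect_length(g$genome, 2)
  expect_equal(unname(Biostrings::width(g$genome)), c(1e6, 1e6))
  g2 <- generate_genome(c(chr1 = 1e6, chr2 = 1e6), gc_fraction = 0.41, seed = 7)
  expect_identical(as.character(g$genome), as.character(g2$genome))
  # observed GC within a 6-sigma binomial band at n = 1e6
  g6 <- generate_genome(c(chr1 = 1e6), gc_fraction = 0.60, seed = 3)
  gc_obs <- sum(Biostrings::letterFrequency(g6$genome, c("G", "C"))) / 1e6
  expect_gt(gc_obs, 0.58); expect_lt(gc_obs, 0.62)
  expect_error(generate_genome(c(chr1 = 0)), ">= 10,000")
})

test_that("hard-masked runs are N in the FASTA and emitted as intervals", {
  g <- generate_genome(c(chr1 = 50000), hardmask_fraction = 0.1, seed = 5)
  expect_gt(nrow(g$hardmask), 0)
  n_count <- sum(Biostrings::letterFrequency(g$genome, "N"))
  expect_equal(n_count, sum(g$hardmask$end - g$hardmask$start))
  r <- g$hardmask[1, ]
  run <- Biostrings::subseq(g$genome[[r$chrom]], r$start + 1, r$end)
  expect_equal(as.character(run), strrep("N", r$end - r$start))
})

test_that("gene placement respects bounds, non-overlap and class weights", {
  g <- generate_genome(c(chr1 = 500000, chr2 = 500000), seed = 2)
  genes <- generate_genes(g$genome, 50, length_range = c(2000, 10000),
                          promoter_len = 1000, seed = 3)
  expect_equal(nrow(genes), 50)
  expect_true(all(genes$end - genes$start >= 2000 &
                    genes$end - genes$start <= 10000))
  lens <- setNames(Biostrings::width(g$genome), names(g$genome))
  room <- ifelse(genes$strand == "+", genes$start >= 1000,
                 genes$end + 1000 <= lens[genes$chrom])
  expect_true(all(room))
  for (ch in unique(genes$chrom)) {
    d <- genes[genes$chrom == ch, ]
    expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
  # single-class weights give a single label
  only <- generate_genes(g$genome, 20, class_weights = c(protein_coding = 1),
                         seed = 4)
  expect_true(all(only$class_label == "protein_coding"))
  expect_error(generate_genes(c(chr1 = 20000), 500, seed = 1), "could not place")
})

test_that("class label draws follow the weights (binomial band)", {
  g <- generate_genome(c(chr1 = 3e6, chr2 = 3e6), seed = 9)
  w <- c(pseudogene = 0.1, protein_coding = 0.9)
  genes <- generate_genes(g$genome, 10000, length_range = c(100, 300),
                          promoter_len = 50, class_weights = w, seed = 10)
  n_pseudo <- sum(genes$class_label == "pseudogene")
  expect_gte(n_pseudo, 850)   # 5-sigma band around 1000 of 10000
  expect_lte(n_pseudo, 1150)
})

test_that("enrichment tracks realize label means and content identities", {
  chrl <- c(chr1 = 100000)
  seg1 <- segmentation("chr1", 0, 100000, "only")
  tr <- generate_enrichment_tracks(seg1, c(only = 700), chrl,
                                   replicate_cv = 0, n_replicates = 1, seed = 1)
  expect_true(all(tr$tracks$rep1$value == 700))
  expect_equal(unname(tr$contents["rep1"]), 700)
  # two labels on equal halves, no noise: content is the arithmetic mean
  seg2 <- segmentation(rep("chr1", 2), c(0, 50000), c(50000, 100000),
                       c("lo", "hi"))
  tr2 <- generate_enrichment_tracks(seg2, c(lo = 100, hi = 900), chrl,
                                    replicate_cv = 0, n_replicates = 1, seed = 1)
  expect_equal(unname(tr2$contents["rep1"]), 500)
  # content equals the length-weighted mean of the truth rates (1e-9 rel.)
  tr3 <- generate_enrichment_tracks(seg2, c(lo = 100, hi = 900), chrl,
                                    replicate_cv = 0.3, n_replicates = 2, seed = 8)
  w <- tr3$truth$end - tr3$truth$start
  for (r in 1:2) {
    rate <- tr3$truth[[paste0("rate_rep", r)]]
    expect_equal(unname(tr3$contents[r]), sum(rate * w) / sum(w),
                 tolerance = 1e-9)
    expect_equal(tr3$tracks[[r]]$value, rate)
  }
})

test_that("lognormal replicate noise has the configured CV", {
  chrl <- c(chr1 = 1e6)
  seg <- segmentation("chr1", 0, 1e6, "only")
  tr <- generate_enrichment_tracks(seg, c(only = 700), chrl,
                                   replicate_cv = 0.2, n_replicates = 1,
                                   bin = 100, seed = 6)
  v <- tr$tracks$rep1$value   # 1e4 bins
  cv <- sd(v) / mean(v)
  expect_gt(cv, 0.17); expect_lt(cv, 0.23)
})

test_that("RT tracks realize label means and stratification recovers thirds", {
  chrl <- c(chr1 = 300000)
  seg3 <- segmentation(rep("chr1", 3), c(0, 100000, 200000),
                       c(100000, 200000, 300000), c("E", "M", "L"))
  rt0 <- generate_rt_track(seg3, c(E = 3, M = 0, L = -3), chrl,
                           noise_sd = 0, seed = 1)
  expect_true(all(rt0$value[1:1000] == 3))
  expect_identical(generate_rt_track(seg3, c(E = 3, M = 0, L = -3), chrl,
                                     noise_sd = 0.2, seed = 4)$value,
                   generate_rt_track(seg3, c(E = 3, M = 0, L = -3), chrl,
                                     noise_sd = 0.2, seed = 4)$value)
  # uniformly placed variants split into thirds within 5 points
  set.seed(13)
  v <- variant_set("chr1", sample(0:(3e5 - 1), 3000), "C", "T")
  strat <- stratify_by_rt(v, rt0)
  props <- strat$counts[c("early", "middle", "late")] / 3000
  expect_true(all(abs(props - 1 / 3) < 0.05))
  expect_equal(sum(strat$counts), 3000)
})

test_that("variant generation honors the spectrum, AF model and determinism", {
  g <- generate_genome(c(chr1 = 200000), seed = 21)
  channels <- uraseq:::sbs96_channels()
  # a component concentrated on T[C>T]N
  tcn <- ifelse(substr(channels, 1, 1) == "T" &
                  substr(channels, 3, 5) == "C>T", 1, 0)
  comp <- cbind(pure = tcn / sum(tcn))
  sim <- generate_variants(g$genome, 300, c(pure = 1), comp, seed = 22)
  expect_equal(nrow(sim$vset), 300)
  expect_true(all(sim$truth$sbs_type == "C>T"))
  cl <- classify_sbs(sim$vset, g$genome)
  expect_true(all(cl$sbs_type == "C>T"))
  expect_true(all(substr(cl$tri, 1, 1) == "T"))
  expect_true(all(sim$truth$af >= 0 & sim$truth$af <= 1))
  sim2 <- generate_variants(g$genome, 300, c(pure = 1), comp, seed = 22)
  expect_identical(sim$truth, sim2$truth)
})

test_that("truth channel counts round-trip through the emitted VCF", {
  g <- generate_genome(c(chr1 = 300000, chr2 = 300000), seed = 31)
  comp <- synthetic_components()
  out <- tempfile("simvcf_")
  sim <- generate_variants(g$genome, 500, c(apobec = 0.6, background = 0.4),
                           comp, cluster_fraction = 0.2, cluster_imd = 100,
                           seed = 32, out_dir = out)
  vset <- suppressWarnings(read_vcf(file.path(out, "variants.vcf")))
  expect_equal(nrow(vset), 500)
  cl <- classify_sbs(vset, g$genome)
  s96 <- sbs96_matrix(cl)
  truth_counts <- table(sim$truth$channel96)
  expect_equal(as.numeric(s96[names(truth_counts)]),
               as.numeric(truth_counts))
  expect_equal(sum(s96), 500)
  # every truth ref matches the generated FASTA at its coordinate
  gc <- genome_chars(g$genome)
  ref_g <- mapply(function(ch, p) gc[[ch]][p + 1], sim$truth$chrom,
                  sim$truth$pos)
  expect_equal(unname(ref_g), sim$truth$ref)
})

test_that("cluster placement produces short-IMD runs detectable at the threshold", {
  g <- generate_genome(c(chr1 = 500000), seed = 41)
  comp <- synthetic_components()
  sim <- generate_variants(g$genome, 600, c(apobec = 0.7, background = 0.3),
                           comp, cluster_fraction = 0.25, cluster_imd = 100,
                           seed = 42)
  truth_cl <- sim$truth[sim$truth$in_cluster, ]
  expect_gt(nrow(truth_cl), 0)
  cl <- classify_sbs(sim$vset, g$genome)
  det <- cluster_variants(cl, max_imd = 100, min_size = 2,
                          type_filter = "C>T")
  det_keys <- with(det$variants[!is.na(det$variants$cluster_id), ],
                   paste(chrom, pos))
  # recall 1: every generator cluster member is recovered
  expect_true(all(paste(truth_cl$chrom, truth_cl$pos) %in% det_keys))
})

test_that("without clustering the C>T spacing stays dispersed", {
  g <- generate_genome(c(chr1 = 2e6), seed = 51)
  comp <- synthetic_components()
  sim <- generate_variants(g$genome, 1000, c(apobec = 0.5, background = 0.5),
                           comp, cluster_fraction = 0, seed = 52)
  cl <- classify_sbs(sim$vset, g$genome)
  imd <- intermutational_distances(cl, type_filter = "C>T")
  expect_gt(median(imd$imd), 1000)
})
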