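# Variant filtering, SBS/DBS classification, AF-weighted fractions, IMDs,
# clusters and stratification.

test_that("VCF writing and reading round-trip records, AF and FILTER", {
  g <- toy_genome()
  v <- variant_set(chrom = c("chr1", "chr1", "chr2"),
                   pos = c(99, 499, 42),
                   ref = substring(as.character(c(g[["chr1"]], g[["chr1"]],
                                                  g[["chr2"]])),
                                   c(100, 500, 43), c(100, 500, 43)),
                   alt = c("A", "C", "G"),
                   af = c(0.25, 0.5, NA),
                   filter = c("PASS", "germline;slippage", "PASS"))
  # avoid ref == alt in the fixture
  v$alt[v$alt == v$ref] <- ifelse(v$ref[v$alt == v$ref] == "T", "G", "T")
  f <- tempfile(fileext = ".vcf")
  write_vcf(v, f, chrom_lengths = c(chr1 = 50000, chr2 = 50000))
  rt <- suppressWarnings(read_vcf(f))
  expect_equal(rt$chrom, v$chrom)
  expect_equal(rt$pos, v$pos)
  expect_equal(rt$ref, v$ref)
  expect_equal(rt$alt, v$alt)
  expect_equal(rt$af, v$af, tolerance = 1e-6)
  expect_equal(rt$filter, v$filter)
})

test_that("AF falls back to FORMAT/AD when INFO/AF is absent", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ttumor",
    "chr1\t100\t.\tC\tT\t.\tPASS\t.\tAD\t30,10"), f)
  v <- suppressWarnings(read_vcf(f))
  expect_equal(v$af, 0.25)
})

test_that("multi-allelic records are split before filtering", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"AF\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\t.\tC\tT,G\t.\tPASS\tAF=0.3,0.1"), f)
  v <- suppressWarnings(read_vcf(f))
  expect_equal(nrow(v), 2)
  expect_equal(sort(v$alt), c("G", "T"))
})

test_that("filtering removes records carrying any excluded label", {
  filt <- c("PASS", "germline;slippage", "PASS", "weak_evidence", "PASS",
            "base_qual", "PASS", "PASS", "PASS", "PASS")
  v <- variant_set("chr1", seq(100, 1000, by = 100), rep("C", 10),
                   rep("T", 10), af = 0.1, filter = filt)
  kept <- filter_variants(v)
  expect_equal(nrow(kept), 7)
  expect_false(any(grepl("germline|weak_evidence|base_qual", kept$filter)))
  # a label that is not excluded survives
  v2 <- variant_set("chr1", 100, "C", "T", 0.1, filter = "clustered_events")
  expect_equal(nrow(filter_variants(v2)), 1)
})

test_that("SBS classification collapses purines by reverse complement", {
  g <- Biostrings::DNAStringSet(c(chr1 = "AATGCAACATT"))
  # genome ...T[G]C...: G>A at 0-based pos 3 is C>T with context G[C>T]A
  v <- variant_set("chr1", 3, "G", "A", 0.5)
  cl <- classify_sbs(v, g)
  expect_equal(cl$sbs_type, "C>T")
  expect_equal(cl$tri, "G[C>T]A")
  # plain pyrimidine case: C>T in ACA
  v2 <- variant_set("chr1", 7, "C", "T", 0.5)  # context "ACA"
  cl2 <- classify_sbs(v2, g)
  expect_equal(cl2$tri, "A[C>T]A")
  expect_equal(cl2$penta, "AA[C>T]AT")
  # mismatching reference is a hard error
  expect_error(classify_sbs(variant_set("chr1", 3, "C", "T"), g), "mismatch")
})

test_that("channel assignment agrees with a string-matching oracle", {
  g <- toy_genome()
  gc <- genome_chars(g)
  set.seed(99)
  n <- 50
  chrom <- sample(names(g), n, replace = TRUE)
  pos <- sample(10:40000, n)
  ref <- mapply(function(ch, p) gc[[ch]][p + 1], chrom, pos)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  v <- variant_set(chrom, pos, ref, alt, af = 0.2)
  cl <- classify_sbs(v, g)
  expected <- mapply(oracle_channel96, cl$chrom, cl$pos, cl$alt,
                     MoreArgs = list(genome_chars = gc))
  expect_equal(unname(cl$tri), unname(expected))
  # classification of the reverse-complemented record on the other strand
  # yields the identical channel
  rcg <- Biostrings::DNAStringSet(Biostrings::reverseComplement(g[["chr1"]]))
  names(rcg) <- "chr1"
  len <- length(g[["chr1"]])
  on1 <- cl[cl$chrom == "chr1", , drop = FALSE]
  vrc <- variant_set("chr1", len - 1 - on1$pos,
                     revcomp_chr(on1$ref), revcomp_chr(on1$alt), af = 0.2)
  clrc <- classify_sbs(vrc, rcg)
  expect_setequal(clrc$tri, on1$tri)
})

test_that("weighted fractions follow AF sums and always total one", {
  v <- variant_set("chr1", c(100, 200, 300), c("C", "C", "T"),
                   c("T", "T", "A"), af = c(0.5, 0.3, 0.2))
  v$sbs_type <- c("C>T", "C>T", "T>A")
  fr <- weighted_sbs_fractions(v)
  expect_equal(fr$fraction[fr$sbs_type == "C>T"], 0.8)
  expect_equal(sum(fr$fraction), 1)
  # a single record carries fraction 1 for its type
  v1 <- v[1, , drop = FALSE]
  fr1 <- weighted_sbs_fractions(v1)
  expect_equal(fr1$fraction[fr1$sbs_type == "C>T"], 1)
  # unweighted mode equals plain count fractions
  fru <- weighted_sbs_fractions(v, weighted = FALSE)
  expect_equal(fru$fraction[fru$sbs_type == "C>T"], 2 / 3)
  v$af <- NA_real_
  expect_error(weighted_sbs_fractions(v), "allele frequency")
})

test_that("intermutational distances are per-chromosome gaps of one type", {
  v <- variant_set(c("chr1", "chr1", "chr1", "chr2"),
                   c(100, 150, 1150, 500), rep("C", 4), rep("T", 4))
  v$sbs_type <- "C>T"
  imd <- intermutational_distances(v)
  expect_equal(imd$imd, c(50, 1000))
  # events on different chromosomes contribute no gap
  v2 <- variant_set(c("chr1", "chr2"), c(100, 100), c("C", "C"), c("T", "T"))
  v2$sbs_type <- "C>T"
  expect_equal(nrow(intermutational_distances(v2)), 0)
})

test_that("uniform placement yields near-exponential spacing", {
  set.seed(7)
  pos <- sort(sample(0:1e7, 1000))
  v <- variant_set("chr1", pos, "C", "T")
  v$sbs_type <- "C>T"
  imd <- intermutational_distances(v)
  expect_equal(mean(imd$imd), 1e4, tolerance = 0.1)
})

test_that("cluster detection finds maximal short-IMD runs", {
  v <- variant_set("chr1", c(10, 20, 30, 5000), rep("C", 4), rep("T", 4))
  cl <- cluster_variants(v, max_imd = 100, min_size = 2)
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cl$clusters$n, 3)
  expect_equal(sum(!is.na(cl$variants$cluster_id)), 3)
  # all gaps beyond the threshold: nothing clusters
  far <- variant_set("chr1", c(0, 1000, 2000), rep("C", 3), rep("T", 3))
  expect_equal(nrow(cluster_variants(far, max_imd = 100)$clusters), 0)
  # infinite threshold: a single cluster per chromosome
  v2 <- variant_set(rep(c("chr1", "chr2"), each = 3),
                    rep(c(0, 1e6, 5e6), 2), rep("C", 6), rep("T", 6))
  cl2 <- cluster_variants(v2, max_imd = Inf)
  expect_equal(nrow(cl2$clusters), 2)
})

test_that("doublet detection merges adjacent pairs into 78 strand-agnostic classes", {
  v <- variant_set("chr1", c(100, 101), c("C", "C"), c("T", "T"), af = c(0.4, 0.6))
  d <- detect_dbs(v)
  expect_equal(d$dbs78, "CC>TT")
  expect_equal(d$af, 0.5)
  # GG>AA collapses to CC>TT
  v2 <- variant_set("chr1", c(100, 101), c("G", "G"), c("A", "A"))
  expect_equal(detect_dbs(v2)$dbs78, "CC>TT")
  # explicit MNP record
  v3 <- variant_set("chr1", 100, "CC", "TT", 0.2)
  expect_equal(detect_dbs(v3)$dbs78, "CC>TT")
  # no adjacent pairs -> empty
  v4 <- variant_set("chr1", c(100, 102), c("C", "C"), c("T", "T"))
  expect_equal(nrow(detect_dbs(v4)), 0)
  # three consecutive: greedy left-to-right pairing leaves the third out
  v5 <- variant_set("chr1", c(100, 101, 102), rep("C", 3), rep("T", 3))
  expect_message(d5 <- detect_dbs(v5), "unpaired")
  expect_equal(nrow(d5), 1)
  expect_equal(d5$pos, 100)
  # the canonical category list has exactly 78 entries
  expect_length(uraseq:::dbs78_channels(), 78)
})

test_that("replication-timing strata partition variants with middle-inclusive bounds", {
  rt <- binned_track(rep("chr1", 3), c(0, 100, 200), c(100, 200, 300),
                     c(3, 2.5, -3), units = "RT_score")
  v <- variant_set("chr1", c(50, 150, 250, 5000), rep("C", 4), rep("T", 4),
                   af = 0.2)
  v$sbs_type <- "C>T"
  s <- stratify_by_rt(v, rt)
  expect_equal(unname(s$counts), c(1, 1, 1, 1))
  expect_equal(s$variants$rt_stratum, c("early", "middle", "late", "unassigned"))
  expect_equal(sum(s$counts), nrow(v))
  # all scores +3: everything early
  rt_hi <- binned_track("chr1", 0, 10000, 3, units = "RT_score")
  expect_equal(unname(stratify_by_rt(v[1:3, ], rt_hi)$counts["early"]), 3)
})

test_that("per-segment fractions reproduce the global value and constructed splits", {
  seg1 <- segmentation("chr1", 0, 10000, "only")
  v <- variant_set("chr1", c(100, 200, 300, 400),
                   c("C", "C", "T", "T"), c("T", "T", "A", "C"),
                   af = c(0.4, 0.2, 0.3, 0.1))
  v$sbs_type <- c("C>T", "C>T", "T>A", "T>C")
  global <- weighted_sbs_fractions(v)
  bys <- fractions_by_segment(v, seg1)
  expect_equal(bys$table$ctot_fraction,
               global$fraction[global$sbs_type == "C>T"])
  # two labels: C>T only in A, other SBS in B
  seg2 <- segmentation(rep("chr1", 2), c(0, 250), c(250, 10000), c("A", "B"))
  bys2 <- fractions_by_segment(v, seg2)
  expect_equal(bys2$table$ctot_fraction[bys2$table$label == "A"], 1)
  expect_equal(bys2$table$ctot_fraction[bys2$table$label == "B"], 0)
  expect_equal(bys2$unassigned, 0)
})
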