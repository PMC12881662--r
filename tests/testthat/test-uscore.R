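# Gene intervals, U-scores, differential calling, class enrichment,
# histograms and network statistics.

genes_fixture <- function() {
  data.frame(gene_id = c("g1", "g2"),
             chrom = "chr1",
             start = c(5000, 5000), end = c(8000, 8000),
             strand = c("+", "-"),
             stringsAsFactors = FALSE)
}

test_that("gene intervals attach a strand-aware promoter and subtract blacklist", {
  g <- genes_fixture()
  iv <- build_gene_intervals(g[1, ], promoter_len = 1000)
  expect_equal(iv[, c("start", "end")], data.frame(start = 4000, end = 8000))
  iv_m <- build_gene_intervals(g[2, ], promoter_len = 1000)
  expect_equal(iv_m[, c("start", "end")], data.frame(start = 5000, end = 9000))

  bl <- data.frame(chrom = "chr1", start = 6000, end = 7000)
  iv_b <- build_gene_intervals(g[1, ], blacklist = bl, promoter_len = 1000)
  expect_equal(iv_b$start, c(4000, 7000))
  expect_equal(iv_b$end, c(6000, 8000))

  # promoter clipped at the chromosome start
  g0 <- data.frame(gene_id = "g0", chrom = "chr1", start = 300, end = 2000,
                   strand = "+")
  expect_equal(build_gene_intervals(g0, promoter_len = 1000)$start, 0)

  dup <- rbind(g, g[1, ])
  expect_error(build_gene_intervals(dup), "duplicate gene_id")
})

test_that("U-scores are coverage-weighted track means; relative mode normalizes", {
  g <- genes_fixture()
  iv <- build_gene_intervals(g, promoter_len = 1000)
  p <- make_track(rep(700, 100), units = "U_per_Mb")
  us <- compute_uscores(p, iv)
  expect_equal(us$uscore, c(700, 700))

  # relative scores: genome-wide mean of fully covered uniform genes is 1
  set.seed(3)
  r <- make_track(runif(100, 0.5, 2))
  rel <- compute_uscores(r, iv, relative = TRUE)
  direct <- average_over_intervals(r, cbind(iv, interval_id = iv$gene_id))
  expect_equal(rel$uscore, direct$mean / track_mean(r))
  # doubling the track leaves relative scores unchanged
  r2 <- make_track(2 * r$value)
  expect_equal(compute_uscores(r2, iv, relative = TRUE)$uscore, rel$uscore)
  # uniform relative track: every fully covered gene scores exactly 1
  uni_rel <- compute_uscores(make_track(rep(3, 100)), iv, relative = TRUE)
  expect_equal(uni_rel$uscore, c(1, 1), tolerance = 1e-9)
})

test_that("Welch test matches the closed-form statistic and handles degeneracy", {
  a <- c(1, 2, 3, 4); b <- a + 10
  w <- welch_two_sample(a, b)
  expect_lt(w$p, 0.01)
  expect_equal(w$p, oracle_welch_p(a, b), tolerance = 1e-12)
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1), mean = runif(1, 0, 2))
    expect_equal(welch_two_sample(x, y)$p, oracle_welch_p(x, y),
                 tolerance = 1e-12)
    # swapping groups negates t, preserves p
    expect_equal(welch_two_sample(y, x)$t, -welch_two_sample(x, y)$t)
  }
  eq <- welch_two_sample(c(2, 2, 2), c(2, 2, 2))
  expect_equal(eq$t, 0); expect_equal(eq$p, 1)
  expect_error(welch_two_sample(1, c(1, 2)), ">= 2")
})

test_that("differential calling applies Eq-style fold change and both gates", {
  A <- matrix(c(10, 10, 14, 14, 20, 20), nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), NULL))
  B <- matrix(c(5, 5, 10, 10, 10, 10), nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), NULL))
  res <- differential_uscore(A, B)
  expect_equal(res$fold_change[res$gene_id == "gA"], 2)
  expect_equal(res$log2_fc[res$gene_id == "gA"], 1)
  # FC = 1.4 fails the fold-change gate no matter how small p is
  expect_false(res$significant[res$gene_id == "gB"])
  # combined score: FC 2 at p 0.01 gives exactly 2
  expect_equal(log2(2) * -log10(0.01), 2)
  expect_equal(res$combined_score, res$log2_fc * res$neg_log10_p)
  # thresholds on the transformed scales travel with the result
  expect_equal(attr(res, "log2_fc_threshold"), log2(1.5))
  expect_equal(attr(res, "neg_log10_p_threshold"), -log10(0.05))
})

test_that("differential calling is group-exchange antisymmetric", {
  set.seed(21)
  A <- matrix(rlnorm(40, 1, 0.3), ncol = 4,
              dimnames = list(paste0("g", 1:10), NULL))
  B <- matrix(rlnorm(40, 1, 0.3), ncol = 4,
              dimnames = list(paste0("g", 1:10), NULL))
  ab <- differential_uscore(A, B)
  ba <- differential_uscore(B, A)
  expect_equal(ba$log2_fc, -ab$log2_fc, tolerance = 1e-12)
  expect_equal(ba$p_value, ab$p_value, tolerance = 1e-12)
  expect_equal(sign(ab$combined_score), sign(ab$log2_fc))
})

test_that("class enrichment matches hand counts and conserves the top set", {
  # 1000 genes; one class occupies exactly the 100 highest scores
  ids <- sprintf("g%04d", 1:1000)
  cls <- setNames(c(rep("hot", 100), rep("cold", 900)), ids)
  us <- data.frame(gene_id = ids, uscore = c(seq(2000, 1901), runif(900, 0, 100)))
  enr <- class_enrichment(us, cls, top_n = 100)
  expect_equal(enr$fold[enr$class == "hot"], 10)
  expect_equal(sum(enr$observed), 100)
  # uniform scores, single class: fold is 1 (ties broken deterministically)
  us1 <- data.frame(gene_id = ids, uscore = rep(1, 1000))
  enr1 <- class_enrichment(us1, setNames(rep("only", 1000), ids), top_n = 200)
  expect_equal(enr1$fold, 1)
  expect_error(class_enrichment(us, cls, top_n = 2000), "top_n")
})

test_that("histograms use half-open bins with explicit overflow", {
  h <- uscore_histogram(runif(50, 0, 12999), 0, 13000, 20)
  expect_length(h$counts, 650)
  h2 <- uscore_histogram(rep(5, 7), 5, 10, 1)
  expect_equal(h2$counts[1], 7)
  set.seed(2)
  x <- c(rnorm(200, 50, 40), NA, NA)
  h3 <- uscore_histogram(x, 0, 100, 7)
  expect_equal(sum(h3$counts) + h3$overflow + h3$underflow, 200)
})

test_that("network summary reproduces 2E/N and local clustering", {
  ring <- cbind(1:200, c(2:200, 1))
  # 118 edges among 200 nodes -> average degree 1.18
  s <- network_summary(ring[1:118, ], 200)
  expect_equal(s$avg_degree, 1.18)
  s2 <- network_summary(rbind(ring, cbind(1:8, 3:10))[1:208, ], 200)
  expect_equal(s2$avg_degree, 2.08)
  # triangle: every node has clustering coefficient 1
  tri <- network_summary(cbind(c("a", "b", "c"), c("b", "c", "a")), 3)
  expect_equal(tri$avg_local_clustering, 1)
  # isolated nodes dilute the average
  tri10 <- network_summary(cbind(c("a", "b", "c"), c("b", "c", "a")), 10)
  expect_equal(tri10$avg_local_clustering, 0.3)
  expect_warning(network_summary(rbind(c(1, 2), c(2, 1)), 5), "duplicate")
  expect_error(network_summary(cbind(1, 1), 5), "self-loop")
})
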