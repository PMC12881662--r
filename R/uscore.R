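# Gene-level U-scores, differential uracilation calling, gene-class
# enrichment and the shared statistics (Welch test, network summary).

#' Build per-gene interval sets (body + core promoter, blacklist-excluded)
#'
#' Each gene is represented by its longest-isoform body extended by a
#' strand-aware upstream core promoter (default 1,000 bp, clipped at the
#' chromosome start), then blacklisted regions are subtracted, leaving a set
#' of disjoint sorted intervals per gene.
#'
#' @param genes data.frame with columns gene_id, chrom, start, end, strand
#'   (0-based half-open, strand "+" or "-").
#' @param blacklist optional data.frame chrom/start/end to subtract.
#' @param promoter_len upstream promoter length in bp (default 1000).
#' @param chrom_lengths optional named vector of chromosome lengths used to
#'   clip promoters/intervals at chromosome ends.
#' @return data.frame (gene_id, chrom, start, end) of disjoint intervals.
#' @export
build_gene_intervals <- function(genes, blacklist = NULL, promoter_len = 1000,
                                 chrom_lengths = NULL) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id: ", genes$gene_id[duplicated(genes$gene_id)][1])
  start <- ifelse(genes$strand == "+",
                  pmax(0, genes$start - promoter_len), genes$start)
  end <- ifelse(genes$strand == "+",
                genes$end, genes$end + promoter_len)
  if (!is.null(chrom_lengths))
    end <- pmin(end, chrom_lengths[genes$chrom])
  ext <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = start, end = end, stringsAsFactors = FALSE)
  if (is.null(blacklist) || nrow(blacklist) == 0) {
    rownames(ext) <- NULL
    return(ext)
  }
  validate_intervals(blacklist, where = "blacklist", allow_overlap = TRUE)
  gg <- same_levels(df_to_granges(ext, keep = "gene_id"),
                    df_to_granges(blacklist))
  sub <- GenomicRanges::subtract(gg[[1]], gg[[2]], ignore.strand = TRUE)
  n_per <- lengths(sub)
  flat <- unlist(sub, use.names = FALSE)
  out <- granges_to_df(flat)
  out <- data.frame(gene_id = rep(ext$gene_id, n_per), out,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compute gene-level U-scores from a probability track
#'
#' The U-score of a gene is the coverage-weighted mean of the p-track over
#' the gene's interval set (body + core promoter minus blacklist). In
#' relative mode the per-gene mean of a cleaned ratio track is divided by
#' the genome-wide length-weighted mean of that same track, making
#' replicates unit-free and directly comparable.
#'
#' @param ptrack a \code{\link{binned_track}}; units \code{"U_per_Mb"} for
#'   absolute scores or \code{"ratio"} for relative mode.
#' @param gene_intervals output of \code{\link{build_gene_intervals}}.
#' @param relative if \code{TRUE}, divide gene means by the genome-wide mean
#'   of \code{ptrack}.
#' @return data.frame (gene_id, uscore, covered_bp); genes with zero track
#'   coverage get \code{NA} scores.
#' @export
compute_uscores <- function(ptrack, gene_intervals, relative = FALSE) {
  if (relative && track_units(ptrack) != "ratio")
    stop("relative U-scores are computed from a ratio track")
  if (!relative && track_units(ptrack) != "U_per_Mb")
    stop("absolute U-scores require a rescaled U_per_Mb p-track")
  iv <- gene_intervals
  iv$interval_id <- seq_len(nrow(iv))
  avg <- average_over_intervals(ptrack, iv)
  w <- avg$covered_bp
  v <- ifelse(is.na(avg$mean), 0, avg$mean) * w
  gsum <- rowsum(cbind(v = v, w = w), iv$gene_id)
  uscore <- ifelse(gsum[, "w"] > 0, gsum[, "v"] / gsum[, "w"], NA_real_)
  if (relative) uscore <- uscore / track_mean(ptrack)
  out <- data.frame(gene_id = rownames(gsum), uscore = as.numeric(uscore),
                    covered_bp = as.numeric(gsum[, "w"]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  n_missing <- sum(is.na(out$uscore))
  if (n_missing > 0)
    message("compute_uscores: ", n_missing, " gene(s) with zero coverage")
  out
}

#' Welch's unequal-variance two-sample t test
#'
#' Thin wrapper over \code{stats::t.test} (Welch-Satterthwaite degrees of
#' freedom) with explicit handling of degenerate inputs: when both groups
#' have zero variance, equal means give t = 0 and p = 1 by convention,
#' unequal means give p = 0.
#'
#' @param a,b numeric vectors, each with at least 2 finite values.
#' @param tails 1 or 2 (default two-sided).
#' @return list(t, df, p).
#' @export
welch_two_sample <- function(a, b, tails = 2) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("welch_two_sample: each group needs >= 2 finite values")
  stopifnot(tails %in% c(1, 2))
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE,
                      alternative = if (tails == 2) "two.sided" else "greater")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Call differentially uracilated genes between two treatments
#'
#' For each gene the fold change is the ratio of the summed replicate
#' U-scores (equivalently, the ratio of group means for balanced designs)
#' and the p-value comes from Welch's two-sample t test on the replicate
#' values. A gene is significant when p < \code{p_thresh} and the fold
#' change exceeds \code{fc_thresh} in either direction, i.e.
#' |log2 FC| > log2(fc_thresh). Raw p-values drive the significance flag; a
#' Benjamini-Hochberg adjusted column is also emitted for reference. The
#' combined ranking score is log2(FC) * (-log10 p).
#'
#' @param groupA,groupB numeric matrices of U-scores, genes in rows (rowname
#'   = gene_id), replicates in columns (>= 2 each). Fold change is A over B.
#' @param fc_thresh fold-change gate (default 1.5).
#' @param p_thresh raw p-value gate (default 0.05).
#' @return data.frame with gene_id, fold_change, log2_fc, p_value,
#'   neg_log10_p, p_adj, significant, combined_score; attributes
#'   \code{log2_fc_threshold} and \code{neg_log10_p_threshold} record the
#'   gates on the transformed scales. Genes present in only one group are
#'   dropped (counted in a message); genes with a zero denominator get
#'   \code{NA} fold changes.
#' @export
differential_uscore <- function(groupA, groupB, fc_thresh = 1.5,
                                p_thresh = 0.05) {
  stopifnot(ncol(groupA) >= 2, ncol(groupB) >= 2)
  common <- intersect(rownames(groupA), rownames(groupB))
  n_drop <- length(union(rownames(groupA), rownames(groupB))) - length(common)
  if (n_drop > 0)
    message("differential_uscore: ", n_drop,
            " gene(s) missing from one group, dropped")
  A <- groupA[common, , drop = FALSE]
  B <- groupB[common, , drop = FALSE]
  sA <- rowSums(A); sB <- rowSums(B)
  fc <- ifelse(sB > 0, sA / sB, NA_real_)
  p <- vapply(seq_along(common), function(i)
    welch_two_sample(A[i, ], B[i, ])$p, numeric(1))
  log2_fc <- log2(fc)
  log2_gate <- log2(fc_thresh)
  p_gate <- -log10(p_thresh)
  sig <- !is.na(fc) & p < p_thresh & abs(log2_fc) > log2_gate
  out <- data.frame(
    gene_id = common,
    fold_change = fc,
    log2_fc = log2_fc,
    p_value = p,
    neg_log10_p = -log10(p),
    p_adj = p.adjust(p, method = "BH"),
    significant = sig,
    combined_score = log2_fc * (-log10(p)),
    stringsAsFactors = FALSE
  )
  attr(out, "log2_fc_threshold") <- log2_gate
  attr(out, "neg_log10_p_threshold") <- p_gate
  out
}

#' Gene-class enrichment among the most uracilated genes
#'
#' Observed versus expected counts of each gene class (GENCODE-style
#' biotype) within the \code{top_n} highest-scoring genes; the expectation
#' is proportional to class size among all scored genes. Ties at the
#' \code{top_n} boundary are broken by gene_id lexicographic order so the
#' selection is deterministic.
#'
#' @param uscores data.frame with gene_id and uscore columns (one sample).
#' @param gene_classes named character vector gene_id -> class label.
#' @param top_n number of top genes to consider (default 2000).
#' @return data.frame (class, observed, expected, fold); fold is \code{NA}
#'   where the expectation is zero.
#' @export
class_enrichment <- function(uscores, gene_classes, top_n = 2000) {
  sc <- uscores[!is.na(uscores$uscore), , drop = FALSE]
  if (top_n > nrow(sc)) stop("top_n exceeds number of scored genes")
  o <- order(-sc$uscore, sc$gene_id)
  top <- sc$gene_id[o][seq_len(top_n)]
  cls_all <- gene_classes[sc$gene_id]
  cls_top <- gene_classes[top]
  classes <- sort(unique(cls_all))
  n_all <- table(factor(cls_all, levels = classes))
  n_top <- table(factor(cls_top, levels = classes))
  expected <- as.numeric(n_all) / nrow(sc) * top_n
  data.frame(class = classes,
             observed = as.numeric(n_top),
             expected = expected,
             fold = ifelse(expected > 0, as.numeric(n_top) / expected, NA_real_),
             stringsAsFactors = FALSE)
}

#' Histogram of U-scores with an explicit overflow bucket
#'
#' Half-open bins [lo + k*w, lo + (k+1)*w); values >= hi are collected in an
#' overflow bucket and values < lo in an underflow bucket, both reported
#' separately so counts always conserve the number of scored genes.
#'
#' @param uscores numeric vector (NA ignored) or data.frame with an
#'   \code{uscore} column.
#' @param lo,hi,bin_width histogram range and bin size (hi > lo, width > 0).
#' @return list(breaks, counts, overflow, underflow, n).
#' @export
uscore_histogram <- function(uscores, lo, hi, bin_width) {
  stopifnot(hi > lo, bin_width > 0)
  x <- if (is.data.frame(uscores)) uscores$uscore else uscores
  x <- x[!is.na(x)]
  n_bins <- ceiling((hi - lo) / bin_width)
  breaks <- lo + bin_width * (0:n_bins)
  overflow <- sum(x >= hi)
  underflow <- sum(x < lo)
  inside <- x[x >= lo & x < hi]
  k <- floor((inside - lo) / bin_width) + 1L
  counts <- tabulate(k, nbins = n_bins)
  list(breaks = breaks, counts = counts, overflow = overflow,
       underflow = underflow, n = length(x))
}

#' Summary statistics of a protein interaction network
#'
#' Average node degree 2E/N and the mean local clustering coefficient over
#' all N nodes (nodes of degree < 2 contribute 0), as reported for STRING
#' networks of top-uracilated gene sets. Duplicate edges are deduplicated
#' with a warning; the node count may exceed the number of nodes that carry
#' edges (isolated genes).
#'
#' @param edges two-column matrix or data.frame of undirected edges
#'   (character or integer node ids), no self-loops.
#' @param n_nodes total number of nodes in the network (>= nodes with edges).
#' @return list(n_nodes, n_edges, avg_degree, avg_local_clustering).
#' @export
network_summary <- function(edges, n_nodes) {
  edges <- as.matrix(edges)
  if (nrow(edges) > 0) {
    if (any(edges[, 1] == edges[, 2])) stop("self-loops not allowed")
    key <- apply(cbind(pmin(edges[, 1], edges[, 2]),
                       pmax(edges[, 1], edges[, 2])), 1, paste, collapse = "\r")
    if (anyDuplicated(key)) {
      warning("duplicate edges removed")
      edges <- edges[!duplicated(key), , drop = FALSE]
    }
  }
  if (nrow(edges) == 0)
    return(list(n_nodes = n_nodes, n_edges = 0L, avg_degree = 0,
                avg_local_clustering = 0))
  em <- matrix(as.character(edges), ncol = 2)
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  n_with_edges <- igraph::vcount(g)
  if (n_nodes < n_with_edges)
    stop("n_nodes smaller than the number of nodes carrying edges")
  n_edges <- igraph::ecount(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  list(n_nodes = n_nodes,
       n_edges = n_edges,
       avg_degree = 2 * n_edges / n_nodes,
       avg_local_clustering = sum(cc) / n_nodes)
}
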