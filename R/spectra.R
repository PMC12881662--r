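# Fixed-order mutational-spectrum vectors (96 / 1,536 / 78 channels),
# cosine comparison, and non-negative least-squares refitting of a measured
# spectrum against reference signatures.

#' Construct a spectrum vector
#'
#' @param values non-negative numeric vector named by channel, or unnamed in
#'   canonical channel order.
#' @param kind "SBS96", "SBS1536" or "DBS78".
#' @param normalized whether values represent a probability vector.
#' @return a \code{spectrum_vector}: named numeric with attributes.
#' @export
spectrum_vector <- function(values, kind = c("SBS96", "SBS1536", "DBS78"),
                            normalized = FALSE) {
  kind <- match.arg(kind)
  channels <- switch(kind, SBS96 = sbs96_channels(),
                     SBS1536 = sbs1536_channels(), DBS78 = dbs78_channels())
  if (is.null(names(values))) {
    if (length(values) != length(channels))
      stop("expected ", length(channels), " values for ", kind)
    names(values) <- channels
  } else {
    if (!all(names(values) %in% channels))
      stop("unknown channel name(s): ",
           paste(head(setdiff(names(values), channels), 3), collapse = ", "))
    full <- setNames(numeric(length(channels)), channels)
    full[names(values)] <- values
    values <- full
  }
  if (any(values < 0)) stop("spectrum values must be non-negative")
  if (normalized) {
    s <- sum(values)
    if (s <= 0) stop("cannot normalize a zero spectrum")
    values <- values / s
  }
  structure(values, kind = kind, normalized = normalized,
            class = "spectrum_vector")
}

#' @export
print.spectrum_vector <- function(x, ...) {
  cat("spectrum_vector:", attr(x, "kind"), "-", length(x), "channels, total",
      format(sum(x)), "\n")
  invisible(x)
}

spectrum_kind <- function(x) attr(x, "kind")

build_channel_spectrum <- function(channels, weights, kind) {
  keep <- !is.na(channels) & !is.na(weights)
  n_skip <- sum(!keep)
  if (n_skip > 0)
    message("spectrum: ", n_skip, " record(s) skipped (missing context or weight)")
  tab <- tapply(weights[keep], channels[keep], sum)
  spectrum_vector(setNames(as.numeric(tab), names(tab)), kind = kind)
}

#' Build the 96-channel trinucleotide substitution spectrum
#'
#' Channels are (5' base, pyrimidine-strand ref>alt, 3' base) in COSMIC
#' canonical order. Records with ambiguous (N) or chromosome-edge contexts
#' are skipped and counted. With \code{weighted = TRUE} each record
#' contributes its allele frequency instead of a unit count.
#'
#' @param vset a \code{\link{variant_set}} classified with
#'   \code{\link{classify_sbs}} (or a raw set plus \code{genome}).
#' @param genome optional \code{DNAStringSet}; required when \code{vset} has
#'   not been classified yet.
#' @param weighted weight by allele frequency (default FALSE: counts).
#' @return a \code{\link{spectrum_vector}} of kind "SBS96".
#' @export
sbs96_matrix <- function(vset, genome = NULL, weighted = FALSE) {
  if (!"tri" %in% names(vset)) {
    if (is.null(genome)) stop("unclassified variant set: supply genome")
    vset <- classify_sbs(vset, genome)
  }
  w <- if (weighted) vset$af else rep(1, nrow(vset))
  build_channel_spectrum(vset$tri, w, "SBS96")
}

#' Build the 1,536-channel pentanucleotide substitution spectrum
#'
#' As \code{\link{sbs96_matrix}} but with two flanking bases on each side
#' (+/-2), on the pyrimidine strand.
#'
#' @inheritParams sbs96_matrix
#' @return a \code{\link{spectrum_vector}} of kind "SBS1536".
#' @export
sbs1536_matrix <- function(vset, genome = NULL, weighted = FALSE) {
  if (!"penta" %in% names(vset)) {
    if (is.null(genome)) stop("unclassified variant set: supply genome")
    vset <- classify_sbs(vset, genome)
  }
  w <- if (weighted) vset$af else rep(1, nrow(vset))
  build_channel_spectrum(vset$penta, w, "SBS1536")
}

#' Collapse a 1,536-channel spectrum to its 96-channel marginal
#'
#' Sums over the outer (+/-2) context positions; exactly reproduces the
#' 96-channel spectrum built from the same records.
#'
#' @param spec a \code{\link{spectrum_vector}} of kind "SBS1536".
#' @return a \code{\link{spectrum_vector}} of kind "SBS96".
#' @export
collapse_1536_to_96 <- function(spec) {
  stopifnot(spectrum_kind(spec) == "SBS1536")
  nm <- names(spec)
  tri <- paste0(substr(nm, 2, 2), substr(nm, 3, nchar(nm) - 2),
                substr(nm, nchar(nm) - 1, nchar(nm) - 1))
  tab <- tapply(as.numeric(spec), tri, sum)
  spectrum_vector(setNames(as.numeric(tab), names(tab)), kind = "SBS96")
}

#' Build the 78-channel doublet substitution spectrum
#'
#' @param doublets output of \code{\link{detect_dbs}}.
#' @param weighted weight by allele frequency (default FALSE).
#' @return a \code{\link{spectrum_vector}} of kind "DBS78".
#' @export
dbs78_matrix <- function(doublets, weighted = FALSE) {
  if (nrow(doublets) == 0)
    return(spectrum_vector(numeric(78), kind = "DBS78"))
  w <- if (weighted) doublets$af else rep(1, nrow(doublets))
  build_channel_spectrum(doublets$dbs78, w, "DBS78")
}

#' Cosine similarity between two spectra
#'
#' a.b / (|a||b|); scale-invariant, in [0, 1] for non-negative spectra.
#'
#' @param a,b \code{\link{spectrum_vector}}s of the same kind (or plain
#'   numeric vectors of equal length), both non-zero.
#' @return scalar similarity.
#' @export
cosine_similarity <- function(a, b) {
  if (inherits(a, "spectrum_vector") && inherits(b, "spectrum_vector") &&
      spectrum_kind(a) != spectrum_kind(b))
    stop("spectra of different kinds")
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("length mismatch")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Refit a measured spectrum as a non-negative mixture of reference
#' signatures
#'
#' Solves weights = argmin ||measured - sum w_i c_i||_2 subject to w_i >= 0
#' (non-negative least squares) on probability-normalized vectors, the
#' deterministic constrained-least-squares equivalent of signature
#' refitting with a fixed component set. Contributions are the weights
#' normalized to sum 1; the reconstituted spectrum is the renormalized
#' mixture and its cosine similarity to the measured spectrum is reported.
#'
#' @param measured a \code{\link{spectrum_vector}} (normalized internally).
#' @param components named list of \code{spectrum_vector}s (or a matrix with
#'   channels in rows), each normalized internally. Duplicate components
#'   make weights non-unique; ties resolve deterministically by listing
#'   order (NNLS active-set), with a warning.
#' @return list(weights, contributions, reconstituted, cosine, residual).
#' @export
refit_spectrum <- function(measured, components) {
  m <- as.numeric(measured); m <- m / sum(m)
  if (is.matrix(components)) {
    C <- components
  } else {
    C <- do.call(cbind, lapply(components, as.numeric))
  }
  if (is.null(colnames(C)))
    colnames(C) <- paste0("component", seq_len(ncol(C)))
  if (nrow(C) != length(m)) stop("component/measured channel mismatch")
  C <- sweep(C, 2, colSums(C), "/")
  if (anyDuplicated(t(C)) > 0)
    warning("duplicate components: weights are not unique; ",
            "deterministic tie-break by listing order")
  fit <- pracma::lsqnonneg(C, m)
  w <- setNames(as.numeric(fit$x), colnames(C))
  total <- sum(w)
  contributions <- if (total > 0) w / total else w
  recon <- as.numeric(C %*% w)
  if (sum(recon) > 0) recon <- recon / sum(recon)
  recon <- spectrum_vector(setNames(recon, rownames(C) %||% names(measured)),
                           kind = spectrum_kind(measured) %||% "SBS96",
                           normalized = TRUE)
  list(weights = w,
       contributions = contributions,
       reconstituted = recon,
       cosine = cosine_similarity(m, as.numeric(recon)),
       residual = sqrt(sum((m - as.numeric(C %*% w))^2)))
}
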