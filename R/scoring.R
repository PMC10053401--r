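#' Score samples by a gene signature
#'
#' The signature score of a sample is the unweighted arithmetic mean of
#' the signature genes' expression, on whatever common unit scale the
#' matrix is in (log2(TPM+1) for cross-cohort comparability). All
#' signature genes must be present: a silent mean over a subset would not
#' be the same score.
#'
#' @param m an [expression_matrix()].
#' @param sig a [signature_set()].
#' @return Named numeric vector of per-sample scores.
#' @examples
#' m <- expression_matrix(matrix(c(2, 2, 4, 4), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("gA", "gB"))))
#' score_samples(m, signature_set("toy", c("gA", "gB")))
#' @export
score_samples <- function(m, sig) {
  if (!inherits(m, "expr_matrix")) stop("`m` must be an expr_matrix")
  if (!inherits(sig, "signature_set")) stop("`sig` must be a signature_set")
  missing <- setdiff(sig$genes, feature_ids(m))
  if (length(missing))
    stop("signature gene(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  rowMeans(unclass(m)[, sig$genes, drop = FALSE])
}

#' Per-gene z-scores
#'
#' Standardizes every gene (column) to mean 0 and sample SD 1 (n-1
#' denominator), as used for heatmap displays. Scoring itself never uses
#' z-scores.
#'
#' @param m an [expression_matrix()] with no constant genes.
#' @return Plain numeric matrix of z-scores with the same dimnames.
#' @export
zscore_genes <- function(m) {
  vals <- unclass(m)
  sds <- apply(vals, 2L, stats::sd)
  const <- which(!is.na(sds) & sds == 0)
  if (length(const))
    stop("constant gene(s) cannot be z-scored: ",
         paste(colnames(vals)[utils::head(const, 5)], collapse = ", "))
  out <- scale(vals)
  matrix(out, nrow(out), ncol(out), dimnames = dimnames(out))
}

#' Complete-linkage hierarchical clustering on Euclidean distances
#'
#' Agglomerative complete-linkage clustering of samples or genes using
#' Euclidean distance, the combination used for the package's heatmap
#' displays. Items are ordered lexicographically by id before clustering
#' so tie-breaking is deterministic.
#'
#' @param m an [expression_matrix()] or plain numeric matrix with
#'   dimnames.
#' @param axis cluster `"samples"` (rows) or `"genes"` (columns).
#' @return A [stats::hclust] object (merge heights are non-decreasing for
#'   complete linkage) with attributes `linkage` and `metric`.
#' @export
hclust_complete <- function(m, axis = c("samples", "genes")) {
  axis <- match.arg(axis)
  vals <- unclass(m)
  x <- if (axis == "samples") vals else t(vals)
  if (nrow(x) < 2L) stop("need at least 2 items to cluster")
  x <- x[order(rownames(x)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(x), method = "complete")
  attr(hc, "linkage") <- "complete"
  attr(hc, "metric") <- "euclidean"
  hc
}

#' Gene-gene correlation matrix over a signature
#'
#' Pairwise-complete Pearson correlations among the signature genes, the
#' co-expression display used to check that a signature is coordinately
#' expressed in a cohort.
#'
#' @param m an [expression_matrix()] with at least 4 samples.
#' @param sig a [signature_set()] whose genes are all present in `m`.
#' @return Symmetric correlation matrix with unit diagonal; genes constant
#'   across samples are dropped with a message.
#' @export
gene_gene_corr <- function(m, sig) {
  if (nrow(m) < 4L) stop("need at least 4 samples")
  missing <- setdiff(sig$genes, feature_ids(m))
  if (length(missing))
    stop("signature gene(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  vals <- unclass(m)[, sig$genes, drop = FALSE]
  sds <- apply(vals, 2L, stats::sd, na.rm = TRUE)
  const <- !is.na(sds) & sds == 0
  if (any(const)) {
    message("gene_gene_corr: dropping constant gene(s): ",
            paste(colnames(vals)[const], collapse = ", "))
    vals <- vals[, !const, drop = FALSE]
  }
  cc <- stats::cor(vals, use = "pairwise.complete.obs")
  diag(cc) <- 1
  cc
}

#' PCA of cohorts on signature genes
#'
#' Concatenates several cohorts' expression matrices restricted to the
#' signature genes, centers on the pooled per-gene means (no per-cohort
#' batch correction) and computes principal components. Coordinates are
#' reproducible up to the usual PCA sign ambiguity and do not depend on
#' the order in which cohorts are supplied.
#'
#' @param matrices named list of [expression_matrix()]s (names are cohort
#'   labels), all containing every signature gene on a common unit scale.
#' @param sig a [signature_set()].
#' @return A `signature_pca`: list with `scores` (data.frame `sample_id`,
#'   `cohort`, `PC1`, `PC2`), `explained` (non-increasing fractions of
#'   variance for all components) and `rotation`.
#' @export
pca_on_signature <- function(matrices, sig) {
  if (inherits(matrices, "expr_matrix")) matrices <- list(cohort1 = matrices)
  if (is.null(names(matrices)) || any(!nzchar(names(matrices))))
    names(matrices) <- paste0("cohort", seq_along(matrices))
  blocks <- lapply(names(matrices), function(lab) {
    m <- matrices[[lab]]
    missing <- setdiff(sig$genes, feature_ids(m))
    if (length(missing))
      stop("cohort '", lab, "' lacks signature gene(s): ",
           paste(missing, collapse = ", "))
    unclass(m)[, sig$genes, drop = FALSE]
  })
  x <- do.call(rbind, blocks)
  cohort <- rep(names(matrices), vapply(blocks, nrow, integer(1)))
  if (nrow(x) < 2L) stop("need at least 2 samples for PCA")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- data.frame(sample_id = rownames(x), cohort = cohort,
                       PC1 = pc$x[, 1],
                       PC2 = if (ncol(pc$x) >= 2) pc$x[, 2] else 0,
                       stringsAsFactors = FALSE)
  rownames(scores) <- NULL
  structure(list(scores = scores, explained = expl,
                 rotation = pc$rotation),
            class = "signature_pca")
}

#' @export
print.signature_pca <- function(x, ...) {
  cat(sprintf("<signature_pca> %d samples, %d cohorts; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), length(unique(x$scores$cohort)),
              100 * x$explained[1],
              100 * ifelse(length(x$explained) > 1, x$explained[2], 0)))
  invisible(x)
}

#' @export
plot.signature_pca <- function(x, ...) {
  co <- factor(x$scores$cohort)
  plot(x$scores$PC1, x$scores$PC2, col = as.integer(co), pch = 19,
       xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained[1]),
       ylab = sprintf("PC2 (%.1f%%)",
                      100 * ifelse(length(x$explained) > 1,
                                   x$explained[2], 0)), ...)
  graphics::legend("topright", legend = levels(co), col = seq_along(levels(co)),
                   pch = 19, bty = "n")
  invisible(x)
}

#' Greedy backward reduction of a signature
#'
#' Iteratively eliminates the signature member whose removal most improves
#' the absolute correlation between the signature score (mean expression)
#' and drug sensitivity, stopping when no single removal improves |r| or
#' when two genes remain. Ties are broken by gene symbol. The achieved |r|
#' along the trace is non-decreasing by construction.
#'
#' @param sig a [signature_set()] scored on `m`.
#' @param m an [expression_matrix()].
#' @param s a [sensitivity_vector()] (at least 4 shared samples).
#' @param transform sensitivity transform, as in [associate_layer()].
#' @return A `sig_reduction`: list with `signature` (the reduced
#'   [signature_set()]), `removed` (gene symbols, in removal order),
#'   `trace` (data.frame `step`, `removed`, `r_abs`; step 0 is the full
#'   signature) and `initial_r`.
#' @export
reduce_signature <- function(sig, m, s, transform = c("ln", "identity")) {
  transform <- match.arg(transform)
  missing <- setdiff(sig$genes, feature_ids(m))
  if (length(missing))
    stop("signature gene(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  al <- align_samples(m, sensitivity_values(s, transform))
  vals <- al$m[, sig$genes, drop = FALSE]
  sv <- al$s

  score_r <- function(genes)
    abs(stats::cor(rowMeans(vals[, genes, drop = FALSE]), sv))
  cur <- sig$genes
  r_cur <- score_r(cur)
  trace <- data.frame(step = 0L, removed = NA_character_, r_abs = r_cur,
                      stringsAsFactors = FALSE)
  step <- 0L
  while (length(cur) > 2L) {
    r_wo <- vapply(cur, function(g) score_r(setdiff(cur, g)), numeric(1))
    best <- order(-r_wo, cur)[1L]           # tie-break by gene symbol
    if (r_wo[best] <= r_cur) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, removed = cur[best],
                                     r_abs = r_wo[best]))
    r_cur <- r_wo[best]
    cur <- setdiff(cur, cur[best])
  }
  structure(list(
    signature = signature_set(paste0(sig$name, "_reduced"), cur),
    removed = trace$removed[-1L],
    trace = trace,
    initial_r = trace$r_abs[1L]
  ), class = "sig_reduction")
}

#' @export
print.sig_reduction <- function(x, ...) {
  cat(sprintf("<sig_reduction> %d -> %d genes; |r| %.4f -> %.4f\n",
              length(x$signature$genes) + length(x$removed),
              length(x$signature$genes),
              x$initial_r, utils::tail(x$trace$r_abs, 1)))
  if (length(x$removed))
    cat("  removed:", paste(x$removed, collapse = ", "), "\n")
  invisible(x)
}

#' Per-entity responder fractions relative to a reference score
#'
#' For each cancer entity, the fraction of tumors whose signature score is
#' at or below the reference score (e.g. the score of a highly sensitive
#' cell line); ties count as responders. Scores must be on a common unit
#' scale across entities and reference.
#'
#' @param score named numeric vector of per-tumor signature scores.
#' @param entity character vector of entity labels, same length/order as
#'   `score`.
#' @param reference_score reference score (plain number on the same
#'   scale).
#' @return Data.frame with columns `entity`, `n`, `mean_score`,
#'   `responder_fraction`, one row per non-empty entity (entities with no
#'   finite scores are omitted with a message).
#' @export
responder_fraction <- function(score, entity, reference_score) {
  if (length(score) != length(entity))
    stop("`score` and `entity` must have equal length")
  stopifnot_scalar_num(reference_score, "reference_score")
  ok <- is.finite(score)
  ents <- unique(as.character(entity))
  rows <- lapply(ents, function(e) {
    sc <- score[ok & entity == e]
    if (length(sc) == 0L) {
      message("responder_fraction: entity '", e, "' has no scores; omitted")
      return(NULL)
    }
    data.frame(entity = e, n = length(sc), mean_score = mean(sc),
               responder_fraction = mean(sc <= reference_score),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
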