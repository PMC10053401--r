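#' Pearson correlation with a two-sided p-value
#'
#' Pairwise-complete Pearson correlation and the usual two-sided p-value
#' from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom
#' (identical to [stats::cor.test()]). For `|r| = 1` the p-value is
#' reported as the smallest representable positive double rather than 0.
#'
#' @param x,y numeric vectors of equal length; entries where either is
#'   missing are dropped pairwise.
#' @return List with `r`, `p`, `n_used`.
#' @examples
#' pearson_with_p(1:5, c(2, 1, 4, 3, 6))
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs, got ", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: correlation undefined")
  r <- stats::cor(x, y)
  list(r = r, p = .pearson_p(r, n), n_used = n)
}

.pearson_p <- function(r, n) {
  p <- ifelse(abs(r) >= 1, .Machine$double.xmin, {
    tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    2 * stats::pt(-abs(tval), n - 2)
  })
  pmax(p, .Machine$double.xmin)
}

# vectorized gene-wise correlation of a samples x features matrix with a
# sensitivity vector, pairwise-complete; returns kept stats + skip log
.assoc_stats <- function(vals, sv) {
  if (all(!is.finite(sv))) stop("sensitivity values are all missing")
  r <- suppressWarnings(
    as.numeric(stats::cor(vals, sv, use = "pairwise.complete.obs")))
  n_used <- as.integer(colSums(!is.na(vals) & !is.na(sv)))
  feature_id <- colnames(vals)
  too_few <- n_used < 4L
  constant <- !too_few & is.na(r)
  skipped <- data.frame(
    feature_id = feature_id[too_few | constant],
    reason = c(rep("fewer than 4 complete pairs", sum(too_few)),
               rep("constant over complete pairs", sum(constant))),
    stringsAsFactors = FALSE)
  keep <- !(too_few | constant)
  data_kept <- data.frame(feature_id = feature_id[keep], r = r[keep],
                          p = .pearson_p(r[keep], n_used[keep]),
                          n_used = n_used[keep], stringsAsFactors = FALSE)
  list(stats = data_kept, skipped = skipped)
}

#' Gene-wise association of one omics layer with drug sensitivity
#'
#' Correlates every feature of a layer with the sensitivity vector
#' (Pearson, pairwise-complete) and ranks features by ascending p-value
#' (lower p, lower rank; ties get average ranks). Constant features and
#' features with fewer than 4 complete pairs are skipped and logged on the
#' result, never silently reported as r = 0.
#'
#' @param m an [expression_matrix()].
#' @param s a [sensitivity_vector()] sharing at least 4 sample ids with `m`.
#' @param transform `"ln"` (default; EC50 values are correlated on the
#'   natural-log scale) or `"identity"`.
#' @return A `layer_assoc` data.frame with columns `feature_id`, `r`, `p`,
#'   `n_used`, `rank`, carrying attributes `layer`, `transform` and
#'   `skipped` (a data.frame of skipped features with reasons).
#' @export
associate_layer <- function(m, s, transform = c("ln", "identity")) {
  transform <- match.arg(transform)
  if (!inherits(m, "expr_matrix")) stop("`m` must be an expr_matrix")
  if (!inherits(s, "sensitivity_vector"))
    stop("`s` must be a sensitivity_vector")
  al <- align_samples(m, sensitivity_values(s, transform))
  res <- .assoc_stats(al$m, al$s)
  out <- res$stats
  out$rank <- rank(out$p, ties.method = "average")
  if (nrow(res$skipped) > 0)
    message("associate_layer: skipped ", nrow(res$skipped), " feature(s): ",
            paste(utils::head(res$skipped$feature_id, 5), collapse = ", "),
            if (nrow(res$skipped) > 5) ", ..." else "")
  structure(out, layer = attr(m, "layer"), transform = transform,
            skipped = res$skipped,
            class = c("layer_assoc", "data.frame"))
}

#' Combine expression and proteomics associations by average rank
#'
#' Restricts both layers to their shared features, re-ranks p-values
#' within that overlap universe (average ties), and averages the two ranks
#' per gene together with the two correlation coefficients. Symmetric in
#' its two arguments; the result is sorted by ascending average rank.
#'
#' @param a_expr,a_prot `layer_assoc` results from [associate_layer()].
#' @return A `combined_assoc` data.frame with columns `feature_id`,
#'   `r_expr`, `r_prot`, `avg_r`, `p_expr`, `p_prot`, `rank_expr`,
#'   `rank_prot`, `avg_rank`.
#' @export
combine_layers <- function(a_expr, a_prot) {
  shared <- intersect(a_expr$feature_id, a_prot$feature_id)
  if (length(shared) == 0L) stop("no shared features between the two layers")
  e <- a_expr[match(shared, a_expr$feature_id), ]
  p <- a_prot[match(shared, a_prot$feature_id), ]
  rank_expr <- rank(e$p, ties.method = "average")
  rank_prot <- rank(p$p, ties.method = "average")
  out <- data.frame(feature_id = shared,
                    r_expr = e$r, r_prot = p$r,
                    avg_r = (e$r + p$r) / 2,
                    p_expr = e$p, p_prot = p$p,
                    rank_expr = rank_expr, rank_prot = rank_prot,
                    avg_rank = (rank_expr + rank_prot) / 2,
                    stringsAsFactors = FALSE)
  out <- out[order(out$avg_rank, out$feature_id), ]
  rownames(out) <- NULL
  structure(out, class = c("combined_assoc", "data.frame"))
}

#' @export
print.combined_assoc <- function(x, n = 10L, ...) {
  cat(sprintf("<combined_assoc> %d shared features, ranked by average rank\n",
              nrow(x)))
  print.data.frame(utils::head(x, n), digits = 4)
  if (nrow(x) > n) cat("... (", nrow(x) - n, " more)\n", sep = "")
  invisible(x)
}

#' @export
plot.combined_assoc <- function(x, ...) {
  plot(x$avg_r, -log10(pmax(x$avg_rank, 0.5) / nrow(x)),
       xlab = "average Pearson r",
       ylab = "-log10(average rank / n features)",
       main = "rank-combined association", ...)
  invisible(x)
}

#' Select a signature by average-rank cutoff
#'
#' Keeps genes whose average rank is strictly below the cutoff, ordered by
#' average rank. The default cutoff of 38 is the stringent average-rank
#' threshold that yields the 15-gene antioxidant-capacity biomarker set on
#' the original panel.
#'
#' @param ca a `combined_assoc` from [combine_layers()].
#' @param avg_rank_cutoff strict upper bound on the average rank.
#' @param name name for the resulting signature.
#' @return A [signature_set()].
#' @export
select_signature <- function(ca, avg_rank_cutoff = 38, name = "signature") {
  sel <- ca[ca$avg_rank < avg_rank_cutoff, ]
  if (nrow(sel) == 0L)
    stop("no genes with average rank < ", avg_rank_cutoff,
         "; smallest observed is ", format(min(ca$avg_rank), digits = 4),
         " - consider a larger cutoff")
  if (nrow(sel) < 2L)
    stop("only one gene below the cutoff; a signature needs >= 2 genes ",
         "- consider a larger cutoff")
  sel <- sel[order(sel$avg_rank, sel$feature_id), ]
  signature_set(name, sel$feature_id)
}

#' Filter a layer association by p-value
#'
#' Strict `p < p_cutoff` subset, used e.g. to screen a methylation layer
#' with a stringent cutoff (0.001).
#'
#' @param a a `layer_assoc` from [associate_layer()].
#' @param p_cutoff strict upper bound on the p-value.
#' @return The filtered `layer_assoc` (attributes preserved).
#' @export
filter_by_p <- function(a, p_cutoff) {
  keep <- a$p < p_cutoff
  out <- a[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("layer", "transform", "skipped")] <-
    attributes(a)[c("layer", "transform", "skipped")]
  out
}
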