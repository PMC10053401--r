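#' Expression matrix container
#'
#' Lightweight container for a samples-by-features numeric matrix from one
#' omics layer. Rows are samples, columns are features (genes, proteins or
#' methylation clusters); both must carry unique ids.
#'
#' @param values numeric matrix, samples in rows, features in columns, with
#'   rownames (sample ids) and colnames (feature ids).
#' @param layer omics layer, one of `"expression"`, `"proteomics"`,
#'   `"methylation"`.
#' @param units measurement units, one of `"log2tpm1"` (log2(TPM+1)),
#'   `"normalized_protein"`, `"beta"`, `"raw_tpm"`, `"rpkm"`.
#' @return An object of class `expr_matrix`: the matrix with `layer` and
#'   `units` attributes.
#' @examples
#' m <- expression_matrix(
#'   matrix(1:4, 2, 2, dimnames = list(c("s1", "s2"), c("gA", "gB"))),
#'   layer = "expression", units = "log2tpm1"
#' )
#' @export
expression_matrix <- function(values,
                              layer = c("expression", "proteomics",
                                        "methylation"),
                              units = c("log2tpm1", "normalized_protein",
                                        "beta", "raw_tpm", "rpkm")) {
  layer <- match.arg(layer)
  units <- match.arg(units)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x features)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample ids as rownames and feature ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (units == "log2tpm1" && any(values < 0, na.rm = TRUE))
    stop("log2(TPM+1) values cannot be negative")
  structure(values, layer = layer, units = units,
            class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d samples x %d features [layer: %s, units: %s]\n",
              nrow(x), ncol(x), attr(x, "layer"), attr(x, "units")))
  k <- min(5L, nrow(x)); j <- min(5L, ncol(x))
  print(unclass(x)[seq_len(k), seq_len(j), drop = FALSE])
  if (nrow(x) > k || ncol(x) > j) cat("...\n")
  invisible(x)
}

#' Sample ids / feature ids of a container
#'
#' @param x an `expr_matrix` or `sensitivity_vector`.
#' @return Character vector of ids.
#' @export
sample_ids <- function(x) {
  if (inherits(x, "expr_matrix")) return(rownames(x))
  if (inherits(x, "sensitivity_vector")) return(names(x))
  stop("no sample ids for objects of class ", paste(class(x), collapse = "/"))
}

#' @rdname sample_ids
#' @export
feature_ids <- function(x) {
  if (inherits(x, "expr_matrix")) return(colnames(x))
  stop("no feature ids for objects of class ", paste(class(x), collapse = "/"))
}

#' Per-sample drug-sensitivity vector
#'
#' Holds one drug-response scalar per sample: an EC50 in micromolar, its
#' natural log, or an AUC from a dose-response screen (lower AUC = more
#' sensitive).
#'
#' @param values named numeric vector (names are sample ids).
#' @param metric `"ec50"`, `"ln_ec50"` or `"auc"`.
#' @return Object of class `sensitivity_vector`.
#' @export
sensitivity_vector <- function(values, metric = c("ec50", "ln_ec50", "auc")) {
  metric <- match.arg(metric)
  if (!is.numeric(values) || is.null(names(values)))
    stop("`values` must be a named numeric vector")
  if (anyDuplicated(names(values))) stop("duplicate sample ids")
  if (metric == "ec50" && any(values <= 0, na.rm = TRUE))
    stop("EC50 values must be strictly positive")
  structure(values, metric = metric, class = "sensitivity_vector")
}

#' @export
print.sensitivity_vector <- function(x, ...) {
  cat(sprintf("<sensitivity_vector> %d samples [metric: %s]\n",
              length(x), attr(x, "metric")))
  print(utils::head(unclass(x)))
  if (length(x) > 6L) cat("...\n")
  invisible(x)
}

#' Transform a sensitivity vector onto the scale used for correlation
#'
#' The association analysis correlates expression with ln(EC50); AUC values
#' and already-log values pass through unchanged.
#'
#' @param s a [sensitivity_vector()].
#' @param transform `"ln"` (natural log of EC50) or `"identity"`.
#' @return Named numeric vector on the requested scale.
#' @export
sensitivity_values <- function(s, transform = c("ln", "identity")) {
  transform <- match.arg(transform)
  v <- unclass(s)
  metric <- attr(s, "metric")
  if (transform == "ln" && identical(metric, "ec50")) v <- log(v)
  attr(v, "metric") <- NULL
  v
}

#' Gene signature set
#'
#' An ordered set of gene symbols scored, by convention, as the unweighted
#' mean expression of its members per sample.
#'
#' @param name short signature name.
#' @param genes character vector of at least two unique gene symbols.
#' @return Object of class `signature_set`: list with `name`, `genes` and
#'   the fixed `score_rule = "mean"`.
#' @examples
#' signature_set("toy", c("gA", "gB"))
#' @export
signature_set <- function(name, genes) {
  genes <- as.character(genes)
  if (length(genes) < 2L) stop("a signature needs at least 2 genes")
  if (anyDuplicated(genes))
    stop("duplicate genes in signature: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  structure(list(name = as.character(name)[1], genes = genes,
                 score_rule = "mean"),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set> '%s': %d genes (score = mean expression)\n",
              x$name, length(x$genes)))
  cat(" ", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.signature_set <- function(x) length(x$genes)

# shared sample alignment: intersect ids preserving matrix order
align_samples <- function(m, s, min_n = 4L) {
  shared <- intersect(sample_ids(m), names(s))
  if (length(shared) == 0L) stop("no shared samples between matrix and sensitivity")
  if (length(shared) < min_n)
    stop("need at least ", min_n, " shared samples, got ", length(shared))
  list(m = unclass(m)[shared, , drop = FALSE], s = unclass(s)[shared])
}

stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("`", name, "` must be a finite numeric scalar")
  if (positive && x <= 0) stop("`", name, "` must be > 0")
  invisible(x)
}
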