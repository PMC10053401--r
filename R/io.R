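#' Read a samples-by-features matrix from TSV/CSV
#'
#' Expects a header row of feature ids and a first column of sample ids.
#' The delimiter (tab or comma) is sniffed from the header line; TSV is the
#' canonical format. Missing values are encoded `NA`. Files with ragged
#' rows, duplicate ids or non-numeric cells are rejected rather than
#' silently padded or coerced.
#'
#' @param path file path.
#' @param layer,units passed to [expression_matrix()].
#' @return An [expression_matrix()].
#' @seealso [write_matrix()]
#' @export
read_matrix <- function(path, layer = "expression", units = "log2tpm1") {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  nf <- utils::count.fields(path, sep = sep, quote = "\"")
  if (length(unique(nf)) != 1L)
    stop("ragged rows in ", path, ": lines ",
         paste(utils::head(which(nf != nf[1]), 5), collapse = ", "),
         " have a different field count (truncated file?)")
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2L) stop("expected a sample-id column plus >=1 feature column")
  sids <- df[[1L]]
  fids <- colnames(df)[-1L]
  if (anyDuplicated(sids))
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(sids[duplicated(sids)]), collapse = ", "))
  if (anyDuplicated(fids))
    stop("duplicate feature ids in header of ", path, ": ",
         paste(unique(fids[duplicated(fids)]), collapse = ", "))
  vals <- matrix(NA_real_, nrow(df), length(fids),
                 dimnames = list(sids, fids))
  for (j in seq_along(fids)) {
    raw <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw) & raw != "NA")
    if (length(bad))
      stop("non-numeric cell in ", path, " at row '", sids[bad[1]],
           "', column '", fids[j], "': '", raw[bad[1]], "'")
    vals[, j] <- num
  }
  expression_matrix(vals, layer = layer, units = units)
}

#' Write a matrix to TSV
#'
#' Writes with 15 significant digits so that `read_matrix(write_matrix(m))`
#' round-trips to well below 1e-9.
#'
#' @param m an [expression_matrix()] (or plain named matrix).
#' @param path output path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, sep = "\t") {
  vals <- unclass(m)
  out <- cbind(sample_id = rownames(vals),
               as.data.frame(format(vals, digits = 15, trim = TRUE,
                                    scientific = FALSE)))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert an RPKM matrix to log2(TPM+1)
#'
#' Per sample, TPM_g = RPKM_g / sum_g(RPKM_g) * 1e6 followed by log2(TPM+1).
#' The per-sample TPM vector sums to one million before the log transform,
#' so rescaling all RPKM values of a sample by a constant leaves the output
#' unchanged.
#'
#' @param m an [expression_matrix()] with `units = "rpkm"`; all values must
#'   be non-negative and every sample must have a positive total.
#' @return An [expression_matrix()] with `units = "log2tpm1"`.
#' @export
rpkm_to_log2tpm <- function(m) {
  if (!inherits(m, "expr_matrix") || !identical(attr(m, "units"), "rpkm"))
    stop("`m` must be an expr_matrix with units 'rpkm'")
  vals <- unclass(m)
  if (any(vals < 0, na.rm = TRUE)) stop("RPKM values must be non-negative")
  tot <- rowSums(vals, na.rm = TRUE)
  zero <- which(tot <= 0)
  if (length(zero))
    stop("all-zero sample(s): ", paste(rownames(vals)[zero], collapse = ", "))
  tpm <- sweep(vals, 1L, tot, "/") * 1e6
  expression_matrix(log2(tpm + 1), layer = attr(m, "layer"),
                    units = "log2tpm1")
}

# the 15-gene antioxidant-capacity biomarker set; AIFM2 is also known as FSP1
.acb15_genes <- c("ME1", "PGD", "UGDH",
                  "GCLM", "GSR", "SLC7A11", "TXN", "AIFM2",
                  "CBR1", "BLVRB", "AKR1C1", "AKR1C3", "PTGR1", "ALDH3A1",
                  "CYP4F11")
.acb11_drop <- c("AKR1C1", "BLVRB", "GSR", "PTGR1")

#' Built-in antioxidant-capacity biomarker (ACB) signatures
#'
#' `"ACB15"` is the 15-gene antioxidant-capacity biomarker set covering
#' NADP regeneration (ME1, PGD, UGDH), antioxidation (GCLM, GSR, SLC7A11,
#' TXN, AIFM2) and detoxification (CBR1, BLVRB, AKR1C1, AKR1C3, PTGR1,
#' ALDH3A1, CYP4F11). `"ACB11"` is its 11-gene reduction without AKR1C1,
#' BLVRB, GSR and PTGR1, the members with minor contribution to the
#' drug-sensitivity correlation in AML cell lines.
#'
#' @param name `"ACB15"` or `"ACB11"`.
#' @return A [signature_set()].
#' @examples
#' load_builtin_signature("ACB15")
#' @export
load_builtin_signature <- function(name = c("ACB15", "ACB11")) {
  name <- match.arg(name)
  genes <- switch(name,
                  ACB15 = .acb15_genes,
                  ACB11 = setdiff(.acb15_genes, .acb11_drop))
  signature_set(name, genes)
}

#' Read / write a signature
#'
#' Two plain-text encodings are supported: JSON `{"name": ..., "genes":
#' [...]}` (when the path ends in `.json`) and one-symbol-per-line text
#' (any other extension; the name defaults to the file's base name).
#'
#' @param path file path.
#' @param sig a [signature_set()].
#' @return `read_signature` returns a [signature_set()]; `write_signature`
#'   returns `path` invisibly.
#' @export
read_signature <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$name) || is.null(obj$genes))
      stop("signature JSON needs fields 'name' and 'genes'")
    return(signature_set(obj$name, obj$genes))
  }
  genes <- trimws(readLines(path))
  genes <- genes[nzchar(genes)]
  signature_set(sub("\\.[^.]*$", "", basename(path)), genes)
}

#' @rdname read_signature
#' @export
write_signature <- function(sig, path) {
  if (!inherits(sig, "signature_set")) stop("`sig` must be a signature_set")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(name = sig$name, genes = sig$genes), path,
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    writeLines(sig$genes, path)
  }
  invisible(path)
}

#' Read / write a sensitivity vector
#'
#' Two-column table (sample id, value) with a header; delimiter sniffed as
#' in [read_matrix()].
#'
#' @param path file path.
#' @param metric one of `"ec50"`, `"ln_ec50"`, `"auc"`.
#' @param s a [sensitivity_vector()].
#' @return `read_sensitivity` returns a [sensitivity_vector()].
#' @export
read_sensitivity <- function(path, metric = "ec50") {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE)
  if (ncol(df) < 2L) stop("expected two columns: sample id, value")
  v <- as.numeric(df[[2L]])
  names(v) <- as.character(df[[1L]])
  sensitivity_vector(v, metric = metric)
}

#' @rdname read_sensitivity
#' @export
write_sensitivity <- function(s, path) {
  df <- data.frame(sample_id = names(s), value = as.numeric(s))
  colnames(df)[2] <- attr(s, "metric")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
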