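#' Configuration for the synthetic panel generator
#'
#' Bundles and validates every knob of the synthetic multi-omics panel.
#' Defaults emulate the study design the package targets: a panel of 31
#' cell lines by 2,000 genes containing a planted block of 15 co-regulated
#' signature genes whose mean expression correlates with ln(EC50) at
#' r = 0.86, and a compound library of 543 compounds of which 125 are
#' chemically reactive.
#'
#' @param n_samples number of samples (cell lines); at least 4.
#' @param n_genes number of genes; must exceed `n_signature`.
#' @param n_signature size of the planted co-regulated block.
#' @param target_r population correlation between the planted-block mean
#'   expression (signature score) and ln(EC50), in \[-1, 1\]. Positive by
#'   default: low signature expression goes with low EC50 (sensitive).
#' @param within_block_r pairwise population correlation of planted genes,
#'   in \[0, 1\].
#' @param proteomics_noise_sd SD of the per-entry Gaussian noise added to
#'   expression to derive the proteomics layer.
#' @param n_compounds compound-library size.
#' @param frac_reactive fraction of library compounds flagged reactive.
#' @param seed master integer seed; per-component streams are derived from
#'   it by fixed offsets.
#' @return Object of class `synthetic_config` (a validated list).
#' @examples
#' synthetic_config(n_samples = 31, seed = 1)
#' @export
synthetic_config <- function(n_samples = 31L, n_genes = 2000L,
                             n_signature = 15L, target_r = 0.86,
                             within_block_r = 0.6,
                             proteomics_noise_sd = 0.5,
                             n_compounds = 543L, frac_reactive = 125 / 543,
                             seed = 1L) {
  n_samples <- as.integer(n_samples); n_genes <- as.integer(n_genes)
  n_signature <- as.integer(n_signature); n_compounds <- as.integer(n_compounds)
  if (n_samples < 4L)
    stop("n_samples must be >= 4 (correlation p-values are degenerate below)")
  if (n_signature >= n_genes) stop("n_signature must be < n_genes")
  if (n_signature < 2L) stop("n_signature must be >= 2")
  if (abs(target_r) > 1) stop("|target_r| must be <= 1")
  if (within_block_r < 0 || within_block_r > 1)
    stop("within_block_r must be in [0, 1]")
  if (proteomics_noise_sd < 0) stop("proteomics_noise_sd must be >= 0")
  if (frac_reactive < 0 || frac_reactive > 1)
    stop("frac_reactive must be in [0, 1]")
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 n_signature = n_signature, target_r = target_r,
                 within_block_r = within_block_r,
                 proteomics_noise_sd = proteomics_noise_sd,
                 n_compounds = n_compounds, frac_reactive = frac_reactive,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# maximal achievable |corr(score, lnEC50)| for a given block structure:
# the block mean can never be better correlated with the latent factor than
# sqrt(w k / (w k + 1 - w)) where w = within_block_r, k = block size
block_score_factor_r <- function(within_block_r, k) {
  if (within_block_r == 0) return(0)
  sqrt(within_block_r * k / (within_block_r * k + 1 - within_block_r))
}

#' Generate a synthetic multi-omics panel with a planted signature
#'
#' Builds a samples-by-genes log2(TPM+1) expression matrix in which
#' `n_signature` planted genes load on one shared latent Gaussian factor
#' (pairwise correlation `within_block_r`), a proteomics layer equal to
#' expression plus independent Gaussian noise, and an EC50 vector whose
#' natural log shares the latent factor, calibrated analytically so that
#' the population correlation between the planted-block mean and ln(EC50)
#' equals `target_r`. Background genes are independent Gaussian noise
#' (SD 1) on the log2(TPM+1) scale. Expression is floored at 0 after
#' noise; means (6 for planted, 5 for background genes) keep the floor
#' from binding in practice.
#'
#' @param config a [synthetic_config()].
#' @return A `panel_bundle`: list with `expression` and `proteomics`
#'   ([expression_matrix()]s with identical, identically ordered sample
#'   ids), `sensitivity` (EC50 [sensitivity_vector()], strictly positive),
#'   `truth` (planted gene ids) and `config`.
#' @examples
#' b <- generate_panel(synthetic_config(n_samples = 31, seed = 1))
#' cor(score_samples(b$expression, signature_set("truth", b$truth)),
#'     log(as.numeric(b$sensitivity)))
#' @export
generate_panel <- function(config) {
  if (!inherits(config, "synthetic_config"))
    stop("`config` must be a synthetic_config")
  n <- config$n_samples; p <- config$n_genes; k <- config$n_signature
  w <- config$within_block_r; rt <- config$target_r
  rho_max <- block_score_factor_r(w, k)
  if (rt != 0 && abs(rt) > rho_max + 1e-12)
    stop(sprintf(paste0("target_r = %.3f is unattainable: with ",
                        "within_block_r = %.2f and %d planted genes the ",
                        "block mean cannot correlate with ln(EC50) beyond ",
                        "%.3f in absolute value"), rt, w, k, rho_max))
  set.seed(config$seed + 1L)

  sids <- sprintf("S%03d", seq_len(n))
  gids <- sprintf("g%05d", seq_len(p))
  truth <- sort(sample(gids, k))

  z <- stats::rnorm(n)                       # shared latent factor
  expr <- matrix(stats::rnorm(n * p, mean = 5, sd = 1), n, p,
                 dimnames = list(sids, gids))
  eps <- matrix(stats::rnorm(n * k), n, k)
  block <- sqrt(w) * z + sqrt(1 - w) * eps   # unit-variance planted genes
  expr[, truth] <- 6 + block
  expr[expr < 0] <- 0

  # ln(EC50) = alpha * z + sqrt(1-alpha^2) * u, alpha chosen so that
  # corr(block mean, lnEC50) = target_r in the population
  alpha <- if (rt == 0) 0 else rt / rho_max
  u <- stats::rnorm(n)
  ln_ec50 <- alpha * z + sqrt(max(0, 1 - alpha^2)) * u
  ec50 <- exp(ln_ec50)                       # geometric mean 1 uM
  names(ec50) <- sids

  prot <- expr + matrix(stats::rnorm(n * p, sd = config$proteomics_noise_sd),
                        n, p)

  structure(list(
    expression = expression_matrix(expr, layer = "expression",
                                   units = "log2tpm1"),
    proteomics = expression_matrix(prot, layer = "proteomics",
                                   units = "normalized_protein"),
    sensitivity = sensitivity_vector(ec50, metric = "ec50"),
    truth = truth,
    config = config
  ), class = "panel_bundle")
}

#' @export
print.panel_bundle <- function(x, ...) {
  cat(sprintf(paste0("<panel_bundle> %d samples x %d genes, %d planted ",
                     "signature genes, target r = %.2f\n"),
              nrow(x$expression), ncol(x$expression), length(x$truth),
              x$config$target_r))
  invisible(x)
}

#' Four-parameter logistic (4PL) dose-response curve
#'
#' Evaluates `bottom + (top - bottom) / (1 + 10^(hill * (log10(c) -
#' log10(ec50))))`, the "log(inhibitor) versus response, variable slope"
#' model. At `c = ec50` the value is the midpoint `(top + bottom) / 2`;
#' for `hill > 0` viability decreases with concentration towards `bottom`.
#'
#' @param conc concentration(s), strictly positive (same units as `ec50`).
#' @param ec50 half-maximal concentration (> 0).
#' @param hill Hill slope.
#' @param top,bottom upper/lower asymptotes (viability %).
#' @return Numeric vector of responses.
#' @examples
#' fourpl(10, ec50 = 1, hill = 1, top = 100, bottom = 0)  # 100/11
#' @export
fourpl <- function(conc, ec50, hill, top, bottom) {
  bottom + (top - bottom) / (1 + 10^(hill * (log10(conc) - log10(ec50))))
}

#' Simulate a dose-response viability curve
#'
#' Generates replicate viability readings from the 4PL model plus Gaussian
#' noise, as produced by a viability screen.
#'
#' @param ec50 true half-maximal concentration in micromolar (> 0).
#' @param hill true Hill slope.
#' @param top,bottom true asymptotes (viability %).
#' @param concentrations tested concentrations in micromolar (all > 0).
#' @param noise_sd SD of additive Gaussian noise on the viability scale.
#' @param replicates replicates per concentration.
#' @param seed integer seed (`NULL` leaves the RNG state alone).
#' @return A `dose_response_curve`: data.frame with columns
#'   `concentration`, `replicate`, `viability`.
#' @examples
#' generate_dose_response(1, 1, 100, 0, 10^seq(-3, 2), noise_sd = 0)
#' @export
generate_dose_response <- function(ec50, hill, top, bottom, concentrations,
                                   noise_sd = 0, replicates = 1L,
                                   seed = NULL) {
  stopifnot_scalar_num(ec50, "ec50", positive = TRUE)
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  df <- expand.grid(replicate = seq_len(replicates),
                    concentration = as.numeric(concentrations))
  df <- df[, c("concentration", "replicate")]
  mu <- fourpl(df$concentration, ec50, hill, top, bottom)
  df$viability <- mu + if (noise_sd > 0)
    stats::rnorm(nrow(df), sd = noise_sd) else 0
  rownames(df) <- NULL
  structure(df, class = c("dose_response_curve", "data.frame"))
}

#' Simulate a compound library in signature-correlation space
#'
#' Creates an AUC response matrix (samples x compounds) over the panel's
#' samples. A designated reference compound gets an AUC equal to a linear
#' rescaling of the panel's ln(EC50) (so lower AUC = more sensitive).
#' Reactive compounds get AUCs that are noisy increasing transforms of the
#' panel's signature score, so their signature-correlation vectors resemble
#' the reference's; inert compounds get independent noise.
#'
#' @param bundle a `panel_bundle` from [generate_panel()].
#' @param signature a [signature_set()] with genes present in
#'   `bundle$expression` (typically built from `bundle$truth`).
#' @param config a [synthetic_config()] supplying `n_compounds`,
#'   `frac_reactive` and the seed stream.
#' @param auc_noise_sd SD of the noise mixed into reactive compounds'
#'   latent response, relative to the unit-variance signature signal
#'   (default 1: signal and noise contribute equally).
#' @return A `compound_library`: list with `responses` (samples x
#'   compounds AUC matrix including the reference column), `reactive`
#'   (named logical; the reference is flagged reactive but is excluded
#'   from rankings and enrichment totals downstream), `reference_id`.
#' @export
generate_compound_library <- function(bundle, signature, config,
                                      auc_noise_sd = 1) {
  if (!inherits(bundle, "panel_bundle")) stop("`bundle` must be a panel_bundle")
  if (auc_noise_sd < 0) stop("auc_noise_sd must be >= 0")
  n_cmp <- config$n_compounds
  n_reactive <- floor(n_cmp * config$frac_reactive + 1e-9)
  if (config$frac_reactive > 0 && n_cmp * config$frac_reactive < 1) {
    warning("n_compounds * frac_reactive < 1; emitting zero reactive compounds")
    n_reactive <- 0L
  }
  set.seed(config$seed + 2L)
  n <- nrow(bundle$expression)
  sids <- rownames(bundle$expression)

  score <- score_samples(bundle$expression, signature)
  s_std <- as.numeric(scale(score))
  ln_ec50 <- log(as.numeric(bundle$sensitivity))

  ids <- sprintf("CMP%04d", seq_len(n_cmp))
  reactive <- stats::setNames(rep(FALSE, n_cmp), ids)
  if (n_reactive > 0) reactive[sample(ids, n_reactive)] <- TRUE

  resp <- matrix(NA_real_, n, n_cmp, dimnames = list(sids, ids))
  for (id in ids) {
    latent <- if (reactive[[id]])
      s_std + stats::rnorm(n, sd = auc_noise_sd)
    else
      stats::rnorm(n)
    resp[, id] <- 8 + 2 * as.numeric(scale(latent))  # CTRP-like AUC scale
  }

  ref_id <- "reference"
  ref_auc <- 8 + 2 * as.numeric(scale(ln_ec50))
  responses <- cbind(resp, matrix(ref_auc, n, 1,
                                  dimnames = list(sids, ref_id)))
  reactive <- c(reactive, stats::setNames(TRUE, ref_id))

  structure(list(responses = responses, reactive = reactive,
                 reference_id = ref_id),
            class = "compound_library")
}

#' @export
print.compound_library <- function(x, ...) {
  n <- ncol(x$responses) - 1L
  cat(sprintf("<compound_library> %d compounds (+ reference '%s'), %d reactive, %d samples\n",
              n, x$reference_id,
              sum(x$reactive[names(x$reactive) != x$reference_id]),
              nrow(x$responses)))
  invisible(x)
}

#' Generate nuclei counts with a known growth-rate (GR) value
#'
#' Inverts the normalized growth-rate formula
#' `GR = 2^(log2(x_c/x0) / log2(x_ctrl/x0)) - 1` analytically, so that
#' [compute_gr()] on the returned counts recovers `gr_true` exactly when
#' noise is off: `x_ctrl = x0 * fold_ctrl` and
#' `x_c = x0 * 2^(log2(gr_true + 1) * log2(fold_ctrl))`.
#'
#' @param gr_true target GR value; must exceed -1, otherwise the treated
#'   count would be non-positive.
#' @param x0 nuclei count at treatment time (> 0).
#' @param fold_ctrl fold-growth of the untreated control (> 1).
#' @param seed integer seed, used only when `poisson_noise = TRUE`.
#' @param poisson_noise if `TRUE`, replace the exact counts by Poisson
#'   draws with those means.
#' @return A `gr_input`: list with `x_c`, `x_ctrl`, `x0`.
#' @examples
#' g <- generate_growth_counts(sqrt(2) - 1, x0 = 1000, fold_ctrl = 4)
#' g$x_c  # 2000
#' @export
generate_growth_counts <- function(gr_true, x0, fold_ctrl, seed = NULL,
                                   poisson_noise = FALSE) {
  stopifnot_scalar_num(x0, "x0", positive = TRUE)
  if (fold_ctrl <= 1) stop("fold_ctrl must be > 1 (control must grow)")
  if (gr_true <= -1)
    stop("gr_true <= -1 implies a non-positive treated count")
  x_ctrl <- x0 * fold_ctrl
  x_c <- x0 * 2^(log2(gr_true + 1) * log2(fold_ctrl))
  if (poisson_noise) {
    if (!is.null(seed)) set.seed(seed)
    x_c <- stats::rpois(1L, x_c)
    x_ctrl <- stats::rpois(1L, x_ctrl)
    x0 <- stats::rpois(1L, x0)
    if (min(x_c, x_ctrl, x0) <= 0 || x_ctrl <= x0)
      stop("Poisson noise produced degenerate counts; increase x0")
  }
  structure(list(x_c = x_c, x_ctrl = x_ctrl, x0 = x0), class = "gr_input")
}
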