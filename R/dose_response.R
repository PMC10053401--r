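#' Fit a four-parameter logistic dose-response model
#'
#' Least-squares fit of the "log(inhibitor) versus response, variable
#' slope" model `v = bottom + (top - bottom) / (1 + 10^(hill * (log10(c) -
#' log10(ec50))))` to replicate viability data, via bounded
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]). Initialization: `top` and
#' `bottom` from the max/min of per-concentration mean viability, `ec50`
#' from the concentration whose mean viability is nearest the half-range,
#' `hill = 1`. EC50 is bounded within `[min(c)/100, max(c)*100]` and
#' reported in the original concentration units; `top >= bottom` is
#' enforced by fitting the span `top - bottom >= 0`.
#'
#' @param curve a `dose_response_curve` (see [generate_dose_response()]) or
#'   any data.frame with numeric columns `concentration` and `viability`;
#'   at least 4 distinct concentrations, all > 0.
#' @param hill_bounds length-2 bounds on the Hill slope.
#' @param flat_tol if the range of per-concentration mean viability is
#'   below this, the data carry no dose response and fitting aborts.
#' @return An object of class `fit4pl` with fields `ec50`, `hill`, `top`,
#'   `bottom`, `rss`, `converged`, plus `fitted`, `data` and `n`. If the
#'   optimizer stops without convergence the best-found parameters are
#'   returned with `converged = FALSE`.
#' @examples
#' cur <- generate_dose_response(1, 1, 100, 0, 10^seq(-3, 2, length.out = 8))
#' coef(fit_4pl(cur))
#' @export
fit_4pl <- function(curve, hill_bounds = c(-10, 10), flat_tol = 1e-6) {
  df <- as.data.frame(curve)
  if (!all(c("concentration", "viability") %in% colnames(df)))
    stop("`curve` needs columns 'concentration' and 'viability'")
  df <- df[is.finite(df$concentration) & is.finite(df$viability), ,
           drop = FALSE]
  if (any(df$concentration <= 0)) stop("concentrations must be > 0")
  conc <- df$concentration; v <- df$viability
  uc <- sort(unique(conc))
  if (length(uc) < 4L)
    stop("need at least 4 distinct concentrations, got ", length(uc))
  mean_v <- vapply(uc, function(cc) mean(v[conc == cc]), numeric(1))
  if (diff(range(mean_v)) < flat_tol)
    stop("no dose response: viability range below tolerance (",
         format(flat_tol), ")")

  top0 <- max(mean_v); bot0 <- min(mean_v)
  mid <- (top0 + bot0) / 2
  lec0 <- log10(uc[which.min(abs(mean_v - mid))])
  lec_lo <- log10(min(uc)) - 2; lec_hi <- log10(max(uc)) + 2
  span <- top0 - bot0
  lower <- c(bottom = bot0 - span, span = 0, lec = lec_lo,
             hill = hill_bounds[1])
  upper <- c(bottom = top0 + span, span = 3 * span, lec = lec_hi,
             hill = hill_bounds[2])
  start <- c(bottom = bot0, span = span, lec = lec0, hill = 1)

  lconc <- log10(conc)
  model <- function(p) p[["bottom"]] +
    p[["span"]] / (1 + 10^(p[["hill"]] * (lconc - p[["lec"]])))

  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ bottom + span / (1 + 10^(hill * (lconc - lec))),
      start = as.list(start), lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  if (!is.null(fit)) {
    p <- stats::coef(fit)
    converged <- isTRUE(fit$convInfo$isConv)
  } else {
    # fall back to bounded quasi-Newton from the same start
    obj <- function(q) sum((v - model(stats::setNames(q, names(start))))^2)
    op <- stats::optim(start, obj, method = "L-BFGS-B",
                       lower = lower, upper = upper)
    p <- stats::setNames(op$par, names(start))
    converged <- op$convergence == 0L
  }
  fitted <- model(p)
  structure(list(ec50 = unname(10^p[["lec"]]), hill = unname(p[["hill"]]),
                 top = unname(p[["bottom"]] + p[["span"]]),
                 bottom = unname(p[["bottom"]]),
                 rss = sum((v - fitted)^2), converged = converged,
                 fitted = fitted,
                 data = data.frame(concentration = conc, viability = v),
                 n = length(v)),
            class = "fit4pl")
}

#' @export
print.fit4pl <- function(x, ...) {
  cat("Four-parameter logistic dose-response fit\n")
  cat(sprintf("  EC50: %.6g   Hill: %.4g   top: %.4g   bottom: %.4g\n",
              x$ec50, x$hill, x$top, x$bottom))
  cat(sprintf("  RSS: %.6g on %d points%s\n", x$rss, x$n,
              if (x$converged) "" else "  [did not converge]"))
  invisible(x)
}

#' @export
coef.fit4pl <- function(object, ...) {
  c(ec50 = object$ec50, hill = object$hill, top = object$top,
    bottom = object$bottom)
}

#' @export
summary.fit4pl <- function(object, ...) {
  res <- stats::residuals(object)
  cat("Four-parameter logistic dose-response fit\n")
  cat(sprintf("  %d points over %d concentrations [%.4g, %.4g]\n",
              object$n, length(unique(object$data$concentration)),
              min(object$data$concentration),
              max(object$data$concentration)))
  print(coef(object))
  cat(sprintf("  residual SD: %.4g   RSS: %.6g   converged: %s\n",
              stats::sd(res), object$rss, object$converged))
  invisible(object)
}

#' @export
predict.fit4pl <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$concentration
          else if (is.numeric(newdata)) newdata
          else newdata$concentration
  fourpl(conc, object$ec50, object$hill, object$top, object$bottom)
}

#' @export
residuals.fit4pl <- function(object, ...) {
  object$data$viability - object$fitted
}

#' @export
plot.fit4pl <- function(x, ...) {
  d <- x$data
  grid <- 10^seq(log10(min(d$concentration)), log10(max(d$concentration)),
                 length.out = 200)
  plot(d$concentration, d$viability, log = "x",
       xlab = "concentration", ylab = "viability (%)", ...)
  graphics::lines(grid, predict(x, grid))
  graphics::abline(v = x$ec50, lty = 2)
  invisible(x)
}

#' Normalized growth rate (GR)
#'
#' Computes `GR = 2^(log2(x_c/x0) / log2(x_ctrl/x0)) - 1` from nuclei
#' counts: `x_c` treated, `x_ctrl` untreated control, `x0` at treatment
#' time. GR = 1 means uninhibited growth (`x_c = x_ctrl`), GR = 0 is
#' cytostasis (`x_c = x0`), GR < 0 indicates cell loss; GR is strictly
#' increasing in `x_c`.
#'
#' @param x_c treated nuclei count(s) (> 0), or a `gr_input` from
#'   [generate_growth_counts()] (in which case the other arguments are
#'   taken from it).
#' @param x_ctrl control nuclei count; must exceed `x0`.
#' @param x0 nuclei count at treatment time (> 0).
#' @return GR value(s), vectorized over `x_c`.
#' @examples
#' compute_gr(2000, x_ctrl = 4000, x0 = 1000)  # sqrt(2) - 1
#' @export
compute_gr <- function(x_c, x_ctrl = NULL, x0 = NULL) {
  if (inherits(x_c, "gr_input")) {
    g <- x_c; x_c <- g$x_c; x_ctrl <- g$x_ctrl; x0 <- g$x0
  }
  stopifnot_scalar_num(x_ctrl, "x_ctrl", positive = TRUE)
  stopifnot_scalar_num(x0, "x0", positive = TRUE)
  if (any(x_c <= 0)) stop("treated counts must be > 0")
  if (x_ctrl <= x0) stop("control did not grow (x_ctrl <= x0)")
  2^(log2(x_c / x0) / log2(x_ctrl / x0)) - 1
}

#' Degree of redox-probe oxidation (OxD)
#'
#' Normalizes a ratiometric roGFP2 readout (F400/F485) between the fully
#' reduced control (DTT-treated, OxD = 0) and the fully oxidized control
#' (diamide-treated, OxD = 1): `OxD = (r - r_red) / (r_ox - r_red)`,
#' clipped to \[0, 1\].
#'
#' @param r ratio value(s) per timepoint.
#' @param r_red fully-reduced (DTT) control ratio.
#' @param r_ox fully-oxidized (diamide) control ratio; must differ from
#'   `r_red`.
#' @return OxD value(s) in \[0, 1\].
#' @examples
#' compute_oxd(0.6, r_red = 0.2, r_ox = 1.0)  # 0.5
#' @export
compute_oxd <- function(r, r_red, r_ox) {
  stopifnot_scalar_num(r_red, "r_red")
  stopifnot_scalar_num(r_ox, "r_ox")
  if (r_ox == r_red) stop("r_ox must differ from r_red")
  pmin(1, pmax(0, (r - r_red) / (r_ox - r_red)))
}
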