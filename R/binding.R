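#' Fit a one-site saturation binding curve
#'
#' Least-squares fit of `S(L) = bmax * L / (kd + L)` — the
#' ligand-depletion-free hyperbola standard for pull-down and equilibrium
#' binding analysis. `kd` is initialized at the concentration nearest
#' half-maximal signal and `bmax` at the maximal observed signal, with
#' `kd` bounded in `(1e-4, 1e4)` uM. A fit that fails to converge or lands
#' on a bound is returned flagged, never as a silent success. A
#' depletion-aware quadratic variant is available for bead-bound assays
#' where free ligand is materially below total.
#'
#' @param concentrations ligand concentrations, uM (>= 3 distinct values).
#' @param signals observed signals (>= 0), same length.
#' @param normalize divide signals by the fitted `bmax` and refit, so the
#'   reported curve is fraction-of-maximal (`bmax` ~ 1); `kd` is unaffected
#'   by this rescaling.
#' @param model `"hyperbola"` (default) or `"quadratic"` (depletion-aware,
#'   requires `receptor_total`).
#' @param receptor_total total receptor concentration, uM (quadratic model).
#' @param weights `NULL` (unweighted, default) or `"1/S2"`.
#' @return A `binding_fit` list: `kd`, `bmax`, `kd_se`, `bmax_se`,
#'   `residual_sd`, `n_points`, `converged`, `flag` (`NA` or a reason),
#'   `concentrations`, `signals`.
#' @export
fit_one_site <- function(concentrations, signals, normalize = FALSE,
                         model = c("hyperbola", "quadratic"),
                         receptor_total = NULL, weights = NULL) {
  model <- match.arg(model)
  L <- as.numeric(concentrations); S <- as.numeric(signals)
  if (length(L) != length(S))
    stop("'concentrations' and 'signals' differ in length", call. = FALSE)
  if (length(unique(L)) < 3)
    stop("need at least 3 distinct concentrations", call. = FALSE)
  if (any(!is.finite(L)) || any(L < 0)) stop_field("concentrations",
                                                   "must be finite and >= 0")
  if (any(!is.finite(S)) || any(S < 0)) stop_field("signals",
                                                   "must be finite and >= 0")
  bmax0 <- max(S)
  kd0 <- L[which.min(abs(S - bmax0 / 2))]
  if (kd0 <= 0) kd0 <- stats::median(L[L > 0])
  w <- if (identical(weights, "1/S2")) 1 / pmax(S, 1e-12)^2
       else rep(1, length(S))
  lower <- c(kd = 1e-4, bmax = 1e-12)
  upper <- c(kd = 1e4, bmax = Inf)
  dat <- data.frame(L = L, S = S)
  form <- if (model == "hyperbola") {
    S ~ bmax * L / (kd + L)
  } else {
    if (is.null(receptor_total))
      stop("quadratic model requires 'receptor_total'", call. = FALSE)
    R <- receptor_total
    S ~ bmax * ((L + R + kd) - sqrt((L + R + kd)^2 - 4 * L * R)) / (2 * R)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat,
                      start = list(kd = kd0, bmax = bmax0),
                      lower = lower, upper = upper, weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(kd = NA_real_, bmax = NA_real_, kd_se = NA_real_,
                          bmax_se = NA_real_, residual_sd = NA_real_,
                          n_points = length(L), converged = FALSE,
                          flag = conditionMessage(fit),
                          concentrations = L, signals = S),
                     class = "binding_fit"))
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(kd = NA_real_, bmax = NA_real_))
  flag <- NA_character_
  if (est["kd"] <= lower["kd"] * 1.01 || est["kd"] >= upper["kd"] * 0.99)
    flag <- "kd at bound"
  out <- list(kd = unname(est["kd"]), bmax = unname(est["bmax"]),
              kd_se = unname(se["kd"]), bmax_se = unname(se["bmax"]),
              residual_sd = summary(fit)$sigma, n_points = length(L),
              converged = is.na(flag), flag = flag,
              concentrations = L, signals = S)
  class(out) <- "binding_fit"
  if (normalize && is.finite(out$bmax) && out$bmax > 0) {
    renorm <- fit_one_site(L, S / out$bmax, normalize = FALSE, model = model,
                           receptor_total = receptor_total, weights = weights)
    renorm$flag <- out$flag
    renorm$converged <- out$converged & renorm$converged
    return(renorm)
  }
  out
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit: kd = %.4g +/- %.2g uM, bmax = %.4g +/- %.2g, n = %d%s>\n",
              x$kd, x$kd_se, x$bmax, x$bmax_se, x$n_points,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Fit a microtubule co-sedimentation curve
#'
#' Fraction of motor sedimenting with increasing microtubule (tubulin dimer)
#' concentration: `f(M) = fmax * M / (kd + M)`. Same machinery as
#' [fit_one_site()]; fractions must lie in `[0, 1]`.
#'
#' @param mt_concentrations uM tubulin dimer.
#' @param fraction_sedimented proportions in `[0, 1]`.
#' @param ... passed to [fit_one_site()].
#' @return A `binding_fit` (its `bmax` is the saturating fraction `fmax`).
#' @export
fit_cosedimentation <- function(mt_concentrations, fraction_sedimented, ...) {
  f <- as.numeric(fraction_sedimented)
  if (any(!is.finite(f)) || any(f < 0 | f > 1))
    stop_field("fraction_sedimented", "must lie in [0, 1]")
  fit_one_site(mt_concentrations, f, ...)
}

#' Ratio of two fitted dissociation constants
#'
#' `kd_b / kd_a` with a first-order (delta-method) standard error, used to
#' express regulator-induced affinity shifts ("K_D increased n-fold").
#'
#' @param fit_a,fit_b converged `binding_fit` objects (a = reference).
#' @return List with `ratio`, `se`, `flag` (`NA`, or the reason when either
#'   input fit was flagged, in which case the ratio is propagated flagged).
#' @export
kd_shift_ratio <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "binding_fit"), inherits(fit_b, "binding_fit"))
  flag <- NA_character_
  if (!isTRUE(fit_a$converged) || !isTRUE(fit_b$converged))
    flag <- "input fit flagged"
  ratio <- fit_b$kd / fit_a$kd
  se <- if (is.finite(fit_a$kd_se) && is.finite(fit_b$kd_se))
    abs(ratio) * sqrt((fit_a$kd_se / fit_a$kd)^2 + (fit_b$kd_se / fit_b$kd)^2)
  else NA_real_
  list(ratio = ratio, se = se, flag = flag)
}
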