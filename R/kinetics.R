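# Steady-state enzyme kinetics: Michaelis-Menten and substrate-inhibition
# fits to initial-rate data, asymptotic standard errors, and the derived
# specificity constants (kcat/KM) and substrate-preference ratios.
#
# Rate laws (S and KM/KS in the same concentration unit, E0 molar):
#   MM:                   v = kcat * E0 * S / (KM + S)
#   substrate inhibition: v = kcat * E0 * S / (KM + S * (1 + S/KS))

mm_rate <- function(S, kcat, KM, E0) kcat * E0 * S / (KM + S)
si_rate <- function(S, kcat, KM, KS, E0)
  kcat * E0 * S / (KM + S * (1 + S / KS))

new_kinetic_fit <- function(model, est, se, E0, fit, data, rss,
                            converged) {
  structure(list(model = model, kcat = est[["kcat"]], KM = est[["KM"]],
                 KS = if ("KS" %in% names(est)) est[["KS"]] else NA_real_,
                 se = se, E0 = E0, fit = fit, data = data, rss = rss,
                 converged = converged),
            class = "kinetic_fit")
}

# Levenberg-Marquardt least squares with positivity bounds; asymptotic
# standard errors from a central-difference Jacobian at the optimum.
# A singular J'J (e.g. KS far beyond the sampled range) yields NA standard
# errors rather than a failure.
fit_rate_law <- function(data, E0, model) {
  predict_v <- function(p) {
    if (model == "MM") mm_rate(data$S, p[["kcat"]], p[["KM"]], E0)
    else si_rate(data$S, p[["kcat"]], p[["KM"]], p[["KS"]], E0)
  }
  st <- start_values(data, E0)
  starts <- if (model == "MM") {
    list(unlist(st))
  } else {
    # the substrate-inhibition surface can hold shallow local minima on
    # sparse designs; a small deterministic start grid guards against them
    smax <- max(data$S)
    unlist(recursive = FALSE, lapply(c(1, 2), function(kf)
      unlist(recursive = FALSE, lapply(c(0.2, 1, 5), function(mf)
        lapply(c(smax / 5, smax, 5 * smax), function(ks)
          c(kcat = kf * st$kcat, KM = mf * st$KM, KS = ks))))))
  }
  run_one <- function(p0) {
    minpack.lm::nls.lm(
      par = p0, lower = rep(1e-12, length(p0)),
      fn = function(p) data$v - predict_v(setNames(p, names(p0))),
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                           ptol = 1e-15))
  }
  fits <- lapply(starts, function(p0) tryCatch(run_one(p0),
                                               error = function(e) NULL))
  fits <- fits[!vapply(fits, is.null, logical(1))]
  ok <- vapply(fits, function(f) f$info %in% 1:4, logical(1))
  if (!any(ok)) {
    abort(sprintf("fit did not converge: %s", fits[[1]]$message))
  }
  fits <- fits[ok]
  out <- fits[[which.min(vapply(fits, function(f) sum(f$fvec^2),
                                numeric(1)))]]
  p0 <- starts[[1]]
  est <- setNames(out$par, names(p0))
  if (any(est <= 0)) abort("fit converged to a non-positive parameter")
  rss <- sum(out$fvec^2)
  # central-difference Jacobian of the model curve wrt the parameters
  J <- vapply(seq_along(est), function(k) {
    h <- max(1e-7 * abs(est[k]), 1e-12)
    up <- est; up[k] <- up[k] + h
    dn <- est; dn[k] <- dn[k] - h
    (predict_v(up) - predict_v(dn)) / (2 * h)
  }, numeric(nrow(data)))
  dof <- max(nrow(data) - length(est), 1)
  sigma2 <- rss / dof
  vc <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  se <- if (is.null(vc)) setNames(rep(NA_real_, length(est)), names(est))
  else setNames(sqrt(pmax(diag(vc), 0)), names(est))
  new_kinetic_fit(if (model == "MM") "MM" else "SUBSTRATE_INHIBITION",
                  est, se, E0, out, data, rss,
                  converged = TRUE)
}

check_kinetic_input <- function(data, E0) {
  data <- as_tibble(data)
  if (!all(c("S", "v") %in% names(data))) {
    abort("kinetic data needs columns S and v")
  }
  if (length(unique(data$S)) < 3) {
    abort("at least 3 distinct substrate concentrations are required")
  }
  stopifnot(E0 > 0)
  data
}

start_values <- function(data, E0) {
  vmax <- max(data$v)
  half <- data$S[which.min(abs(data$v - vmax / 2))]
  list(kcat = vmax / E0, KM = max(half, min(data$S[data$S > 0]) / 10))
}

#' Fit the Michaelis-Menten model to initial-rate data
#'
#' Nonlinear least squares for `v = kcat * E0 * S / (KM + S)` via
#' Levenberg-Marquardt with positivity bounds. Starting values are
#' `kcat0 = max(v)/E0` and `KM0 = S` at half-maximal velocity. Standard
#' errors are asymptotic (from the Jacobian at the optimum).
#'
#' @param data Data frame with columns `S` (substrate concentration,
#'   conventionally mM) and `v` (initial velocity).
#' @param E0 Total enzyme concentration (molar).
#' @return Object of class `kinetic_fit` with elements `kcat`, `KM`, `KS`
#'   (`NA` for this model), `se`, `E0`, `rss`, `converged` and the
#'   underlying `nls` fit. Non-convergence or a non-positive parameter at
#'   the optimum raises an error.
#' @seealso [fit_substrate_inhibition()], [specificity_constant()],
#'   [generate_kinetic_dataset()]
#' @export
fit_michaelis_menten <- function(data, E0) {
  data <- check_kinetic_input(data, E0)
  tryCatch(fit_rate_law(data, E0, "MM"),
           error = function(e) abort(paste("Michaelis-Menten fit failed:",
                                           conditionMessage(e))))
}

#' Fit the substrate-inhibition model to initial-rate data
#'
#' Nonlinear least squares for
#' `v = kcat * E0 * S / (KM + S * (1 + S/KS))`. `KS0` starts at `max(S)`;
#' a fitted `KS` above `100 * max(S)` triggers a warning that substrate
#' inhibition is not identifiable from the design (the curve is then
#' indistinguishable from Michaelis-Menten over the sampled range).
#'
#' @inheritParams fit_michaelis_menten
#' @return A `kinetic_fit` with `model = "SUBSTRATE_INHIBITION"` and a
#'   finite `KS` estimate.
#' @export
fit_substrate_inhibition <- function(data, E0) {
  data <- check_kinetic_input(data, E0)
  out <- tryCatch(fit_rate_law(data, E0, "SI"),
                  error = function(e)
                    abort(paste("substrate-inhibition fit failed:",
                                conditionMessage(e))))
  if (out$KS > 100 * max(data$S)) {
    warn(sprintf(
      "KS estimate (%.3g) exceeds 100 x max(S): substrate inhibition not identifiable",
      out$KS))
  }
  out
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("%s fit (E0 = %.3g M)\n",
              if (x$model == "MM") "Michaelis-Menten" else
                "Substrate-inhibition", x$E0))
  cat(sprintf("  kcat = %.4g +/- %.2g s^-1\n", x$kcat, x$se[["kcat"]]))
  cat(sprintf("  KM   = %.4g +/- %.2g\n", x$KM, x$se[["KM"]]))
  if (!is.na(x$KS)) {
    cat(sprintf("  KS   = %.4g +/- %.2g\n", x$KS, x$se[["KS"]]))
  }
  cat(sprintf("  RSS  = %.4g  (converged: %s)\n", x$rss, x$converged))
  invisible(x)
}

#' Tidiers for phosmine result objects
#'
#' [generics::tidy()] returns per-term (or per-row) detail;
#' [generics::glance()] returns a one-row summary.
#'
#' @param x A `kinetic_fit`, `ppm_inventory` or `distance_distribution`.
#' @param ... Unused.
#' @name tidiers
#' @rdname tidiers
#' @method tidy kinetic_fit
#' @export
tidy.kinetic_fit <- function(x, ...) {
  terms <- c("kcat", "KM", if (!is.na(x$KS)) "KS")
  tibble(term = terms,
         estimate = vapply(terms, function(t) x[[t]], numeric(1)),
         std.error = unname(x$se[terms]))
}

#' @rdname tidiers
#' @method glance kinetic_fit
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble(model = x$model, kcat = x$kcat, KM = x$KM, KS = x$KS,
         rss = x$rss, n = nrow(x$data), converged = x$converged,
         kcat_over_KM = specificity_constant(x$kcat, x$KM))
}

#' Specificity constant kcat/KM
#'
#' Second-order rate constant for the enzyme-substrate pair, in
#' M^-1 s^-1. `KM` given in mM (the conventional reporting unit) is
#' converted to molar before dividing.
#'
#' @param kcat Turnover number (s^-1).
#' @param KM Michaelis constant.
#' @param KM_unit Unit of `KM`: `"mM"` (default), `"M"`, or `"uM"`.
#' @return kcat/KM in M^-1 s^-1.
#' @examples
#' specificity_constant(3.7, 0.012) # ~3.1e5 M^-1 s^-1
#' @export
specificity_constant <- function(kcat, KM, KM_unit = c("mM", "M", "uM")) {
  KM_unit <- match.arg(KM_unit)
  stopifnot(all(kcat > 0), all(KM > 0))
  KM_molar <- KM * switch(KM_unit, mM = 1e-3, M = 1, uM = 1e-6)
  kcat / KM_molar
}

#' Substrate-preference ratio of two specificity constants
#'
#' Ratio of two specificity constants, rounded half away from zero to
#' `sig_figs` significant figures — the form in which fold-preferences for
#' one substrate over another are conventionally reported.
#'
#' @param sc_numerator,sc_denominator Specificity constants (same units).
#' @param sig_figs Significant figures for reporting (default 2).
#' @return The rounded ratio.
#' @examples
#' specificity_ratio(4.5e5, 2.3e3) # ~200-fold
#' @export
specificity_ratio <- function(sc_numerator, sc_denominator, sig_figs = 2) {
  stopifnot(sc_numerator > 0, sc_denominator > 0)
  signif_half_away(sc_numerator / sc_denominator, sig_figs)
}
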