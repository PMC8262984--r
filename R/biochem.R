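# Quantitative models: Hill dose-response for HOCl oxidation of the CZB
# cysteine, quadratic two-state tight binding for chelator titrations
# (valid when the responsive pool is comparable to K_D, so the hyperbolic
# approximation fails), linear zinc inhibition of diguanylate-cyclase
# activity, crystal-violet relative-biofilm normalization, and paired t
# comparisons.  All fits minimize unweighted squared residuals.

#' Hill dose-response curve
#'
#' `A * L^n / (K_half^n + L^n)`; with n = 2 and L = K_half the response
#' is exactly A/2.
#'
#' @param L ligand concentration(s), >= 0.
#' @param K_half half-maximal concentration, > 0.
#' @param n Hill coefficient (default 2).
#' @param A maximal response (default 1).
#' @return numeric response(s).
#' @export
hill_response <- function(L, K_half, n = 2, A = 1) {
  stopifnot(K_half > 0, all(L >= 0))
  A * L^n / (K_half^n + L^n)
}

#' Fit the Hill model with fixed Hill coefficient
#'
#' Least squares over `K_half` and `A` with `n` held fixed.  `A` is
#' profiled out analytically for each trial `K_half`, and `K_half` is
#' optimized on the log scale from a multistart grid at every observed
#' dose.  Doses above `max_dose` are excluded: beyond ~500 uM HOCl the
#' sulfenic-acid signal decays by overoxidation, so only the monotone
#' rising limb is informative for the Hill model.
#'
#' @param dataset a [dose_response()] dataset.
#' @param n_fixed fixed Hill coefficient (default 2).
#' @param max_dose dose cutoff (same units as `dose`; default 500).
#' @return list of class `"hill_fit"`: K_half, n, A, residual_ss,
#'   converged, n_points.
#' @export
fit_hill <- function(dataset, n_fixed = 2, max_dose = 500) {
  d <- dataset[dataset$dose <= max_dose, , drop = FALSE]
  if (length(unique(d$dose)) < 3L) stop("need >= 3 distinct doses <= max_dose")
  if (any(d$response < 0)) stop("responses must be nonnegative")
  L <- d$dose; y <- d$response
  ss_of <- function(logK) {
    f <- hill_response(L, exp(logK), n = n_fixed, A = 1)
    s2 <- sum(f^2)
    A <- if (s2 > 0) max(sum(y * f) / s2, 0) else 0
    sum((y - A * f)^2)
  }
  starts <- log(unique(L[L > 0]))
  if (length(starts) == 0L) stop("all doses zero")
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, ss_of, method = "Brent",
                      lower = s - log(1e4), upper = s + log(1e4),
                      control = list(reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best) || !is.finite(best$value)) {
    stop("Hill fit failed to converge from any start")
  }
  K <- exp(best$par)
  f <- hill_response(L, K, n = n_fixed, A = 1)
  A <- sum(y * f) / sum(f^2)
  structure(list(K_half = K, n = n_fixed, A = A,
                 residual_ss = best$value,
                 converged = best$convergence == 0L,
                 n_points = length(y)),
            class = "hill_fit")
}

#' Quadratic two-state (tight-binding) response
#'
#' The bound-state signal increment solves
#' `dy^2 - (dy_max + L0 + K_D) dy + dy_max * L0 = 0` (the equilibrium
#' with ligand depletion), taking the physical (smaller) root:
#' `dy = 0.5 * ((dy_max + L0 + K_D) - sqrt((dy_max + L0 + K_D)^2 -
#' 4 * dy_max * L0))` with `dy_max = y_max - y_min`, evaluated in the
#' cancellation-free equivalent form.  The response is `y = y_min + dy`,
#' strictly increasing in `L0` and bounded by `[y_min, y_max]`.
#'
#' @param L0 total ligand concentration(s), >= 0.
#' @param K_D equilibrium dissociation constant, > 0.
#' @param y_min,y_max signal bounds, `y_max >= y_min`.
#' @return numeric response(s).
#' @export
tight_binding_y <- function(L0, K_D, y_min, y_max) {
  stopifnot(all(L0 >= 0), K_D > 0, y_max >= y_min)
  dmax <- y_max - y_min
  S <- dmax + L0 + K_D
  disc <- S^2 - 4 * dmax * L0
  if (any(disc < -1e-8 * S^2)) {
    stop("negative discriminant: numerically invalid inputs")
  }
  disc <- pmax(disc, 0)
  # 0.5*(S - sqrt(disc)) rewritten to avoid catastrophic cancellation
  dy <- ifelse(S + sqrt(disc) > 0, 2 * dmax * L0 / (S + sqrt(disc)), 0)
  y_min + dy
}

#' Fit the quadratic two-state model
#'
#' Least squares over `y_min`, `y_max` and `K_D`, multistarted with
#' `K_D` at every positive observed dose.  Also reports the half-maximal
#' ligand concentration `L_half = K_D + (y_max - y_min)/2`, the closed
#' form at which `dy = dy_max/2`, used for cross-protein potency ratios.
#'
#' @param dataset a [dose_response()] dataset.
#' @return list of class `"two_state_fit"`: y_min, y_max, K_D,
#'   half_max_L, residual_ss, converged.
#' @export
fit_two_state <- function(dataset) {
  if (length(unique(dataset$dose)) < 4L) stop("need >= 4 distinct doses")
  L <- dataset$dose; y <- dataset$response
  obj <- function(p) {
    ymin <- p[1]; dmax <- exp(p[2]); K <- exp(p[3])
    sum((y - tight_binding_y(L, K, ymin, ymin + dmax))^2)
  }
  rng <- max(y) - min(y)
  if (rng <= 0) rng <- max(abs(y), 1)
  starts <- unique(L[L > 0])
  best <- NULL
  for (K0 in starts) {
    p0 <- c(min(y), log(rng), log(K0))
    o <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best) || !is.finite(best$value)) {
    stop("two-state fit failed to converge from any start")
  }
  ymin <- best$par[1]; dmax <- exp(best$par[2]); K <- exp(best$par[3])
  structure(list(y_min = ymin, y_max = ymin + dmax, K_D = K,
                 half_max_L = K + dmax / 2,
                 residual_ss = best$value,
                 converged = best$convergence == 0L),
            class = "two_state_fit")
}

#' Fit a linear inhibition model
#'
#' Ordinary least squares of activity on inhibitor concentration.  For an
#' inhibitor (negative slope) the zero-activity intercept
#' `x_zero = -intercept/slope` is reported, and points whose fitted value
#' falls below zero are dropped once and the line refit (activity cannot
#' be negative; the linear regime ends at depletion).
#'
#' @param dataset a [dose_response()] dataset (dose = inhibitor
#'   concentration, response = activity).
#' @return list of class `"linear_inhibition_fit"`: intercept, slope,
#'   x_zero (NA with a warning when the slope is not negative),
#'   residual_ss, n_used.
#' @export
fit_linear_inhibition <- function(dataset) {
  if (length(unique(dataset$dose)) < 3L) stop("need >= 3 distinct doses")
  d <- data.frame(x = dataset$dose, y = dataset$response)
  fit <- stats::lm(y ~ x, data = d)
  co <- stats::coef(fit)
  if (!is.finite(co[2]) || co[2] >= 0) {
    if (!is.finite(co[2]) || co[2] > 0) {
      warning("non-negative slope: not an inhibitor; x_zero undefined")
    } else {
      warning("zero slope (constant data); x_zero undefined")
    }
    return(structure(list(intercept = unname(co[1]),
                          slope = unname(ifelse(is.finite(co[2]), co[2], 0)),
                          x_zero = NA_real_,
                          residual_ss = sum(stats::residuals(fit)^2),
                          n_used = nrow(d)),
                     class = "linear_inhibition_fit"))
  }
  keep <- stats::fitted(fit) >= 0
  if (!all(keep) && sum(keep) >= 3L) {
    fit <- stats::lm(y ~ x, data = d[keep, , drop = FALSE])
    co <- stats::coef(fit)
  }
  structure(list(intercept = unname(co[1]), slope = unname(co[2]),
                 x_zero = unname(-co[1] / co[2]),
                 residual_ss = sum(stats::residuals(fit)^2),
                 n_used = length(stats::residuals(fit))),
            class = "linear_inhibition_fit")
}

#' Relative biofilm normalization
#'
#' Each A562 reading is divided by the mean untreated wild-type A562 of
#' the same experiment, so untreated wild-type rows average exactly 1
#' within every experiment and ratios are invariant to per-experiment
#' scaling.
#'
#' @param table data.frame with columns `experiment`, `strain`,
#'   `treatment`, `a562` (one row per replicate measurement; a `dose`
#'   column, if present, is carried through).
#' @param ref_strain wild-type strain label (default "WT").
#' @param ref_treatment untreated label (default "untreated").
#' @return the input with a `relative_biofilm` column appended.
#' @export
relative_biofilm <- function(table, ref_strain = "WT",
                             ref_treatment = "untreated") {
  need <- c("experiment", "strain", "treatment", "a562")
  if (!all(need %in% names(table))) {
    stop("biofilm table must have columns ", paste(need, collapse = ", "))
  }
  out <- table
  out$relative_biofilm <- NA_real_
  for (ex in unique(table$experiment)) {
    in_ex <- table$experiment == ex
    ref <- in_ex & table$strain == ref_strain &
      table$treatment == ref_treatment
    if (!any(ref)) {
      stop("experiment '", ex, "' has no untreated ", ref_strain,
           " reference replicates")
    }
    out$relative_biofilm[in_ex] <- table$a562[in_ex] /
      mean(table$a562[ref])
  }
  out
}

#' Paired Student t test
#'
#' Two-sided paired t on the differences.  Zero-variance differences are
#' handled explicitly: all-zero differences give t = 0, p = 1; constant
#' nonzero differences give t = +/-Inf, p = 0.
#'
#' @param treated,control equal-length paired numeric vectors, n >= 2.
#' @return list: t, p, df, mean_difference.
#' @export
paired_t <- function(treated, control) {
  stopifnot(length(treated) == length(control), length(treated) >= 2L)
  d <- treated - control
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = 0, p = 1, df = length(d) - 1L, mean_difference = 0))
    }
    return(list(t = sign(mean(d)) * Inf, p = 0, df = length(d) - 1L,
                mean_difference = mean(d)))
  }
  tt <- stats::t.test(treated, control, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_difference = mean(d))
}
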