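# Two-component kernel-density mixture models: per event, densities for the
# normal (pre-event) and abnormal (post-event) distributions of adjusted
# volumes, yielding P(x|E) and P(x|not E) for the event-based model.

# Weighted quantile (type-4 style linear interpolation on the weighted ecdf).
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  stats::approx(cw, x, xout = probs, rule = 2, ties = "ordered")$y
}

# Silverman's rule bandwidth from responsibility-weighted data. A component
# whose members are all tied (possible under bootstrap resampling) falls
# back to `fallback` (the pooled-data bandwidth) rather than collapsing.
weighted_bandwidth <- function(x, w, fallback = NULL) {
  sw <- sum(w)
  mu <- sum(w * x) / sw
  sd_w <- sqrt(sum(w * (x - mu)^2) / sw)
  n_eff <- sw^2 / sum(w^2)
  iqr_w <- diff(weighted_quantile(x, w, c(0.25, 0.75)))
  spread <- min(sd_w, iqr_w / 1.34)
  if (!is.finite(spread) || spread <= 0) spread <- sd_w
  if (!is.finite(spread) || spread <= 0) {
    if (!is.null(fallback)) return(fallback)
    stop("degenerate bandwidth: component has zero spread")
  }
  0.9 * spread * n_eff^(-1 / 5)
}

# Evaluate a weighted Gaussian-kernel density at points `at`.
kde_eval <- function(locs, w, h, at) {
  d <- stats::dnorm(outer(at, locs, "-"), sd = h)
  drop(d %*% (w / sum(w)))
}

# Component density: weighted KDE with a small uniform background over the
# padded support, so one extreme value cannot acquire overwhelming
# certainty in either direction.
component_density <- function(comp, at, support, eta = 0.01) {
  lo <- support[1]; hi <- support[2]
  pad <- 0.15 * (hi - lo)
  u <- ifelse(at >= lo - pad & at <= hi + pad, 1 / (hi - lo + 2 * pad), 0)
  (1 - eta) * kde_eval(comp$locs, comp$w, comp$h, at) + eta * u
}

#' Fit a two-component KDE mixture to one biomarker
#'
#' Models the covariate-adjusted values of one event as a mixture of a
#' normal-appearing component and an abnormal (lower-volume) component, each
#' a Gaussian-kernel density estimate, with mixing fraction `theta` for the
#' abnormal component. Estimation is an alternating classification-EM
#' scheme: responsibilities are initialized from group labels (controls are
#' anchored in the normal component; cases split at a low control
#' percentile), then each iteration refits both component KDEs from the
#' responsibility-weighted data (Silverman's rule bandwidth per component),
#' recomputes case posteriors, and reassigns case responsibilities by the
#' posterior's maximum (hard assignment — soft weights allow the abnormal
#' component to leak slowly into the normal bulk and never settle), updating
#' `theta` until no assignment changes. The abnormal component is constrained
#' to lie below the normal component (atrophy direction) at every iteration.
#' Each component density carries a 1% uniform background over the padded
#' observed support, so a single extreme value cannot acquire overwhelming
#' certainty in either direction.
#'
#' @param control_values,case_values Numeric vectors of adjusted volumes.
#' @param init_percentile Control percentile below which case values start in
#'   the abnormal component (default 0.10).
#' @param max_iter,tol Convergence controls: stop when the largest
#'   responsibility change falls below `tol` (default 1e-4; with hard
#'   assignments this means no case changed component) or after `max_iter`
#'   iterations (default 200).
#' @param theta_bounds Clamp for the abnormal mixing fraction
#'   (default `[0.01, 0.99]`).
#' @param min_n Minimum values required per group (default 10).
#' @return An object of class `kde_mixture`: component kernel locations,
#'   weights and bandwidths, `theta`, a monotone posterior curve on a
#'   512-point grid, `converged`, and `n_iter`.
#' @export
fit_kde_mixture <- function(control_values, case_values,
                            init_percentile = 0.10,
                            max_iter = 200, tol = 1e-4,
                            theta_bounds = c(0.01, 0.99),
                            min_n = 10) {
  ctrl <- as.numeric(control_values)
  case <- as.numeric(case_values)
  if (any(!is.finite(ctrl)) || any(!is.finite(case))) {
    stop("non-finite biomarker values")
  }
  if (length(ctrl) < min_n || length(case) < min_n) {
    stop("need at least ", min_n, " values per group")
  }
  x <- c(ctrl, case)
  n_ctrl <- length(ctrl)
  is_case <- c(rep(FALSE, n_ctrl), rep(TRUE, length(case)))
  if (stats::sd(x) == 0) stop("degenerate bandwidth: zero variance input")

  # abnormal-component responsibility; controls stay anchored at 0
  cut <- stats::quantile(ctrl, init_percentile, names = FALSE)
  r <- as.numeric(is_case & x < cut)
  # the abnormal component needs at least two kernels to have a bandwidth
  floor_abnormal <- function(r) {
    if (sum(r) < 2) {
      low <- order(ifelse(is_case, x, Inf))[1:2]
      r[low] <- 1
    }
    r
  }
  r <- floor_abnormal(r)

  clamp <- function(v) pmin(theta_bounds[2], pmax(theta_bounds[1], v))
  converged <- FALSE
  theta <- clamp(mean(r[is_case]))
  sup <- range(x)
  h_pooled <- weighted_bandwidth(x, rep(1, length(x)))
  h_n <- h_a <- NA_real_
  for (it in seq_len(max_iter)) {
    w_n <- 1 - r
    w_a <- r
    h_n <- weighted_bandwidth(x[w_n > 0], w_n[w_n > 0], fallback = h_pooled)
    h_a <- weighted_bandwidth(x[w_a > 0], w_a[w_a > 0], fallback = h_pooled)
    f_n <- component_density(list(locs = x[w_n > 0], w = w_n[w_n > 0],
                                  h = h_n), case, sup)
    f_a <- component_density(list(locs = x[w_a > 0], w = w_a[w_a > 0],
                                  h = h_a), case, sup)
    post <- theta * f_a / (theta * f_a + (1 - theta) * f_n)
    r_new <- r
    r_new[is_case] <- as.numeric(post > 0.5)
    r_new <- floor_abnormal(r_new)
    # direction constraint: abnormal component must sit below normal
    med_n <- stats::median(x[r_new == 0])
    med_a <- stats::median(x[is_case][r_new[is_case] == 1])
    if (is.finite(med_a) && med_a >= med_n) {
      r_new[is_case] <- 1 - r_new[is_case]
      r_new <- floor_abnormal(r_new)
    }
    delta <- max(abs(r_new - r))
    r <- r_new
    theta <- clamp(mean(r[is_case]))
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("KDE mixture did not converge within ", max_iter, " iterations",
            call. = FALSE)
  }
  w_n <- 1 - r
  w_a <- r
  fit <- structure(list(
    normal = list(locs = x[w_n > 0], w = w_n[w_n > 0] / sum(w_n), h = h_n),
    abnormal = list(locs = x[w_a > 0], w = w_a[w_a > 0] / sum(w_a), h = h_a),
    theta = theta, converged = converged, n_iter = it,
    support = range(x)
  ), class = "kde_mixture")
  fit$posterior_grid <- monotone_posterior_grid(fit)
  fit
}

# Posterior P(E|x) on a dense grid, made non-increasing in x by
# pooled-adjacent-violators (atrophy: lower volume means more abnormal).
monotone_posterior_grid <- function(fit, n_grid = 512) {
  # grid spans the observed support only: beyond it both components decay
  # to the uniform background and the raw posterior tends to theta, which
  # would otherwise leak into the PAV projection; values outside the
  # support get constant extrapolation instead
  grid <- seq(fit$support[1], fit$support[2], length.out = n_grid)
  f_n <- component_density(fit$normal, grid, fit$support)
  f_a <- component_density(fit$abnormal, grid, fit$support)
  post <- fit$theta * f_a / (fit$theta * f_a + (1 - fit$theta) * f_n)
  post[!is.finite(post)] <- 0.5
  iso <- -stats::isoreg(grid, -post)$yf   # non-increasing PAV fit
  list(x = grid, posterior = pmin(1, pmax(0, iso)))
}

#' Event likelihoods under a fitted KDE mixture
#'
#' Evaluates the abnormal and normal component densities at each value,
#' giving `P(x|E)` and `P(x|not E)`. Densities are floored at `floor_eps` so
#' a single outlier far outside the support cannot force an infinite
#' log-likelihood downstream.
#'
#' @param fit A `kde_mixture`.
#' @param values Numeric vector of adjusted volumes.
#' @param floor_eps Density floor (default 1e-10).
#' @return A list with numeric vectors `p_event` and `p_not_event`.
#' @export
event_likelihoods <- function(fit, values, floor_eps = 1e-10) {
  stopifnot(inherits(fit, "kde_mixture"))
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("non-finite values")
  p_e <- component_density(fit$abnormal, values, fit$support)
  p_n <- component_density(fit$normal, values, fit$support)
  list(p_event = pmax(p_e, floor_eps), p_not_event = pmax(p_n, floor_eps))
}

#' Monotone posterior probability of abnormality
#'
#' `P(E|x)` from the fitted mixture, read off the pooled-adjacent-violators
#' cleaned grid so the probability of the event never increases with volume.
#'
#' @param fit A `kde_mixture`.
#' @param values Numeric vector.
#' @return Posterior probabilities in `[0, 1]`.
#' @export
posterior_abnormal <- function(fit, values) {
  stopifnot(inherits(fit, "kde_mixture"))
  g <- fit$posterior_grid
  stats::approx(g$x, g$posterior, xout = values, rule = 2)$y
}

#' Mixture log-likelihood of a set of values
#'
#' Log-likelihood of `values` under the full two-component mixture
#' `theta * P(x|E) + (1 - theta) * P(x|not E)`; used for held-out model
#' comparison.
#'
#' @inheritParams event_likelihoods
#' @return Scalar log-likelihood.
#' @export
mixture_loglik <- function(fit, values, floor_eps = 1e-10) {
  lk <- event_likelihoods(fit, values, floor_eps)
  sum(log(fit$theta * lk$p_event + (1 - fit$theta) * lk$p_not_event))
}

#' Fit KDE mixtures for every event in adjusted case/control tables
#'
#' @param cases,controls Covariate-adjusted biomarker tables sharing the same
#'   event columns.
#' @param events Event columns to fit (default: all).
#' @param ... Passed to [fit_kde_mixture()].
#' @return Named list of `kde_mixture` fits.
#' @export
fit_all_mixtures <- function(cases, controls, events = NULL, ...) {
  events <- events %||% event_columns(cases)
  fits <- lapply(events, function(ev) {
    fit_kde_mixture(controls[[ev]], cases[[ev]], ...)
  })
  stats::setNames(fits, events)
}

# Two-component Gaussian mixture under the same labelling scheme; internal
# comparator for the KDE mixture on skewed data.
fit_gaussian_mixture <- function(control_values, case_values,
                                 init_percentile = 0.10,
                                 max_iter = 200, tol = 1e-4,
                                 theta_bounds = c(0.01, 0.99)) {
  ctrl <- as.numeric(control_values); case <- as.numeric(case_values)
  x <- c(ctrl, case)
  is_case <- c(rep(FALSE, length(ctrl)), rep(TRUE, length(case)))
  cut <- stats::quantile(ctrl, init_percentile, names = FALSE)
  r <- ifelse(is_case & x < cut, 1, 0)
  if (sum(r) < 2) r[is_case & rank(x, ties.method = "first") <= 2] <- 1
  clamp <- function(v) pmin(theta_bounds[2], pmax(theta_bounds[1], v))
  theta <- clamp(mean(r[is_case]))
  wmoments <- function(w) {
    sw <- sum(w); mu <- sum(w * x) / sw
    list(mu = mu, sd = max(sqrt(sum(w * (x - mu)^2) / sw), 1e-8))
  }
  for (it in seq_len(max_iter)) {
    mn <- wmoments(1 - r); ma <- wmoments(pmax(r, 1e-12))
    f_n <- stats::dnorm(case, mn$mu, mn$sd)
    f_a <- stats::dnorm(case, ma$mu, ma$sd)
    r_new <- r
    r_new[is_case] <- theta * f_a / (theta * f_a + (1 - theta) * f_n)
    if (ma$mu >= mn$mu) r_new[is_case] <- 1 - r_new[is_case]
    delta <- max(abs(r_new - r)); r <- r_new
    theta <- clamp(mean(r[is_case]))
    if (delta < tol) break
  }
  mn <- wmoments(1 - r); ma <- wmoments(pmax(r, 1e-12))
  list(normal = mn, abnormal = ma, theta = theta)
}

gaussian_mixture_loglik <- function(fit, values, floor_eps = 1e-10) {
  f_n <- pmax(stats::dnorm(values, fit$normal$mu, fit$normal$sd), floor_eps)
  f_a <- pmax(stats::dnorm(values, fit$abnormal$mu, fit$abnormal$sd), floor_eps)
  sum(log(fit$theta * f_a + (1 - fit$theta) * f_n))
}

#' Serialize KDE mixture fits to JSON
#'
#' @param fits Named list of `kde_mixture` objects.
#' @param path Output JSON path.
#' @export
write_mixture_fits <- function(fits, path) {
  payload <- lapply(fits, function(f) {
    list(theta = f$theta, converged = f$converged, n_iter = f$n_iter,
         normal = list(locs = f$normal$locs, w = f$normal$w, h = f$normal$h),
         abnormal = list(locs = f$abnormal$locs, w = f$abnormal$w,
                         h = f$abnormal$h))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
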