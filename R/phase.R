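new_density_profile <- function(z, density, se, box, n_frames,
                                temperature = NA_real_) {
  structure(tibble::tibble(z = z, density = density, se = se),
            class = c("density_profile", "tbl_df", "tbl", "data.frame"),
            box = box, n_frames = n_frames, temperature = temperature)
}

#' Slab density profile
#'
#' Bins the implicit-solvent protein mass density along z. Each frame is
#' recentred before averaging: the dense phase's periodic (circular) centre
#' of mass is shifted to the middle of the box, so interface drift does not
#' smear the profile. Densities are reported in g/cm^3 for the protein in a
#' massless implicit solvent.
#'
#' @param traj A `cg_trajectory` from a slab run.
#' @param n_bins Number of z bins (default 25).
#' @param table A [param_table()] (bead masses).
#' @param recentre Recentre the dense phase each frame (default `TRUE`).
#' @return A `density_profile` tibble: `z` (bin centres, A), `density`
#'   (g/cm^3) and `se` (standard error over frames).
#' @export
density_profile <- function(traj, n_bins = 25, table = default_param_table(),
                            recentre = TRUE) {
  box <- traj$box
  if (!(box[3] >= box[1]))
    stop("geometry error: density profiles need a slab box with L_z >= L_x")
  mass <- residue_params(table, paste(traj$topology$type, collapse = ""))$mass
  lz <- box[3]
  nf <- dim(traj$frames)[3]
  bin_vol <- box[1] * box[2] * lz / n_bins
  breaks <- seq(0, lz, length.out = n_bins + 1)
  prof <- matrix(0, n_bins, nf)
  for (f in seq_len(nf)) {
    z <- traj$frames[, 3, f] %% lz
    if (recentre) {
      theta <- z / lz * 2 * pi
      centre <- atan2(sum(mass * sin(theta)), sum(mass * cos(theta))) /
        (2 * pi) * lz
      z <- (z - centre + lz / 2) %% lz
    }
    idx <- pmin(pmax(findInterval(z, breaks, rightmost.closed = TRUE), 1L),
                n_bins)
    prof[, f] <- vapply(seq_len(n_bins), function(b)
      sum(mass[idx == b]), 0) * 1.66054 / bin_vol
  }
  new_density_profile(
    z = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
    density = rowMeans(prof),
    se = apply(prof, 1, sd) / sqrt(max(nf, 2)),
    box = box, n_frames = nf, temperature = traj$spec$temperature)
}

#' Coexisting densities from a slab profile
#'
#' Fits the recentred profile with two plateaus joined by symmetric
#' hyperbolic-tangent interfaces of finite thickness:
#' `rho(z) = rho_v + (rho_l - rho_v)/2 * (tanh((z - z1)/w) - tanh((z - z2)/w))`.
#' When the two plateaus are statistically indistinguishable (single-phase
#' region, near or above the critical temperature) the point is flagged
#' `converged = FALSE` rather than raising an error.
#'
#' @param profile A `density_profile`.
#' @param temperature Temperature label for the point; defaults to the
#'   profile's own.
#' @param min_contrast Minimum relative plateau contrast
#'   `(rho_l - rho_v) / (rho_l + rho_v)` below which the point is flagged
#'   unconverged.
#' @return A one-row `coexistence point` tibble: `temperature`, `rho_v`,
#'   `rho_l`, `se_v`, `se_l`, `converged`. On converged output
#'   `rho_l >= rho_v >= 0`.
#' @export
fit_coexistence <- function(profile, temperature = NULL,
                            min_contrast = 0.25) {
  if (is.null(temperature)) temperature <- attr(profile, "temperature")
  if (is.null(temperature)) temperature <- NA_real_
  z <- profile$z
  rho <- profile$density
  n <- length(z)
  k <- max(2L, round(n / 8))
  ord <- order(rho)
  rho_v0 <- mean(rho[ord[seq_len(k)]])
  rho_l0 <- mean(rho[ord[seq(n - k + 1, n)]])
  unconverged <- tibble::tibble(temperature = temperature, rho_v = NA_real_,
                                rho_l = NA_real_, se_v = NA_real_,
                                se_l = NA_real_, converged = FALSE)
  if (!is.finite(rho_l0) || rho_l0 <= 0) return(unconverged)
  if ((rho_l0 - rho_v0) / (rho_l0 + rho_v0 + 1e-300) < min_contrast)
    return(unconverged)
  # starting interface positions: half-max crossings around the dense peak
  half <- (rho_l0 + rho_v0) / 2
  dense <- rho >= half
  if (!any(dense) || all(dense)) return(unconverged)
  z1_0 <- min(z[dense]); z2_0 <- max(z[dense])
  w0 <- max(diff(z)[1], (z2_0 - z1_0) / 10)
  dat <- data.frame(z = z, rho = rho)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rho ~ rv + (rl - rv) / 2 * (tanh((z - z1) / w) - tanh((z - z2) / w)),
      data = dat,
      start = list(rv = max(rho_v0, 0), rl = rho_l0, z1 = z1_0, z2 = z2_0,
                   w = w0),
      lower = c(0, 0, min(z), min(z), 1e-3),
      upper = c(Inf, Inf, max(z), max(z), diff(range(z))),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(unconverged)
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 5), names(est)))
  if (est[["rl"]] < est[["rv"]]) return(unconverged)
  contrast <- (est[["rl"]] - est[["rv"]]) /
    (est[["rl"]] + est[["rv"]] + 1e-300)
  if (!is.finite(contrast) || contrast < min_contrast) return(unconverged)
  tibble::tibble(temperature = temperature, rho_v = est[["rv"]],
                 rho_l = est[["rl"]], se_v = unname(se["rv"]),
                 se_l = unname(se["rl"]), converged = TRUE)
}

#' Fit a binodal and locate the critical point
#'
#' Simultaneously fits the order-parameter scaling law
#' `rho_l - rho_v = A (1 - T/Tc)^beta` and the law of rectilinear diameters
#' `(rho_l + rho_v)/2 = rho_c + B (Tc - T)` to a set of coexistence points.
#' The critical exponent is fixed to the 3D-Ising value `beta = 0.325` by
#' default (fitting it on small systems is unstable). Unconverged points and
#' points at or above the fitted critical temperature are excluded and
#' reported; points within `margin * Tc` below `Tc` are down-weighted to
#' soften interfacial-broadening bias. Predicted vapour densities are
#' clipped at zero.
#'
#' @param points Tibble of coexistence points ([fit_coexistence()] rows or
#'   [make_synthetic_binodal()] output).
#' @param beta Critical exponent (fixed, not fitted).
#' @param margin Fraction of `Tc` defining the down-weighted near-critical
#'   band.
#' @param near_tc_weight Weight applied to points inside the margin.
#' @return A `binodal_fit` object with elements `tc`, `rho_c`, `amplitude`,
#'   `diam_slope`, `beta`, `se` (named vector), `points` (input with an
#'   `included` flag) and `residual_sd`.
#' @export
build_binodal <- function(points, beta = 0.325, margin = 0.02,
                          near_tc_weight = 0.5) {
  pts <- tibble::as_tibble(points)
  usable <- pts$converged & is.finite(pts$rho_l) & is.finite(pts$rho_v)
  if (sum(usable) < 3)
    stop("insufficient data: need at least 3 converged sub-critical points")
  fit1 <- NULL
  for (iter in 1:3) {
    sub <- pts[usable, ]
    width <- sub$rho_l - sub$rho_v
    diam <- (sub$rho_l + sub$rho_v) / 2
    t_max <- max(sub$temperature)
    dfit <- lm(diam ~ sub$temperature)
    tc0 <- if (!is.null(fit1)) fit1$par[["tc"]] else
      t_max + 0.2 * diff(range(sub$temperature))
    a0 <- max(width) / max(1 - min(sub$temperature) / tc0, 1e-6)^beta
    resid_fn <- function(p) {
      tc <- p[["tc"]]; rhoc <- p[["rhoc"]]; a <- p[["a"]]; b <- p[["b"]]
      s <- pmax(1 - sub$temperature / tc, 0)
      wts <- ifelse(sub$temperature > (1 - margin) * tc,
                    sqrt(near_tc_weight), 1)
      c(wts * (width - a * s^beta),
        wts * (diam - (rhoc + b * (tc - sub$temperature))))
    }
    nls_out <- minpack.lm::nls.lm(
      par = c(tc = tc0, rhoc = mean(diam), a = a0,
              b = -unname(coef(dfit)[2])),
      fn = resid_fn,
      lower = c(min(sub$temperature), 0, 1e-12, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    fit1 <- nls_out
    tc_hat <- nls_out$par[["tc"]]
    new_usable <- usable & pts$temperature < tc_hat & pts$converged
    if (identical(new_usable, usable)) break
    if (sum(new_usable) < 3) break
    usable <- new_usable
  }
  p <- fit1$par
  covm <- tryCatch({
    dof <- max(length(fit1$fvec) - 4, 1)
    s2 <- sum(fit1$fvec^2) / dof
    s2 * solve(fit1$hessian / 2)
  }, error = function(e) NULL)
  se <- if (is.null(covm)) setNames(rep(NA_real_, 4), names(p)) else
    setNames(sqrt(pmax(diag(covm), 0)), names(p))
  pts$included <- usable
  structure(list(tc = p[["tc"]], rho_c = p[["rhoc"]],
                 amplitude = p[["a"]], diam_slope = p[["b"]], beta = beta,
                 se = c(tc = unname(se["tc"]), rho_c = unname(se["rhoc"]),
                        amplitude = unname(se["a"]),
                        diam_slope = unname(se["b"])),
                 points = pts,
                 residual_sd = sd(fit1$fvec)),
            class = "binodal_fit")
}

#' @export
print.binodal_fit <- function(x, ...) {
  cat("<binodal_fit> Tc = ", signif(x$tc, 6), " K (se ",
      signif(x$se[["tc"]], 3), "), rho_c = ", signif(x$rho_c, 4),
      ", beta = ", x$beta, "\n  ", sum(x$points$included), " of ",
      nrow(x$points), " points included\n", sep = "")
  invisible(x)
}

#' Predicted binodal branches
#'
#' @param object A `binodal_fit`.
#' @param temperature Temperatures at which to evaluate the fit.
#' @param ... Unused.
#' @return Tibble with `temperature`, `rho_v` (clipped at zero) and `rho_l`.
#' @export
predict.binodal_fit <- function(object, temperature = NULL, ...) {
  if (is.null(temperature))
    temperature <- seq(min(object$points$temperature), object$tc,
                       length.out = 100)
  s <- pmax(1 - temperature / object$tc, 0)
  width <- object$amplitude * s^object$beta
  diam <- object$rho_c + object$diam_slope * (object$tc - temperature)
  tibble::tibble(temperature = temperature,
                 rho_v = pmax(diam - width / 2, 0),
                 rho_l = diam + width / 2)
}

#' @export
tidy.binodal_fit <- function(x, ...) {
  tibble::tibble(
    term = c("tc", "rho_c", "amplitude", "diam_slope", "beta"),
    estimate = c(x$tc, x$rho_c, x$amplitude, x$diam_slope, x$beta),
    std.error = c(x$se[["tc"]], x$se[["rho_c"]], x$se[["amplitude"]],
                  x$se[["diam_slope"]], NA_real_))
}

#' @export
glance.binodal_fit <- function(x, ...) {
  tibble::tibble(tc = x$tc, rho_c = x$rho_c,
                 n_points = nrow(x$points),
                 n_included = sum(x$points$included),
                 residual_sd = x$residual_sd)
}

#' Ratio of two critical temperatures
#'
#' @param fit_a,fit_b `binodal_fit` objects.
#' @return One-row tibble: `ratio = Tc(a)/Tc(b)` with its uncertainty from
#'   quadrature-propagated relative errors.
#' @export
relative_tc <- function(fit_a, fit_b) {
  ratio <- fit_a$tc / fit_b$tc
  rel <- sqrt((fit_a$se[["tc"]] / fit_a$tc)^2 +
              (fit_b$se[["tc"]] / fit_b$tc)^2)
  tibble::tibble(ratio = ratio, se = ratio * rel)
}
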