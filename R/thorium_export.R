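# Export flux from 238U:234Th disequilibrium.
#
# 234Th (half-life 24.1 d) is produced at a known rate from conservative
# 238U (itself a linear function of salinity) and scavenged onto sinking
# particles.  The depth-integrated deficiency of total 234Th relative to
# 238U, times the decay constant, gives the steady-state (SS) export flux at
# the integration depth; repeat occupations of the same water parcel allow a
# non-steady-state (NSS) correction from the rate of change of the 234Th
# inventory.  An optional diffusive term -kappa * d2A/dz2 corrects for
# turbulent mixing.  Fluxes convert to carbon through a measured C:234Th
# ratio on sinking particles.

#' Thorium export model configuration
#'
#' @param lambda_234 234Th decay constant, d^-1; default `log(2)/24.1`
#'   (half-life 24.1 d).
#' @param kappa Vertical eddy diffusivity for the mixing correction,
#'   m^2 d^-1 (default 0: no correction).
#' @param u_coeffs Named vector `c(slope, intercept)` of the salinity ->
#'   238U activity relation, dpm L^-1 per psu; default the standard
#'   open-ocean relation `0.0786 * S - 0.315`.
#' @export
th_config <- function(lambda_234 = log(2) / 24.1, kappa = 0,
                      u_coeffs = c(slope = 0.0786, intercept = -0.315)) {
  assert_num(lambda_234, "lambda_234", lower = 0, strict = TRUE)
  assert_num(kappa, "kappa", lower = 0)
  structure(list(lambda_234 = lambda_234, kappa = kappa, u_coeffs = u_coeffs),
            class = "th_config")
}

#' Salinity-derived 238U activity
#'
#' `A_U = slope * S + intercept` (dpm L^-1).  Salinities outside the oceanic
#' range (30--38 psu) are accepted but flagged with a warning.
#'
#' @param salinity Practical salinity, psu (vectorised).
#' @param cfg A [th_config()].
#' @export
u238_from_salinity <- function(salinity, cfg = th_config()) {
  if (any(salinity < 30 | salinity > 38))
    warning("salinity outside the oceanic range 30-38 psu; 238U relation extrapolated",
            call. = FALSE)
  cfg$u_coeffs[["slope"]] * salinity + cfg$u_coeffs[["intercept"]]
}

#' Construct a total 234Th profile
#'
#' @param date Occupation date (`Date` or anything `as.Date` accepts).
#' @param depth Sample depths, m, strictly increasing.
#' @param a_th Total 234Th activity, dpm L^-1 (>= 0).
#' @param a_th_sd Measurement standard deviation, dpm L^-1.
#' @param salinity Practical salinity, psu.
#' @return data.frame of class `th_profile` with a `date` attribute.
#' @export
th_profile <- function(date, depth, a_th, a_th_sd = 0, salinity) {
  if (is.unsorted(depth, strictly = TRUE)) stopf("depths must be strictly increasing")
  assert_num(a_th, "a_th", lower = 0)
  df <- data.frame(depth = depth, a_th = a_th,
                   a_th_sd = rep_len(a_th_sd, length(depth)),
                   salinity = rep_len(salinity, length(depth)))
  attr(df, "date") <- as.Date(date)
  class(df) <- c("th_profile", "data.frame")
  df
}

# constant continuation of the shallowest sample up to the surface
extend_to_surface <- function(p) {
  if (p$depth[1] > 0) {
    top <- p[1, , drop = FALSE]
    top$depth <- 0
    p <- rbind(top, p)
  }
  p
}

# second derivative of a on an irregular grid z (3-point; endpoints copy the
# adjacent interior value)
second_deriv <- function(z, a) {
  n <- length(z)
  d2 <- numeric(n)
  if (n < 3) return(d2)
  for (i in 2:(n - 1)) {
    h1 <- z[i] - z[i - 1]; h2 <- z[i + 1] - z[i]
    d2[i] <- 2 * (a[i - 1] / (h1 * (h1 + h2)) - a[i] / (h1 * h2) +
                    a[i + 1] / (h2 * (h1 + h2)))
  }
  d2[1] <- d2[2]; d2[n] <- d2[n - 1]
  d2
}

# trapezoid quadrature weights on grid z (same length as z)
trapz_weights <- function(z) {
  n <- length(z)
  w <- numeric(n)
  dz <- diff(z)
  w[1] <- dz[1] / 2; w[n] <- dz[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dz[-length(dz)] + dz[-1]) / 2
  w
}

# restrict an (extended) profile to [0, z_int], adding an interpolated node
# at z_int
clip_profile <- function(p, z_int) {
  if (z_int > max(p$depth)) stopf("z_int = %g m is below the deepest sample (%g m)",
                                  z_int, max(p$depth))
  if (!(z_int %in% p$depth)) {
    new <- data.frame(depth = z_int,
                      a_th = stats::approx(p$depth, p$a_th, z_int)$y,
                      a_th_sd = stats::approx(p$depth, p$a_th_sd, z_int)$y,
                      salinity = stats::approx(p$depth, p$salinity, z_int)$y)
    p <- rbind(p, new)
    p <- p[order(p$depth), , drop = FALSE]
  }
  p[p$depth <= z_int, , drop = FALSE]
}

#' Steady-state 234Th export flux
#'
#' Integrates the 238U--234Th deficiency from the surface (shallowest sample
#' continued to 0 m) to `z_int` by the trapezoid rule:
#' `flux = lambda * int(A_U - A_Th) dz + int M dz`, with the mixing term
#' `M = -kappa * d2(A_Th)/dz2` (central differences on the sample grid).
#' Activities in dpm L^-1 are converted to dpm m^-3 (x1000).  Measurement
#' uncertainties propagate in quadrature through the quadrature weights.
#'
#' @param profile A [th_profile()].
#' @param z_int Integration depth, m (within the profile).
#' @param cfg A [th_config()].
#' @return List: `flux`, `sd` (dpm m^-2 d^-1), and `components`
#'   (`decay`, `mixing`).
#' @export
ss_export <- function(profile, z_int, cfg = th_config()) {
  stopifnot(inherits(profile, "th_profile"))
  p <- clip_profile(extend_to_surface(as.data.frame(profile)), z_int)
  a_u <- cfg$u_coeffs[["slope"]] * p$salinity + cfg$u_coeffs[["intercept"]]
  deficiency <- a_u - p$a_th                       # dpm L^-1
  decay <- cfg$lambda_234 * 1000 * pracma::trapz(p$depth, deficiency)
  mixing <- 0
  if (cfg$kappa > 0) {
    # curvature on the raw sample grid, so the constant surface extension
    # does not inject an artificial kink
    raw <- as.data.frame(profile)
    m <- -cfg$kappa * second_deriv(raw$depth, raw$a_th)
    mixing <- 1000 * trapz_extended(raw$depth, m, 0, z_int)
  }
  w <- trapz_weights(p$depth)
  sd <- cfg$lambda_234 * 1000 * sqrt(sum((w * p$a_th_sd)^2))
  list(flux = decay + mixing, sd = sd,
       components = list(decay = decay, mixing = mixing))
}

#' Non-steady-state 234Th export flux from two occupations
#'
#' `flux = lambda * int(A_U - Abar_Th) dz - (I2 - I1)/(t2 - t1)`, where
#' `Abar_Th` is the two-profile mean on the union depth grid and `I` the
#' trapezoidal 234Th inventory (dpm m^-2) to `z_int`.  Collapses to
#' [ss_export()] when the profiles are identical.
#'
#' @param p1,p2 [th_profile()] objects, `p2` later than `p1`, both spanning
#'   `z_int`.
#' @param z_int Integration depth, m.
#' @param cfg A [th_config()].
#' @return List: `flux`, `sd`, `components` (`decay`, `mixing`,
#'   `inventory_change`).
#' @export
nss_export <- function(p1, p2, z_int, cfg = th_config()) {
  stopifnot(inherits(p1, "th_profile"), inherits(p2, "th_profile"))
  t1 <- attr(p1, "date"); t2 <- attr(p2, "date")
  dt <- as.numeric(t2 - t1)
  if (dt <= 0) stopf("p2 must be sampled after p1 (got dt = %g d)", dt)
  e1 <- extend_to_surface(as.data.frame(p1)); e2 <- extend_to_surface(as.data.frame(p2))
  grid <- sort(unique(c(e1$depth, e2$depth, z_int)))
  grid <- grid[grid <= z_int]
  on_grid <- function(p) data.frame(
    depth = grid,
    a_th = stats::approx(p$depth, p$a_th, grid, rule = 2)$y,
    a_th_sd = stats::approx(p$depth, p$a_th_sd, grid, rule = 2)$y,
    salinity = stats::approx(p$depth, p$salinity, grid, rule = 2)$y)
  g1 <- on_grid(e1); g2 <- on_grid(e2)
  if (z_int > max(e1$depth) || z_int > max(e2$depth))
    stopf("z_int = %g m is below the deepest sample", z_int)
  abar <- (g1$a_th + g2$a_th) / 2
  sbar <- (g1$salinity + g2$salinity) / 2
  a_u <- cfg$u_coeffs[["slope"]] * sbar + cfg$u_coeffs[["intercept"]]
  decay <- cfg$lambda_234 * 1000 * pracma::trapz(grid, a_u - abar)
  mixing <- 0
  if (cfg$kappa > 0) {
    raw <- grid[grid >= max(min(as.data.frame(p1)$depth),
                            min(as.data.frame(p2)$depth))]
    m <- -cfg$kappa * second_deriv(raw, abar[match(raw, grid)])
    mixing <- 1000 * trapz_extended(raw, m, 0, z_int)
  }
  inv1 <- 1000 * pracma::trapz(grid, g1$a_th)
  inv2 <- 1000 * pracma::trapz(grid, g2$a_th)
  dinv <- (inv2 - inv1) / dt
  w <- trapz_weights(grid)
  sd_bar <- cfg$lambda_234 * 1000 *
    sqrt(sum((w * sqrt(g1$a_th_sd^2 + g2$a_th_sd^2) / 2)^2))
  sd_inv <- 1000 * sqrt(sum((w * g1$a_th_sd)^2) + sum((w * g2$a_th_sd)^2)) / dt
  list(flux = decay + mixing - dinv, sd = sqrt(sd_bar^2 + sd_inv^2),
       components = list(decay = decay, mixing = mixing, inventory_change = dinv))
}

#' Convert a 234Th flux to POC flux via a C:234Th ratio
#'
#' `POC = th_flux * c_to_th * 12.011 / 1000` (µmol C -> mg C).
#'
#' @param th_flux 234Th flux, dpm m^-2 d^-1.
#' @param c_to_th C:234Th ratio of sinking particles, µmol C dpm^-1.
#' @return POC flux, mg C m^-2 d^-1.
#' @export
poc_flux_from_th <- function(th_flux, c_to_th) {
  assert_num(c_to_th, "c_to_th", lower = 0)
  th_flux * c_to_th * 12.011 / 1000
}
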