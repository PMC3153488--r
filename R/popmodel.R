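# Exact two-locus population-genetic theory for the admixture model:
# joint genotype distributions, mixture moments, the genuine/spurious
# covariance decomposition, theoretical regression coefficients for the
# three analyses, and noncentral-t power prediction.

#' Joint genotype distribution at a test marker and a QTL
#'
#' Probability table of the nine joint genotypes in a randomly mating
#' population, parameterized by the allele frequencies and the LD
#' coefficient. With `Q = P(T|A)` and `R = P(T|a)` the cell probabilities
#' are products of gamete probabilities, e.g. `P(AA, TT) = (qQ)^2` and
#' `P(Aa, Tt) = 2q(1-q)(Q + R - 2QR)`.
#'
#' @param pair A [locus_pair()].
#' @return A 3x3 numeric matrix; rows are QTL genotypes `AA`, `Aa`, `aa`,
#'   columns marker genotypes `TT`, `Tt`, `tt`. Entries are nonnegative and
#'   sum to one; the implied allele-count covariance equals `2D`.
#' @examples
#' joint_genotype_distribution(locus_pair(q = 0.5, p = 0.5, D = 0))
#' @export
joint_genotype_distribution <- function(pair) {
  stopifnot(inherits(pair, "locus_pair"))
  q <- pair$q; Q <- pair$Q; R <- pair$R
  tab <- rbind(
    AA = q^2           * c(Q^2, 2 * Q * (1 - Q), (1 - Q)^2),
    Aa = 2 * q * (1 - q) * c(Q * R, Q + R - 2 * Q * R, (1 - Q) * (1 - R)),
    aa = (1 - q)^2     * c(R^2, 2 * R * (1 - R), (1 - R)^2)
  )
  colnames(tab) <- c("TT", "Tt", "tt")
  tab
}

# Per-subpopulation summaries used throughout: within-population marker
# variance, marker-trait covariance and subpopulation trait mean.
subpop_summary <- function(sp, eff) {
  q <- sp$q; p <- sp$p; D <- sp$D
  list(
    mean_x  = 2 * p,
    var_x   = 2 * p * (1 - p),
    mean_z  = 2 * sp$c,
    # genetic deviation gamma(g) in {-d, h, d}; mean and second moment
    mean_g  = eff$d * (2 * q - 1) + 2 * eff$h * q * (1 - q),
    msq_g   = eff$d^2 * (q^2 + (1 - q)^2) + eff$h^2 * 2 * q * (1 - q),
    cov_xy  = 2 * D * (eff$d + (1 - 2 * q) * eff$h)
  )
}

#' Exact first and second moments of the admixed population
#'
#' Closed-form mixture moments of the test-marker genotype `X`, trait `Y`
#' and control-marker genotype `Z` under an [admixture_spec()], including
#' the decomposition of `Cov(X, Y)` into its genuine (within-subpopulation
#' LD) and spurious (stratification) components and the control-marker
#' structure signal `delta`.
#'
#' @param spec An [admixture_spec()].
#' @return A list with elements `mean_x`, `var_x`, `mean_y`, `var_y`,
#'   `mean_z`, `var_z`, `var_z_expected`, `delta`, `cov_xy_total`,
#'   `cov_xy_genuine`, `cov_xy_spurious`, `cov_xz`, `cov_zy` and the
#'   per-subpopulation summaries in `subpops`.
#' @export
mixture_moments <- function(spec) {
  stopifnot(inherits(spec, "admixture_spec"))
  m <- spec$m; eff <- spec$effects
  s1 <- subpop_summary(spec$subpop1, eff)
  s2 <- subpop_summary(spec$subpop2, eff)
  w <- c(m, 1 - m)
  dp <- spec$subpop1$p - spec$subpop2$p
  dc <- spec$subpop1$c - spec$subpop2$c
  dg <- s1$mean_g - s2$mean_g

  mean_x <- w[1] * s1$mean_x + w[2] * s2$mean_x
  var_x  <- w[1] * s1$var_x + w[2] * s2$var_x + m * (1 - m) * (2 * dp)^2
  mean_g <- w[1] * s1$mean_g + w[2] * s2$mean_g
  var_g  <- w[1] * s1$msq_g + w[2] * s2$msq_g - mean_g^2

  cbar <- w[1] * spec$subpop1$c + w[2] * spec$subpop2$c
  # inline so that the degenerate single-population case m = 1 is allowed
  svi <- list(var_expected = 2 * cbar * (1 - cbar),
              delta = 2 * m * (1 - m) * dc^2)
  svi$var_observed <- svi$var_expected + svi$delta

  genuine  <- w[1] * s1$cov_xy + w[2] * s2$cov_xy
  spurious <- 2 * m * (1 - m) * dp * dg

  list(
    mean_x = mean_x, var_x = var_x,
    mean_y = eff$mu + mean_g, var_y = var_g + eff$sigma2,
    mean_z = 2 * cbar, var_z = svi$var_observed,
    var_z_expected = svi$var_expected, delta = svi$delta,
    cov_xy_total = genuine + spurious,
    cov_xy_genuine = genuine, cov_xy_spurious = spurious,
    cov_xz = 4 * m * (1 - m) * dp * dc,
    cov_zy = 2 * m * (1 - m) * dc * dg,
    cov_xp = 2 * m * (1 - m) * dp,
    cov_py = m * (1 - m) * dg,
    var_p = m * (1 - m),
    subpops = list(s1, s2)
  )
}

#' Marker-QTL LD coefficient in the admixed population
#'
#' The mixture LD is the weighted within-subpopulation LD plus a
#' nonlinear term created by allele-frequency divergence:
#' `D_mix = m D1 + (1-m) D2 + m(1-m)(p1-p2)(q1-q2)`.
#'
#' @param spec An [admixture_spec()].
#' @return The mixture LD coefficient (dimensionless).
#' @export
mixture_ld <- function(spec) {
  stopifnot(inherits(spec, "admixture_spec"))
  m <- spec$m
  s1 <- spec$subpop1; s2 <- spec$subpop2
  m * s1$D + (1 - m) * s2$D + m * (1 - m) * (s1$p - s2$p) * (s1$q - s2$q)
}

#' Genuine/spurious decomposition of the marker-trait covariance
#'
#' In the admixed population `Cov(X, Y)` splits exactly into a genuine part
#' (the admixture-weighted within-subpopulation covariances, each equal to
#' `2 D_i (d + (1 - 2 q_i) h)`) and a spurious part created by
#' stratification, `2 m (1-m) (p1 - p2)(mu1 - mu2)` where `mu_i` is the
#' subpopulation trait mean.
#'
#' @param spec An [admixture_spec()].
#' @return An object of class `cov_decomposition`: a list with `total`,
#'   `genuine` and `spurious`, satisfying `total = genuine + spurious`.
#' @export
mixture_covariance <- function(spec) {
  mom <- mixture_moments(spec)
  structure(list(total = mom$cov_xy_total,
                 genuine = mom$cov_xy_genuine,
                 spurious = mom$cov_xy_spurious),
            class = "cov_decomposition")
}

#' @export
print.cov_decomposition <- function(x, ...) {
  cat(sprintf("Cov(X,Y) = %g  [genuine %g + spurious %g]\n",
              x$total, x$genuine, x$spurious))
  invisible(x)
}

#' Expected vs observed genotypic variance at a control marker
#'
#' Under admixture the expected (Hardy-Weinberg) genotypic variance at an
#' unlinked control marker is `2 cbar (1 - cbar)` with
#' `cbar = m c1 + (1-m) c2`, while the observed variance exceeds it by
#' `delta = 2 m (1-m) (c1 - c2)^2`. A positive `delta` is the structure
#' signal exploited by the corrected analysis.
#'
#' @param m Admixture proportion in (0, 1).
#' @param c1,c2 Control-marker allele frequencies in the two subpopulations.
#' @return A list with `var_expected`, `var_observed` and `delta`
#'   (`delta >= 0` always).
#' @examples
#' structure_variance_inflation(0.5, 0.9, 0.1)
#' @export
structure_variance_inflation <- function(m, c1, c2) {
  if (m <= 0 || m >= 1) stop("admixture proportion m must be in (0,1)")
  for (v in c(c1, c2)) if (v <= 0 || v >= 1)
    stop("control marker frequencies must be in (0,1)")
  cbar <- m * c1 + (1 - m) * c2
  delta <- 2 * m * (1 - m) * (c1 - c2)^2
  list(var_expected = 2 * cbar * (1 - cbar),
       var_observed = 2 * cbar * (1 - cbar) + delta,
       delta = delta)
}

#' Control-marker-corrected covariance from sufficient statistics
#'
#' The spurious stratification component of `Cov(X, Y)` factors through the
#' latent ancestry, so it can be removed exactly using the control marker:
#' `Cov* = Cov(X, Y) - Cov(X, Z) Cov(Z, Y) / (2 delta)` where `delta` is the
#' observed-minus-expected variance at the control marker.
#'
#' @param cov_xy,cov_xz,cov_zy Covariances of trait, test-marker and
#'   control-marker genotypes.
#' @param delta Control-marker structure signal; must be nonzero.
#' @return The corrected covariance.
#' @export
corrected_covariance <- function(cov_xy, cov_xz, cov_zy, delta) {
  if (!is.finite(delta) || delta == 0)
    stop("control marker carries no structure signal (delta = 0)")
  cov_xy - cov_xz * cov_zy / (2 * delta)
}

#' Population-level regression coefficient for each analysis method
#'
#' Exact large-sample value of the slope each analysis estimates:
#' `"simple"` is `Cov(X, Y) / Var(X)` with full mixture moments (so it
#' absorbs the spurious component); `"corrected"` is the control-marker
#' corrected covariance over `Var(X)` and equals the genuine covariance over
#' `Var(X)`; `"structured"` is the partial slope of `Y` on `X` given true
#' subpopulation membership.
#'
#' @param spec An [admixture_spec()].
#' @param method One of `"corrected"`, `"simple"`, `"structured"`.
#' @return The population-level regression coefficient.
#' @export
theoretical_coefficient <- function(spec,
                                    method = c("corrected", "simple",
                                               "structured")) {
  method <- match.arg(method)
  mom <- mixture_moments(spec)
  switch(method,
    simple = mom$cov_xy_total / mom$var_x,
    corrected = {
      if (spec$subpop1$c == spec$subpop2$c)
        stop("structure uncorrectable by this control marker: c1 = c2 gives delta = 0")
      cstar <- if (mom$delta > 0)
        corrected_covariance(mom$cov_xy_total, mom$cov_xz, mom$cov_zy,
                             mom$delta)
      else mom$cov_xy_total   # no structure: nothing to subtract
      cstar / mom$var_x
    },
    structured = {
      den <- mom$var_x * mom$var_p - mom$cov_xp^2
      if (den <= 0) stop("confounded design: X fully determined by membership")
      (mom$var_p * mom$cov_xy_total - mom$cov_xp * mom$cov_py) / den
    })
}

# Exact asymptotic variance (times n) of the corrected slope, computed by
# enumerating the joint distribution of (X, G, Z) over both subpopulations
# and integrating the influence function of the estimator. The influence
# function treats the corrected slope as a smooth function of the sample
# moments (Sxy, Sxz, Szy, Sxx, delta-hat).
corrected_slope_if_variance <- function(spec) {
  mom <- mixture_moments(spec)
  eff <- spec$effects
  sxx <- mom$var_x; sxy <- mom$cov_xy_total
  sxz <- mom$cov_xz; szy <- mom$cov_zy; szz <- mom$var_z
  delta <- mom$delta
  if (delta <= 0) stop("influence variance undefined without structure signal")
  b  <- corrected_covariance(sxy, sxz, szy, delta) / sxx
  c1 <- szy / (2 * delta); c2 <- sxz / (2 * delta)
  c3 <- sxz * szy / (2 * delta^2)
  mx <- mom$mean_x; mz <- mom$mean_z
  gbar <- mom$mean_y - eff$mu

  w <- c(spec$m, 1 - spec$m)
  total <- 0
  for (i in 1:2) {
    sp <- spec[[paste0("subpop", i)]]
    jt <- joint_genotype_distribution(sp$pair)   # rows AA,Aa,aa ~ g = 2,1,0
    pz <- stats::dbinom(0:2, 2, sp$c)
    for (gi in 1:3) for (xi in 1:3) {
      pgx <- jt[gi, xi]
      if (pgx == 0) next
      g <- 3 - gi          # QTL allele count
      x <- 3 - xi          # marker allele count
      gv <- c(-eff$d, eff$h, eff$d)[g + 1]
      gd <- gv - gbar      # E[y - mean_y | g]
      xd <- x - mx
      for (zi in 0:2) {
        pw <- w[i] * pgx * pz[zi + 1]
        if (pw == 0) next
        zd <- zi - mz
        if_delta <- (zd^2 - szz) + (mz - 1) * zd
        alpha <- (-sxy - c1 * (xd * zd - sxz) + c2 * szy + c3 * if_delta -
                    b * (xd^2 - sxx)) / sxx
        beta <- (xd - c2 * zd) / sxx
        total <- total + pw * (alpha^2 + 2 * alpha * beta * gd +
                                 beta^2 * (gd^2 + eff$sigma2))
      }
    }
  }
  total
}

#' Power of the slope t-test from the noncentral t distribution
#'
#' Predicts `P(|T'| > t_{alpha/2, v})` where `T'` is noncentral t with
#' `v = n - 3` degrees of freedom. The noncentrality parameter is
#' `b sqrt(n Var(X) / sigma2)` scaled, in the default `"gamma"` form, by the
#' small-sample factor `sqrt(2/v) Gamma(v/2) / Gamma((v-1)/2)` that makes
#' the mean of the noncentral t equal the expected t ratio
#' (Johnson-Kotz moment matching); `"asymptotic"` omits the factor.
#'
#' @param b Population-level regression coefficient.
#' @param var_x Variance of the marker genotype.
#' @param sigma2_resid Effective residual variance of the fit (for the
#'   corrected analysis this includes the sampling noise of the correction
#'   term; see [predict_power_for_spec()]).
#' @param n Sample size (> 3).
#' @param alpha Two-sided test size in (0, 1).
#' @param ncp_form `"gamma"` (default) or `"asymptotic"`.
#' @return An object of class `power_prediction`: list with `power`, `v`,
#'   `ncp` and `alpha`.
#' @examples
#' predict_power(b = 0.25, var_x = 0.5, sigma2_resid = 1, n = 200, alpha = 0.05)
#' @export
predict_power <- function(b, var_x, sigma2_resid, n, alpha = 0.05,
                          ncp_form = c("gamma", "asymptotic")) {
  ncp_form <- match.arg(ncp_form)
  if (n <= 3) stop("power prediction requires n > 3 (v = n - 3 must be positive)")
  stopifnot(var_x > 0, sigma2_resid > 0, alpha > 0, alpha < 1)
  v <- n - 3
  ncp <- b * sqrt(n * var_x / sigma2_resid)
  if (ncp_form == "gamma")
    ncp <- ncp * exp(0.5 * log(2 / v) + lgamma(v / 2) - lgamma((v - 1) / 2))
  tc <- stats::qt(1 - alpha / 2, df = v)
  power <- if (ncp == 0) alpha else
    stats::pt(-tc, df = v, ncp = ncp) + 1 - stats::pt(tc, df = v, ncp = ncp)
  structure(list(power = power, v = v, ncp = ncp, alpha = alpha),
            class = "power_prediction")
}

#' @export
print.power_prediction <- function(x, ...) {
  cat(sprintf("predicted power %.4f (v = %d, ncp = %.4f, alpha = %g)\n",
              x$power, x$v, x$ncp, x$alpha))
  invisible(x)
}

#' Predicted power of each analysis under an admixture scenario
#'
#' Combines [theoretical_coefficient()] with the exact large-sample variance
#' of the corresponding estimator to predict the power of the slope t-test
#' at sample size `n`. For the corrected analysis the estimator variance is
#' obtained from its influence function (it exceeds the naive residual
#' variance because the correction term is itself estimated); for the simple
#' and membership-regression analyses the classical least-squares forms are
#' used.
#'
#' @param spec An [admixture_spec()].
#' @param n Sample size.
#' @param method `"corrected"`, `"simple"` or `"structured"`.
#' @param alpha Two-sided test size.
#' @param ncp_form Passed to [predict_power()].
#' @return A `power_prediction` object.
#' @export
predict_power_for_spec <- function(spec, n,
                                   method = c("corrected", "simple",
                                              "structured"),
                                   alpha = 0.05,
                                   ncp_form = c("gamma", "asymptotic")) {
  method <- match.arg(method)
  mom <- mixture_moments(spec)
  b <- theoretical_coefficient(spec, method)
  sigma2_eff <- switch(method,
    simple = mom$var_y - mom$cov_xy_total^2 / mom$var_x,
    # the influence variance is already on the slope scale: solve
    # sigma2_eff / (n var_x) = E[IF^2] / n for the effective residual variance
    corrected = corrected_slope_if_variance(spec) * mom$var_x,
    structured = {
      den <- mom$var_x * mom$var_p - mom$cov_xp^2
      b2 <- (mom$var_x * mom$cov_py - mom$cov_xp * mom$cov_xy_total) / den
      resid <- mom$var_y - b * mom$cov_xy_total - b2 * mom$cov_py
      rho2 <- mom$cov_xp^2 / (mom$var_x * mom$var_p)
      resid / (1 - rho2)
    })
  predict_power(b, mom$var_x, sigma2_eff, n, alpha, ncp_form = ncp_form)
}
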