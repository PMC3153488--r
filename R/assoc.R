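# The three association analyses: control-marker-corrected regression,
# uncorrected simple regression, and multiple regression on population
# membership; plus control-marker screening and selection.

new_assoc_result <- function(b, se, df, p, method, n_used, extra = list()) {
  structure(c(list(b = b, se = se, t = if (se > 0) b / se else 0,
                   df = df, p = p, method = method, n_used = n_used),
              extra),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s regression: b = %.4g (se %.4g), t = %.3f, df = %d, p = %.3g, n = %d\n",
              x$method, x$b, x$se, x$t, x$df, x$p, x$n_used))
  invisible(x)
}

# two-sided t-test p-value, kept strictly positive so downstream -log10
# transforms stay finite
two_sided_p <- function(t, df) {
  if (!is.finite(t)) return(.Machine$double.xmin)
  max(2 * stats::pt(-abs(t), df), .Machine$double.xmin)
}

#' Simple regression test for marker-trait association
#'
#' Ordinary least-squares regression of the trait on the marker allele
#' count: `b = Cov(X, Y) / Var(X)` with the classical slope standard error
#' on `n - 2` degrees of freedom. In a single randomly mating population
#' the slope is `2D(d + (1 - 2q)h) / (2p(1-p))`, so its t-test is a test of
#' LD between marker and QTL; in a structured population the slope also
#' absorbs the spurious stratification component.
#'
#' @param x Marker allele counts (0/1/2, NA allowed).
#' @param y Trait values (NA allowed). Complete pairs are used.
#' @return An `assoc_result` with fields `b`, `se`, `t`, `df`, `p`,
#'   `method = "simple"`, `n_used`.
#' @export
fit_simple <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  n <- length(x)
  if (n < 3) stop("need at least 3 complete (x, y) pairs")
  sxx <- stats::var(x)
  if (sxx == 0) stop("zero marker variance: monomorphic test marker")
  sxy <- stats::cov(x, y); syy <- stats::var(y)
  b <- sxy / sxx
  sse <- (n - 1) * (syy - b * sxy)
  sse <- max(sse, 0)
  se <- sqrt(sse / (n - 2) / ((n - 1) * sxx))
  df <- n - 2L
  p <- if (se == 0) {
    if (b == 0) 1 else .Machine$double.xmin
  } else two_sided_p(b / se, df)
  new_assoc_result(b, se, df, p, "simple", n)
}

# delta-hat (observed minus HWE-expected variance) of a control-marker
# genotype vector, plus its jackknife standard error (leave-one-out,
# computed in O(n) with updating formulas)
control_delta <- function(z) {
  n <- length(z)
  mz <- mean(z)
  var_obs <- stats::var(z)
  delta <- var_obs - mz * (1 - mz / 2)   # 2 p(1-p) with p = mean(z)/2
  if (n < 3) return(list(delta = delta, se_jack = Inf))
  S <- sum(z); Q <- sum(z^2)
  m_i <- (S - z) / (n - 1)
  v_i <- (Q - z^2 - (n - 1) * m_i^2) / (n - 2)
  d_i <- v_i - m_i * (1 - m_i / 2)
  se_jack <- sqrt((n - 1) / n * sum((d_i - mean(d_i))^2))
  list(delta = delta, se_jack = se_jack)
}

#' Control-marker-corrected regression test
#'
#' Removes the spurious stratification component of the marker-trait
#' covariance using a single control marker `Z` (an autosomal marker on
#' another chromosome, in linkage equilibrium with both QTL and test marker
#' within subpopulations). The corrected covariance is
#' `Cov* = Cov(X,Y) - Cov(X,Z) Cov(Z,Y) / (2 delta)` where
#' `delta = var_obs(Z) - 2 p(1-p)` is the control marker's excess of
#' observed over Hardy-Weinberg-expected genotypic variance; the reported
#' slope is `b* = Cov* / Var(X)`, tested by Student's t on `n - 3` degrees
#' of freedom.
#'
#' The default standard error is the delta-method (influence-function)
#' estimate, which accounts for the sampling noise of the correction term
#' and is calibrated under stratified nulls; `se = "ols"` gives the naive
#' residual-based slope standard error instead (anti-conservative under
#' strong structure; retained for comparison).
#'
#' The correction divides by `delta`, so it is only attempted when the
#' estimated structure signal clearly exceeds its sampling noise:
#' `delta > delta_k * SE_jackknife(delta)`. Below that (including negative
#' `delta`, which arises by sampling under panmixia) the control marker
#' carries no usable signal; the fit errors, or with `fallback = TRUE`
#' degrades to [fit_simple()] with a warning.
#'
#' @param x Test-marker allele counts (0/1/2, NA allowed).
#' @param z Control-marker allele counts (0/1/2, NA allowed).
#' @param y Trait values. Complete (x, z, y) triples are used.
#' @param delta_k Signal-to-noise multiple required of `delta` (default 2).
#' @param se `"delta"` (default) or `"ols"`.
#' @param fallback If TRUE, fall back to the simple regression with a
#'   warning when the control marker carries no structure signal.
#' @return An `assoc_result` with `method = "corrected"` plus fields
#'   `delta` and `delta_se`.
#' @export
fit_corrected <- function(x, z, y, delta_k = 2,
                          se = c("delta", "ols"), fallback = FALSE) {
  se_type <- match.arg(se)
  keep <- stats::complete.cases(x, z, y)
  x <- as.numeric(x[keep]); z <- as.numeric(z[keep]); y <- as.numeric(y[keep])
  n <- length(x)
  if (n < 4) stop("need at least 4 complete (x, z, y) triples")
  sxx <- stats::var(x)
  if (sxx == 0) stop("zero marker variance: monomorphic test marker")
  cd <- control_delta(z)
  if (!is.finite(cd$delta) || cd$delta <= delta_k * cd$se_jack) {
    msg <- sprintf(
      "control marker carries no structure signal (delta = %.4g, jackknife se = %.4g)",
      cd$delta, cd$se_jack)
    if (fallback) {
      warning(msg, "; falling back to the simple regression", call. = FALSE)
      return(fit_simple(x, y))
    }
    stop(errorCondition(msg, class = c("cmassoc_no_structure_signal",
                                       "error", "condition")))
  }
  delta <- cd$delta
  mx <- mean(x); my <- mean(y); mz <- mean(z)
  sxy <- stats::cov(x, y); sxz <- stats::cov(x, z)
  szy <- stats::cov(z, y); syy <- stats::var(y); szz <- stats::var(z)
  cstar <- corrected_covariance(sxy, sxz, szy, delta)
  b <- cstar / sxx
  df <- n - 3L
  if (se_type == "delta") {
    c1 <- szy / (2 * delta); c2 <- sxz / (2 * delta)
    c3 <- sxz * szy / (2 * delta^2)
    xd <- x - mx; yd <- y - my; zd <- z - mz
    if_delta <- (zd^2 - szz) + (mz - 1) * zd
    infl <- (xd * yd - sxy - c1 * (xd * zd - sxz) - c2 * (zd * yd - szy) +
               c3 * if_delta - b * (xd^2 - sxx)) / sxx
    se_b <- sqrt(sum(infl^2)) / n
  } else {
    sse <- max((n - 1) * (syy - 2 * b * sxy + b^2 * sxx), 0)
    se_b <- sqrt(sse / df / ((n - 1) * sxx))
  }
  p <- if (se_b == 0) {
    if (b == 0) 1 else .Machine$double.xmin
  } else two_sided_p(b / se_b, df)
  new_assoc_result(b, se_b, df, p, "corrected", n,
                   extra = list(delta = delta, delta_se = cd$se_jack))
}

#' Multiple regression on marker genotype and population membership
#'
#' Regresses the trait on the marker allele count and the probability of
#' membership to subpopulation 1, `Y = b0 + b1 X + b2 P + e`, and tests the
#' marker coefficient `b1` by Student's t on `n - 3` degrees of freedom.
#' Coefficients and standard errors follow the classical normal-equations
#' forms for two regressors.
#'
#' If the membership covariate is constant it carries no information and is
#' dropped, but the residual degrees of freedom remain `n - 3` (a
#' membership parameter was still spent); if marker and membership are
#' collinear the design is confounded and the fit errors.
#'
#' @param x Marker allele counts (0/1/2, NA allowed).
#' @param membership_prob Probability of membership to subpopulation 1,
#'   each in \[0, 1\].
#' @param y Trait values. Complete rows are used.
#' @return An `assoc_result` with `method = "structured"` plus field `b2`
#'   (the membership coefficient, NA when membership was constant).
#' @export
fit_structured <- function(x, membership_prob, y) {
  keep <- stats::complete.cases(x, membership_prob, y)
  x <- as.numeric(x[keep]); pm <- as.numeric(membership_prob[keep])
  y <- as.numeric(y[keep])
  n <- length(x)
  if (n < 4) stop("need at least 4 complete (x, membership, y) rows")
  if (any(pm < 0 | pm > 1)) stop("membership probabilities must be in [0, 1]")
  sxx <- stats::var(x)
  if (sxx == 0) stop("zero marker variance: monomorphic test marker")
  spp <- stats::var(pm)
  df <- n - 3L
  if (spp == 0) {
    # membership uninformative: slope from the simple fit, df still n - 3
    sxy <- stats::cov(x, y); syy <- stats::var(y)
    b1 <- sxy / sxx
    sse <- max((n - 1) * (syy - b1 * sxy), 0)
    se1 <- sqrt(sse / df / ((n - 1) * sxx))
    p <- if (se1 == 0) { if (b1 == 0) 1 else .Machine$double.xmin }
         else two_sided_p(b1 / se1, df)
    return(new_assoc_result(b1, se1, df, p, "structured", n,
                            extra = list(b2 = NA_real_)))
  }
  sxp <- stats::cov(x, pm)
  det <- sxx * spp - sxp^2
  if (det <= 1e-12 * sxx * spp)
    stop("confounded design: marker genotype collinear with membership")
  sxy <- stats::cov(x, y); spy <- stats::cov(pm, y); syy <- stats::var(y)
  b1 <- (spp * sxy - sxp * spy) / det
  b2 <- (sxx * spy - sxp * sxy) / det
  sse <- max((n - 1) * (syy - b1 * sxy - b2 * spy), 0)
  s2 <- sse / df
  se1 <- sqrt(s2 * spp / ((n - 1) * det))
  p <- if (se1 == 0) { if (b1 == 0) 1 else .Machine$double.xmin }
       else two_sided_p(b1 / se1, df)
  new_assoc_result(b1, se1, df, p, "structured", n,
                   extra = list(b2 = b2))
}

#' Screen markers eligible as control-marker candidates
#'
#' A candidate control marker must be autosomal, lie on a different
#' chromosome from the test marker, differ from the test marker itself, and
#' have a missing-genotype fraction below the given threshold.
#'
#' @param geno A [genotype_dataset()].
#' @param test_marker Id of the test marker.
#' @param max_missing_fraction Maximum tolerated missing fraction
#'   (default 0.1).
#' @return Character vector of eligible marker ids.
#' @export
screen_control_candidates <- function(geno, test_marker,
                                      max_missing_fraction = 0.1) {
  stopifnot(inherits(geno, "genotype_dataset"))
  map <- geno$map
  if (!test_marker %in% map$marker)
    stop("test marker not found in dataset: ", test_marker)
  test_chrom <- map$chrom[map$marker == test_marker][1]
  missing_frac <- rowMeans(is.na(geno$geno))
  ok <- map$autosome &
    map$chrom != test_chrom &
    map$marker != test_marker &
    missing_frac[map$marker] < max_missing_fraction
  ids <- map$marker[ok]
  if (length(ids) == 0)
    stop("no eligible control markers after screening")
  ids
}

#' Select the control marker with the strongest structure signal
#'
#' For each candidate computes the Hardy-Weinberg-expected genotypic
#' variance `2 p(1-p)` (with `p` the sample allele frequency), the observed
#' sample variance (n - 1 denominator), and their difference `delta`; the
#' chosen control marker is the one maximizing `delta`. Ties break
#' deterministically toward the lowest chromosome, then position, then id.
#'
#' @param zmat Candidate genotype matrix, markers in rows, individuals in
#'   columns (0/1/2, NA allowed), rownames = marker ids.
#' @param map Optional map tibble (`marker`, `chrom`, `pos`) used for
#'   tie-breaking.
#' @return A one-row tibble (the choice) with attribute `"candidates"`
#'   holding the full ranked table: `marker`, `var_expected`,
#'   `var_observed`, `delta`, `freq`, `missing_frac`.
#' @export
select_control_marker <- function(zmat, map = NULL) {
  if (is.vector(zmat)) zmat <- matrix(zmat, nrow = 1,
                                      dimnames = list("candidate", NULL))
  if (nrow(zmat) < 1) stop("no control-marker candidates supplied")
  if (is.null(rownames(zmat))) rownames(zmat) <- paste0("m", seq_len(nrow(zmat)))
  stats_one <- function(z) {
    z <- z[!is.na(z)]
    nz <- length(z)
    p <- mean(z) / 2
    var_exp <- 2 * p * (1 - p)
    var_obs <- if (nz > 1) stats::var(z) else NA_real_
    c(var_exp, var_obs, var_obs - var_exp, p)
  }
  st <- t(apply(zmat, 1, stats_one))
  out <- tibble::tibble(
    marker = rownames(zmat),
    var_expected = unname(st[, 1]),
    var_observed = unname(st[, 2]),
    delta = unname(st[, 3]),
    freq = unname(st[, 4]),
    missing_frac = unname(rowMeans(is.na(zmat))))
  if (!is.null(map)) {
    idx <- match(out$marker, map$marker)
    out$chrom <- map$chrom[idx]
    out$pos <- map$pos[idx]
    ord <- order(-out$delta, chrom_rank(out$chrom), out$pos, out$marker)
  } else {
    ord <- order(-out$delta, out$marker)
  }
  out <- out[ord, ]
  choice <- out[1, ]
  attr(choice, "candidates") <- out
  choice
}

# numeric rank for chromosome labels ("chr10", "X", "7", ...): autosomes by
# number, then X, Y, MT, then anything else alphabetically
chrom_rank <- function(chrom) {
  lab <- sub("^[Cc]hr", "", as.character(chrom))
  num <- suppressWarnings(as.numeric(lab))
  rank <- ifelse(!is.na(num), num,
                 ifelse(lab %in% c("X", "x"), 100,
                        ifelse(lab %in% c("Y", "y"), 101,
                               ifelse(lab %in% c("MT", "M", "mt"), 102, 200))))
  rank + as.numeric(factor(lab)) * 1e-6   # stable among unknown labels
}
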