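# Forward simulation of admixed samples with the exact statistical
# structure assumed by the theory: two randomly mating subpopulations,
# haplotype-level LD between test marker and QTL, an unlinked control
# marker, and a normally distributed trait driven by one biallelic QTL.

#' Simulate an admixed sample of genotypes and phenotypes
#'
#' Each individual's subpopulation of origin is Bernoulli(`m`); its joint
#' (QTL, test-marker) genotype is drawn from the two-locus genotype
#' distribution of that subpopulation (gametes carry allele A with
#' probability `q_i` and, given the QTL allele, marker allele T with
#' probability `Q_i` or `R_i`); the control-marker genotype is Binomial(2,
#' `c_i`) independently of both; and the trait is the QTL genotypic value
#' plus Normal(0, `sigma2`) noise.
#'
#' @param spec An [admixture_spec()].
#' @param n Number of individuals (>= 0).
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @return An object of class `admix_sample`: list with vectors `x`
#'   (test-marker counts), `z` (control-marker counts), `y` (trait),
#'   `qtl` (latent QTL allele counts, for validation only), `true_label`
#'   (1/2) and `membership_prob` (probability of membership to
#'   subpopulation 1, initialized to the truth).
#' @examples
#' sp <- admixture_spec(0.5,
#'                      subpop_model(q = 0.8, p = 0.8, c = 0.8),
#'                      subpop_model(q = 0.2, p = 0.2, c = 0.2))
#' s <- simulate_admixed_sample(sp, n = 100, seed = 1)
#' @export
simulate_admixed_sample <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "admixture_spec"))
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n != round(n))
    stop("n must be a nonnegative integer")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  if (n == 0) {
    return(structure(list(x = integer(0), z = integer(0), y = numeric(0),
                          qtl = integer(0), true_label = integer(0),
                          membership_prob = numeric(0), spec = spec),
                     class = "admix_sample"))
  }
  pop <- ifelse(stats::runif(n) < spec$m, 1L, 2L)
  qv <- c(spec$subpop1$q, spec$subpop2$q)[pop]
  Qv <- c(spec$subpop1$pair$Q, spec$subpop2$pair$Q)[pop]
  Rv <- c(spec$subpop1$pair$R, spec$subpop2$pair$R)[pop]
  cv <- c(spec$subpop1$c, spec$subpop2$c)[pop]
  # two gametes per individual, haplotype-level LD
  a1 <- stats::rbinom(n, 1, qv); a2 <- stats::rbinom(n, 1, qv)
  t1 <- stats::rbinom(n, 1, ifelse(a1 == 1, Qv, Rv))
  t2 <- stats::rbinom(n, 1, ifelse(a2 == 1, Qv, Rv))
  g <- a1 + a2
  x <- t1 + t2
  z <- stats::rbinom(n, 2, cv)
  eff <- spec$effects
  gval <- c(-eff$d, eff$h, eff$d)[g + 1L]
  y <- eff$mu + gval + stats::rnorm(n, 0, sqrt(eff$sigma2))
  structure(list(x = as.integer(x), z = as.integer(z), y = y,
                 qtl = as.integer(g), true_label = pop,
                 membership_prob = as.numeric(pop == 1L), spec = spec),
            class = "admix_sample")
}

#' @export
print.admix_sample <- function(x, ...) {
  cat(sprintf("admix_sample: n = %d (subpop 1: %d, subpop 2: %d)\n",
              length(x$x), sum(x$true_label == 1L), sum(x$true_label == 2L)))
  invisible(x)
}

#' Simulate a multilocus marker panel as a Markov chain along haplotypes
#'
#' Genotypes at `L` loci in one randomly mating population. Haplotypes are
#' generated locus by locus: the first allele from its marginal frequency,
#' each subsequent allele from the conditional distribution implied by the
#' two-locus haplotype table of adjacent loci (so adjacent LD is controlled
#' exactly, and non-adjacent LD decays as the product of adjacent
#' dependences). An individual's genotype is the sum of two independent
#' haplotypes.
#'
#' @param p Vector of allele frequencies, one per locus, each in (0, 1).
#' @param D Vector of adjacent-locus LD coefficients, length `length(p) - 1`
#'   (may be zero-length for a single locus). Each checked against the
#'   Lewontin bounds of its flanking frequencies.
#' @param n Number of individuals.
#' @param seed Optional integer seed.
#' @return Integer matrix of allele counts, markers in rows, individuals in
#'   columns.
#' @export
simulate_marker_panel <- function(p, D = numeric(length(p) - 1), n,
                                  seed = NULL) {
  L <- length(p)
  stopifnot(L >= 1, all(p > 0), all(p < 1))
  if (length(D) != L - 1)
    stop("adjacent LD list must have length(p) - 1 entries")
  for (k in seq_along(D)) {
    bd <- lewontin_bounds(p[k], p[k + 1])
    if (D[k] < bd[1] - 1e-12 || D[k] > bd[2] + 1e-12)
      stop(sprintf("adjacent D[%d] = %g outside Lewontin bounds [%g, %g]",
                   k, D[k], bd[1], bd[2]))
  }
  if (!is.null(seed)) set.seed(seed)
  hap <- function() {
    h <- matrix(0L, nrow = L, ncol = n)
    h[1, ] <- stats::rbinom(n, 1, p[1])
    for (k in seq_len(L - 1)) {
      # P(next = 1 | cur) from the two-locus haplotype frequencies
      p11 <- p[k] * p[k + 1] + D[k]
      cond1 <- p11 / p[k]
      cond0 <- (p[k + 1] - p11) / (1 - p[k])
      h[k + 1, ] <- stats::rbinom(n, 1, ifelse(h[k, ] == 1L, cond1, cond0))
    }
    h
  }
  out <- hap() + hap()
  rownames(out) <- paste0("m", seq_len(L))
  storage.mode(out) <- "integer"
  out
}

#' Corrupt true subpopulation membership assignments
#'
#' Keeps a fraction `1 - fraction_random` of individuals at their true
#' membership (probability 1 or 0 of belonging to subpopulation 1) and
#' reassigns the remaining individuals to either subpopulation with
#' probability 1/2, emulating partially incorrect ancestry information fed
#' to the membership-covariate regression.
#'
#' @param true_label Integer vector of true subpopulations (1 or 2).
#' @param fraction_random Fraction of individuals randomly reassigned,
#'   in \[0, 1\].
#' @param seed Optional integer seed.
#' @return Numeric vector of assigned membership probabilities (0 or 1).
#' @export
corrupt_membership <- function(true_label, fraction_random, seed = NULL) {
  stopifnot(all(true_label %in% c(1L, 2L)),
            fraction_random >= 0, fraction_random <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(true_label)
  prob <- as.numeric(true_label == 1L)
  corrupt <- stats::runif(n) < fraction_random
  prob[corrupt] <- as.numeric(stats::runif(sum(corrupt)) < 0.5)
  prob
}

#' Replicate simulation study of the three association analyses
#'
#' Simulates `n_reps` independent admixed samples under `spec`, analyzes
#' each with the requested methods, and summarizes the fitted regression
#' coefficients and the proportion of replicates significant at `alpha`.
#' Under a null scenario (no within-subpopulation LD) that proportion is
#' the empirical type-I error; under a non-null scenario it is the
#' empirical power.
#'
#' @param spec An [admixture_spec()].
#' @param n Sample size per replicate.
#' @param n_reps Number of replicates (>= 1).
#' @param alpha Two-sided significance level.
#' @param methods Subset of `c("corrected", "simple", "structured")`.
#' @param control Control-marker policy for the corrected analysis:
#'   `"given"` uses the simulated control marker.
#' @param membership_error Fraction of individuals whose membership is
#'   randomized before the membership-covariate regression (see
#'   [corrupt_membership()]).
#' @param seed Integer seed for the study; replicates use seeds split from
#'   it by counter so studies are reproducible.
#' @return A tibble with one row per method: `method`, `n_reps`,
#'   `n_failed`, `mean_b`, `se_b` (standard error of the mean coefficient
#'   over replicates) and `prop_significant`.
#' @export
run_replicate_study <- function(spec, n, n_reps, alpha = 0.05,
                                methods = c("corrected", "simple",
                                            "structured"),
                                control = "given",
                                membership_error = 0,
                                seed = 1L) {
  stopifnot(n_reps >= 1)
  methods <- match.arg(methods, c("corrected", "simple", "structured"),
                       several.ok = TRUE)
  control <- match.arg(control, "given")
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  b <- matrix(NA_real_, n_reps, length(methods),
              dimnames = list(NULL, methods))
  sig <- matrix(NA, n_reps, length(methods), dimnames = list(NULL, methods))
  for (r in seq_len(n_reps)) {
    s <- simulate_admixed_sample(spec, n, seed = rep_seeds[r])
    memb <- if (membership_error > 0)
      corrupt_membership(s$true_label, membership_error)
    else s$membership_prob
    for (mth in methods) {
      fit <- tryCatch(switch(mth,
        corrected  = fit_corrected(s$x, s$z, s$y),
        simple     = fit_simple(s$x, s$y),
        structured = fit_structured(s$x, memb, s$y)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        b[r, mth] <- fit$b
        sig[r, mth] <- fit$p < alpha
      }
    }
  }
  tibble::tibble(
    method = methods,
    n_reps = n_reps,
    n_failed = colSums(is.na(b))[methods],
    mean_b = colMeans(b, na.rm = TRUE)[methods],
    se_b = apply(b, 2, function(v) {
      v <- v[!is.na(v)]
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    })[methods],
    prop_significant = colMeans(sig, na.rm = TRUE)[methods]
  )
}
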