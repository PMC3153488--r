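# Exact population-genetic theory: joint distributions, mixture moments,
# the genuine/spurious decomposition, and power prediction.

test_that("joint genotype distribution reproduces hand-computed cells and the gamete-enumeration oracle", {
  # independence: all four double homozygotes equal
  tab <- joint_genotype_distribution(locus_pair(q = 0.5, p = 0.5, D = 0))
  expect_equal(tab["AA", "TT"], 0.0625)
  expect_equal(unname(c(tab["AA", "TT"], tab["AA", "tt"],
                        tab["aa", "TT"], tab["aa", "tt"])),
               rep(0.0625, 4))

  # complete association: Q = 1 forces the AA,Tt cell to zero
  tab <- joint_genotype_distribution(locus_pair(q = 0.5, p = 0.5, D = 0.25))
  expect_equal(tab["AA", "TT"], 0.25)
  expect_equal(tab["AA", "Tt"], 0)

  # sums, marginals and allele-count covariance against the oracle
  tab <- joint_genotype_distribution(locus_pair(q = 0.3, p = 0.6, D = 0.05))
  expect_equal(sum(tab), 1)
  xc <- matrix(rep(2:0, times = 3), 3, 3, byrow = TRUE)  # marker counts (columns)
  gc <- matrix(rep(2:0, each = 3), 3, 3, byrow = TRUE)   # QTL counts (rows)
  cov_counts <- sum(tab * xc * gc) - sum(tab * xc) * sum(tab * gc)
  expect_equal(cov_counts, 0.10, tolerance = 1e-12)

  set.seed(71)
  for (rep in 1:50) {
    q <- runif(1, 0.1, 0.9); p <- runif(1, 0.1, 0.9)
    bd <- lewontin_bounds(p, q)
    D <- runif(1, 0.9 * bd[1], 0.9 * bd[2])
    tab <- joint_genotype_distribution(locus_pair(q, p, D))
    expect_equal(unname(tab), unname(oracle_joint_distribution(q, p, D)),
                 tolerance = 1e-12)
    expect_true(all(tab >= -1e-15))
    expect_equal(sum(tab * xc), 2 * p, tolerance = 1e-12)
    expect_equal(sum(tab * xc * gc) - sum(tab * xc) * sum(tab * gc), 2 * D,
                 tolerance = 1e-12)
  }
})

test_that("LD coefficients outside the Lewontin bounds are rejected with the violated bound named", {
  expect_error(locus_pair(q = 0.5, p = 0.5, D = 0.3), "Lewontin")
  expect_error(locus_pair(q = 0.1, p = 0.1, D = -0.5), "Lewontin")
  expect_error(locus_pair(q = 0, p = 0.5, D = 0), "frequency")
})

test_that("mixture LD combines within-subpopulation LD and frequency divergence", {
  # single population: mixture LD is just D1
  sp1 <- subpop_model(q = 0.3, p = 0.6, c = 0.5, D = 0.05)
  sp2 <- subpop_model(q = 0.5, p = 0.5, c = 0.5, D = 0)
  expect_equal(mixture_ld(admixture_spec(1, sp1, sp2)), 0.05)

  # pure divergence: 0.25 * 0.4 * 0.4 = 0.04
  spec <- admixture_spec(0.5,
                         subpop_model(q = 0.7, p = 0.7, c = 0.5, D = 0),
                         subpop_model(q = 0.3, p = 0.3, c = 0.5, D = 0))
  expect_equal(mixture_ld(spec), 0.04)

  set.seed(72)
  for (rep in 1:30) {
    spec <- random_spec()
    expect_equal(mixture_ld(spec), oracle_mixture_ld(spec), tolerance = 1e-12)
  }
})

test_that("marker-trait covariance decomposes exactly into genuine and spurious parts", {
  # identical subpopulations: no spurious term
  sp <- subpop_model(q = 0.4, p = 0.6, c = 0.5, D = 0.05)
  cd <- mixture_covariance(admixture_spec(0.5, sp, sp))
  expect_equal(cd$spurious, 0)

  # no within-subpopulation LD: association is pure confounding
  spec0 <- admixture_spec(0.5,
                          subpop_model(q = 0.8, p = 0.8, c = 0.8, D = 0),
                          subpop_model(q = 0.2, p = 0.2, c = 0.2, D = 0))
  cd0 <- mixture_covariance(spec0)
  expect_equal(cd0$genuine, 0)
  expect_equal(cd0$total, cd0$spurious)
  expect_equal(cd0$spurious, 2 * 0.25 * 0.6 * 1.2)   # = 0.36

  set.seed(73)
  for (rep in 1:30) {
    spec <- random_spec()
    cd <- mixture_covariance(spec)
    om <- oracle_mixture_moments(spec)
    expect_equal(cd$total, cd$genuine + cd$spurious, tolerance = 1e-14)
    expect_equal(cd$total, om$cov_xy, tolerance = 1e-12)
    expect_equal(cd$genuine,
                 spec$m * om$within_cov_xy[1] +
                   (1 - spec$m) * om$within_cov_xy[2],
                 tolerance = 1e-12)
  }
})

test_that("control-marker variance inflation equals the mixture-moment excess and is nonnegative", {
  expect_equal(structure_variance_inflation(0.5, 0.4, 0.4)$delta, 0)
  expect_equal(structure_variance_inflation(0.5, 0.9, 0.1)$delta, 0.32)
  expect_equal(structure_variance_inflation(0.3, 0.8, 0.2)$delta, 0.1512)

  set.seed(74)
  for (rep in 1:1000) {
    m <- runif(1, 0.05, 0.95)
    c1 <- runif(1, 0.05, 0.95); c2 <- runif(1, 0.05, 0.95)
    svi <- structure_variance_inflation(m, c1, c2)
    expect_gte(svi$delta, 0)
    expect_equal(svi$delta, 2 * m * (1 - m) * (c1 - c2)^2, tolerance = 1e-14)
    # enumeration: variance of a mixture of two Binomial(2, c_i)
    ez <- 2 * (m * c1 + (1 - m) * c2)
    ez2 <- m * (2 * c1 * (1 - c1) + (2 * c1)^2) +
      (1 - m) * (2 * c2 * (1 - c2) + (2 * c2)^2)
    expect_equal(svi$var_observed, ez2 - ez^2, tolerance = 1e-12)
  }
})

test_that("theoretical coefficients match enumeration and the corrected one nulls out confounding", {
  # single population: b = 2 D d / (2 p (1 - p)) = 1
  sp <- subpop_model(q = 0.5, p = 0.5, c = 0.5, D = 0.25)
  spec1 <- admixture_spec(1, sp, subpop_model(q = 0.5, p = 0.5, c = 0.4))
  expect_equal(theoretical_coefficient(spec1, "simple"), 1)

  set.seed(75)
  for (rep in 1:25) {
    spec <- random_spec(zero_ld = TRUE)
    expect_equal(theoretical_coefficient(spec, "corrected"), 0,
                 tolerance = 1e-12)
    expect_equal(theoretical_coefficient(spec, "structured"), 0,
                 tolerance = 1e-12)
  }
  for (rep in 1:25) {
    spec <- random_spec()
    om <- oracle_mixture_moments(spec)
    expect_equal(theoretical_coefficient(spec, "simple"),
                 om$cov_xy / om$var_x, tolerance = 1e-12)
    genuine <- spec$m * om$within_cov_xy[1] +
      (1 - spec$m) * om$within_cov_xy[2]
    expect_equal(theoretical_coefficient(spec, "corrected"),
                 genuine / om$var_x, tolerance = 1e-12)
  }
})

test_that("the corrected coefficient does not depend on which divergent control marker is used", {
  set.seed(76)
  for (rep in 1:20) {
    spec <- random_spec()
    alt <- spec
    alt$subpop1 <- subpop_model(q = spec$subpop1$q, p = spec$subpop1$p,
                                c = 0.85, D = spec$subpop1$D)
    alt$subpop2 <- subpop_model(q = spec$subpop2$q, p = spec$subpop2$p,
                                c = 0.35, D = spec$subpop2$D)
    expect_equal(theoretical_coefficient(spec, "corrected"),
                 theoretical_coefficient(alt, "corrected"),
                 tolerance = 1e-12)
  }
  # equal control frequencies cannot correct structure
  spec <- admixture_spec(0.5,
                         subpop_model(q = 0.8, p = 0.8, c = 0.5, D = 0),
                         subpop_model(q = 0.2, p = 0.2, c = 0.5, D = 0))
  expect_error(theoretical_coefficient(spec, "corrected"), "uncorrectable")
})

test_that("power prediction is alpha at the null, monotone, and approaches 1", {
  for (alpha in c(0.01, 0.05, 0.2)) {
    pp <- predict_power(b = 0, var_x = 0.5, sigma2_resid = 1, n = 100,
                        alpha = alpha)
    expect_equal(pp$power, alpha, tolerance = 1e-10)
  }
  bs <- seq(0, 1, by = 0.1)
  pw <- vapply(bs, function(b)
    predict_power(b, 0.5, 1, 200, 0.05)$power, 0)
  expect_true(all(diff(pw) > 0))
  expect_true(all(pw >= 0.05 - 1e-12))
  ns <- c(10, 50, 200, 1000, 5000)
  pw_n <- vapply(ns, function(n)
    predict_power(0.3, 0.5, 1, n, 0.05)$power, 0)
  expect_true(all(diff(pw_n) > 0))
  expect_gt(pw_n[length(pw_n)], 0.999)
  expect_error(predict_power(0.3, 0.5, 1, n = 3, 0.05), "n > 3")

  # the small-sample gamma factor shrinks the noncentrality slightly and
  # vanishes asymptotically
  pg <- predict_power(0.3, 0.5, 1, 30, 0.05, ncp_form = "gamma")
  pa <- predict_power(0.3, 0.5, 1, 30, 0.05, ncp_form = "asymptotic")
  expect_lt(pg$ncp, pa$ncp)
  pg2 <- predict_power(0.3, 0.5, 1, 5000, 0.05, ncp_form = "gamma")
  pa2 <- predict_power(0.3, 0.5, 1, 5000, 0.05, ncp_form = "asymptotic")
  expect_equal(pg2$ncp / pa2$ncp, 1, tolerance = 1e-3)
})

test_that("the influence-function variance of the corrected slope matches large-sample Monte Carlo", {
  scens <- default_scenarios()
  spec <- scens$ld_strong_struct$spec
  n <- 4000
  set.seed(77)
  bs <- replicate(80, {
    s <- simulate_admixed_sample(spec, n)
    fit_corrected(s$x, s$z, s$y)$b
  })
  sd_theory <- sqrt(cmassoc:::corrected_slope_if_variance(spec) / n)
  # 80 replicates: sd estimate has ~8% relative error; allow 3 of those
  expect_equal(sd(bs), sd_theory, tolerance = 0.25)
})
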