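test_that("GRM matches hand-computed VanRaden method 1 on a 2x2 example", {
  # s1 = (0,0), s2 = (2,2): p = (0.5, 0.5), scale = 1, Z = +-1
  g <- makeGeno(rbind(s1 = c(0L, 0L), s2 = c(2L, 2L)))
  G <- buildGrm(g, ridge = 0)
  expect_equal(unname(G), rbind(c(2, -2), c(-2, 2)), tolerance = 1e-12)
  # duplicate individuals: off-diagonal equals the diagonals (up to ridge)
  g2 <- makeGeno(rbind(a = c(0L, 1L, 2L), b = c(0L, 1L, 2L),
                       c = c(2L, 1L, 0L)))
  G2 <- buildGrm(g2, ridge = 0)
  expect_equal(G2["a", "b"], G2["a", "a"], tolerance = 1e-12)
  expect_equal(G2, t(G2))
  # monomorphic marker is refused
  expect_error(buildGrm(makeGeno(cbind(c(0L, 0L), c(0L, 2L)))),
               "monomorphic")
})

test_that("GRM diagonal mean tracks 1 + mean inbreeding on simulated data", {
  sim <- midSim()
  G <- sim$grm
  fs <- fSnp(sim$sim$genotypes)
  expect_equal(mean(diag(G)), 1 + mean(fs), tolerance = 0.05)
})

test_that("REML equals closed-form ANOVA estimators on a balanced G = I design", {
  set.seed(11)
  q <- 40; m <- 6
  sa <- 1.2; sp <- 0.8; se <- 2.0
  bulls <- sprintf("b%02d", 1:q)
  u <- rnorm(q, 0, sqrt(sa + sp))     # bull effect (a + pe, G = I)
  y <- rep(u, each = m) + rnorm(q * m, 0, sqrt(se))
  ph <- makePheno(bulls, rep(m, q), y)
  G <- diag(q); dimnames(G) <- list(bulls, bulls)
  fit <- fitAnimalModel(ph, G, includeAge = FALSE)
  # one-way ANOVA oracle
  ybar <- tapply(y, rep(bulls, each = m), mean)
  msb <- m * sum((ybar - mean(y))^2) / (q - 1)
  mse <- sum((y - rep(ybar[bulls], each = m))^2) / (q * (m - 1))
  vc <- varComp(fit)
  expect_equal(unname(vc["sigma_e2"]), mse, tolerance = 1e-4)
  # sigma_a2 and sigma_pe2 are only jointly identified when G = I
  expect_equal(unname(vc["sigma_a2"] + vc["sigma_pe2"]),
               (msb - mse) / m, tolerance = 1e-4)
  expect_equal(unname(coefTable(fit)$estimate[1]), mean(y),
               tolerance = 1e-6)
})

test_that("VC at the boundary degenerate to OLS when there is no bull variance", {
  set.seed(12)
  q <- 30; m <- 5
  y <- rnorm(q * m)
  ph <- makePheno(sprintf("b%02d", 1:q), rep(m, q), y)
  G <- diag(q); dimnames(G) <- list(unique(ph$bull_id), unique(ph$bull_id))
  fit <- fitAnimalModel(ph, G, includeAge = FALSE)
  vc <- varComp(fit)
  expect_lt(unname(vc["sigma_a2"] + vc["sigma_pe2"]), 0.05)
  expect_equal(unname(coefTable(fit)$estimate[1]), mean(y),
               tolerance = 1e-3)
})

test_that("GLS solution at fixed VC equals a dense oracle on a small instance", {
  set.seed(13)
  q <- 12; n <- 40
  bulls <- sprintf("b%02d", 1:q)
  bidx <- sample.int(q, n, replace = TRUE)
  bidx[1:q] <- 1:q  # every bull observed
  A <- matrix(rnorm(q * q), q); G <- crossprod(A) / q + diag(q) * 0.1
  dimnames(G) <- list(bulls, bulls)
  age <- runif(n, 20, 100)
  y <- rnorm(n)
  ph <- makePheno(bulls[bidx], rep(1, n), y, age = age,
                  ys = sample(c("y1", "y2"), n, TRUE))
  vcf <- c(0.7, 0.4, 1.3)
  fit <- fitAnimalModel(ph, G, priors = vcf, maxIter = 1L,
                        tolVc = 1e10, tolLl = 1e10)
  # oracle at the same (converged-in-zero-steps) VC
  vc <- varComp(fit)
  X <- cbind(1, as.numeric(ph$year_season == "y2"), age)
  or <- denseGls(y, X, bidx, G, unname(vc))
  expect_equal(unname(coefTable(fit)$estimate), or$beta,
               tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(unname(coefTable(fit)$se), sqrt(diag(or$cov)),
               tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("REML log-likelihood is monotone over accepted iterations", {
  sim <- midSim()
  fit <- fitAnimalModel(sim$ph, sim$grm)
  expect_true(isConverged(fit))
  tr <- remlTrajectory(fit)
  expect_gt(nrow(tr), 1)
  expect_true(all(diff(tr$loglik) >= -1e-7))
  # deliberately poor starting values still converge monotonically
  fit2 <- fitAnimalModel(sim$ph, sim$grm,
                         priors = c(10, 0.01, 0.01) * var(sim$ph$value))
  expect_true(all(diff(remlTrajectory(fit2)$loglik) >= -1e-7))
  expect_equal(unname(varComp(fit2)), unname(varComp(fit)),
               tolerance = 1e-3)
})

test_that("model 1 recovers an injected genome-wide depression slope", {
  sim <- midSim()
  g <- sim$sim$genotypes
  tab <- inbreedingTable(g)
  fr <- setNames(tab$f_roh, tab$sample_id)
  fit <- fitAnimalModel(sim$ph, sim$grm, inbreeding = fr)
  co <- coefTable(fit)
  b2 <- co[co$term == "f", ]
  expect_lt(abs(b2$estimate - sim$cfg$b2True), 2 * b2$se)
  expect_gt(b2$se, 0)
})

test_that("model 2 reports NA for a zero-variance class and collapses to model 1", {
  set.seed(14)
  q <- 25; m <- 4
  bulls <- sprintf("b%02d", 1:q)
  fcls <- cbind(f1 = runif(q, 0, 0.1), f2 = 0, f3 = 0, f4 = 0, f5 = 0)
  rownames(fcls) <- bulls
  u <- rnorm(q, 0, 1)
  y <- rep(u, each = m) - 8 * rep(fcls[, "f1"], each = m) +
    rnorm(q * m, 0, 1.5)
  ph <- makePheno(bulls, rep(m, q), y)
  G <- diag(q); dimnames(G) <- list(bulls, bulls)
  expect_warning(fit <- fitRohClassModel(ph, G, fcls, includeAge = FALSE),
                 "collinear")
  co <- coefTable(fit)
  expect_true(all(is.na(co$estimate[co$term %in% c("f2", "f3", "f4",
                                                   "f5")])))
  expect_false(is.na(co$estimate[co$term == "f1"]))
  # a single nonzero class reproduces the model-1 fit on that covariate
  single <- fitAnimalModel(ph, G, inbreeding = setNames(fcls[, "f1"],
                                                        bulls),
                           includeAge = FALSE)  # same estimable design
  expect_equal(co$estimate[co$term == "f1"],
               coefTable(single)$estimate[coefTable(single)$term == "f"],
               tolerance = 1e-5)
})

test_that("heritability and repeatability follow the footnote formulas", {
  hr <- heritabilityRepeatability(c(sigma_a2 = 1, sigma_pe2 = 1,
                                    sigma_e2 = 2))
  expect_equal(unname(hr), c(0.25, 0.5))
  expect_equal(unname(heritabilityRepeatability(
    c(sigma_a2 = 0, sigma_pe2 = 3, sigma_e2 = 1))["h2"]), 0)
  set.seed(15)
  for (k in 1:20) {
    vc <- setNames(runif(3, 0.01, 5), c("sigma_a2", "sigma_pe2",
                                        "sigma_e2"))
    hr <- heritabilityRepeatability(vc)
    expect_true(hr["h2"] >= 0 && hr["h2"] <= hr["r"] && hr["r"] <= 1)
  }
  expect_error(heritabilityRepeatability(
    c(sigma_a2 = 0, sigma_pe2 = 0, sigma_e2 = 0)), "positive")
})

test_that("REML recovers variance components across seeded replicates", {
  # parameter recovery at small scale: bias of b2-hat small relative to
  # its SE; reported SE consistent with the empirical spread
  set.seed(16)
  ests <- ses <- numeric(10)
  for (k in 1:10) {
    q <- 50; m <- 5
    bulls <- sprintf("b%02d", 1:q)
    fr <- runif(q, 0, 0.3); names(fr) <- bulls
    u <- rnorm(q, 0, sqrt(1.5))
    y <- rep(u, each = m) - 5 * rep(fr, each = m) + rnorm(q * m, 0, 2)
    ph <- makePheno(bulls, rep(m, q), y)
    G <- diag(q); dimnames(G) <- list(bulls, bulls)
    fit <- fitAnimalModel(ph, G, inbreeding = fr, includeAge = FALSE)
    co <- coefTable(fit)
    ests[k] <- co$estimate[co$term == "f"]
    ses[k] <- co$se[co$term == "f"]
  }
  expect_lt(abs(mean(ests) - (-5)), 2 * sd(ests) / sqrt(10))
  expect_lt(abs(sd(ests) / mean(ses) - 1), 0.5)
})
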