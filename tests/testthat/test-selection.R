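test_that("one-way ANOVA F matches hand computation and the t-squared
           identity", {
  out <- anova_f(list(c(1, 2), c(3, 4)))
  expect_equal(out$F, 8)                    # SSB = 4 (df 1), SSW = 1 (df 2)
  expect_equal(out$df1, 1)
  expect_equal(out$df2, 2)
  expect_equal(anova_f(list(c(1, 3), c(2, 2)))$F, 0)
  # two-group F equals the squared pooled-variance t statistic
  with_seed(61, for (i in 1:10) {
    a <- rnorm(7); b <- rnorm(5, mean = 1)
    f <- anova_f(list(a, b))
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(f$F, unname(tt$statistic)^2, tolerance = 1e-12)
    expect_equal(f$p, tt$p.value, tolerance = 1e-12)
  })
  # degenerate inputs
  expect_true(is.infinite(anova_f(list(c(1, 1), c(2, 2)))$F))
  expect_equal(anova_f(list(c(1, 1), c(2, 2)))$p, 0)
  expect_true(is.na(anova_f(list(c(5, 5), c(5, 5)))$F))
  expect_error(anova_f(list(1:3)), "two groups")
  expect_error(anova_f(list(1:3, numeric(0))), "empty group")
})

test_that("F is scale invariant and the vectorized path agrees with aov", {
  x <- with_seed(62, matrix(rnorm(60), 12, 5,
                            dimnames = list(NULL, paste0("g", 1:5))))
  g <- rep(1:3, each = 4)
  tab <- phasesom:::.anova_f_matrix(x, g)
  tab2 <- phasesom:::.anova_f_matrix(x * 3.7, g)
  expect_equal(tab$F, tab2$F, tolerance = 1e-10)
  # independent oracle: stats::aov per probe
  for (j in 1:5) {
    ref <- summary(aov(x[, j] ~ factor(g)))[[1]]
    expect_equal(tab$F[j], ref[["F value"]][1], tolerance = 1e-10)
    expect_equal(tab$p[j], ref[["Pr(>F)"]][1], tolerance = 1e-10)
  }
})

test_that("Benjamini-Hochberg step-up matches the exhaustive-threshold
           oracle for small m", {
  with_seed(63, for (i in 1:40) {
    m <- sample(1:10, 1)
    p <- round(runif(m), 3)
    alpha <- sample(c(0.01, 0.05, 0.1), 1)
    out <- benjamini_hochberg(p, alpha)
    expect_identical(out$reject, oracle_bh_reject(p, alpha))
    expect_equal(out$q, p.adjust(p, "BH"))
    expect_true(all(out$q >= p - 1e-15))
  })
  # worked example: the largest k with p_(k) <= k alpha / m is k = 4
  out <- benjamini_hochberg(c(0.001, 0.008, 0.039, 0.041), 0.05)
  expect_identical(out$reject, rep(TRUE, 4))
  # null input, single p, bad input
  expect_identical(benjamini_hochberg(rep(1, 5), 0.05)$reject, rep(FALSE, 5))
  expect_equal(benjamini_hochberg(rep(1, 5), 0.05)$q, rep(1, 5))
  expect_identical(benjamini_hochberg(0.04, 0.05)$reject, TRUE)
  expect_identical(benjamini_hochberg(0.06, 0.05)$reject, FALSE)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("per-phase selection rejects planted markers and excludes constant
           probes", {
  n <- 24; P <- 400
  g <- rep(1:4, each = 6)
  x <- with_seed(64, {
    x <- matrix(rnorm(n * P), n, P, dimnames = list(NULL, sprintf("p%03d", 1:P)))
    for (j in 1:5) x[, j] <- x[, j] + 3 * c(-1, 1, -1, 1)[g] * (j %% 2 * 2 - 1)
    x[, 400] <- 2  # constant probe
    x
  })
  out <- select_per_phase(expression_matrix(x), g, alpha = 0.01)
  expect_true(all(sprintf("p%03d", 1:5) %in% out$significant))
  expect_identical(out$excluded, "p400")
  expect_false("p400" %in% out$significant)
  # false-discovery proportion among rejections stays near the FDR level
  expect_lte(length(setdiff(out$significant, sprintf("p%03d", 1:5))) /
               max(1, length(out$significant)), 0.05)
  expect_error(select_per_phase(expression_matrix(x), rep(1, n)),
               "two super-clusters")
  expect_error(select_per_phase(expression_matrix(x), g[1:5]), "every sample")
})

test_that("cross-phase intersection keeps only probes significant in all
           phases", {
  out <- intersect_phases(list(A = c("b", "a", "c"), SA = c("c", "a"),
                               C = c("a", "d", "c")))
  expect_identical(out$final_set, c("a", "c"))
  expect_warning(intersect_phases(list(A = "a", SA = "b", C = "c")),
                 "no probe")
  expect_error(intersect_phases(list(A = "a", SA = "b")), "three")
})

test_that("under a global null the three-phase intersection is essentially
           empty", {
  # 50 seeds, no planted effects; expected per-phase BH rejections are near
  # zero at alpha 0.01 and the intersection should be far below alpha
  n_fp <- with_seed(65, vapply(1:50, function(i) {
    g <- rep(1:4, times = c(6, 5, 2, 7))
    sets <- lapply(1:3, function(ph) {
      x <- matrix(rnorm(20 * 200), 20, 200,
                  dimnames = list(NULL, sprintf("p%03d", 1:200)))
      select_per_phase(expression_matrix(x), g, alpha = 0.01)$significant
    })
    length(suppressWarnings(
      intersect_phases(setNames(sets, c("A", "SA", "C")))$final_set))
  }, 0))
  expect_lte(mean(n_fp), 0.01)
  expect_equal(median(n_fp), 0)
})
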