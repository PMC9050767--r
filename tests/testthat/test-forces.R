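test_that("the expected ENC curve has its known values and symmetry", {
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(0), 31)
  expect_equal(enc_expected(1), 32)
  s <- seq(0, 1, by = 0.05)
  # the 29/(s^2+(1-s)^2) term is symmetric about 0.5; only the +s term is not
  expect_equal(enc_expected(s) - s, enc_expected(1 - s) - (1 - s))
  expect_error(enc_expected(1.2))
})

test_that("genes are classified against the expected ENC curve with a band", {
  idx <- data.frame(gene_id = c("on", "above", "below", "edge"),
                    GC3 = c(50, 50, 50, 50),
                    ENC = c(60.5, 61.0 + 0.51, 55, 59.5))
  tab <- enc_plot_table(idx, tol = 1)
  expect_identical(as.character(tab$position),
                   c("on", "above", "below", "on"))
  expect_equal(tab$ENC_expected, rep(60.5, 4))
  expect_equal(as.integer(attr(tab, "counts")), c(1L, 2L, 1L))
})

test_that("PR2 coordinates come from fourfold-box third positions only", {
  expect_equal(pr2_point(c(GCA = 1, GCT = 1, GCG = 1, GCC = 1)),
               c(at_bias = 0.5, gc_bias = 0.5))
  p <- pr2_point(c(GCT = 3, GCA = 1))
  expect_equal(p[["at_bias"]], 0.25)
  expect_true(is.na(p[["gc_bias"]]))
  # twofold families (e.g. Lys AAA/AAG) must not contribute
  expect_equal(pr2_point(c(GCA = 2, GCT = 2, AAA = 50, AAG = 50)),
               c(at_bias = 0.5, gc_bias = NA))
  tab <- pr2_table(c(g1 = make_cds(c("GCT", "GCA", "GCG", "GCC")),
                     g2 = make_cds(c("AAA", "AAA"))))
  expect_identical(tab$valid, c(TRUE, FALSE))
})

test_that("an unbiased generator centres the PR2 cloud on (0.5, 0.5)", {
  sim <- simulate_cds(sim_config(n_genes = 200, gc3_range = NULL,
                                 slope = NULL, kappa = 0, seed = 17))
  tab <- pr2_table(sim$sequences)
  for (coord in c("at_bias", "gc_bias")) {
    v <- tab[[coord]][tab$valid]
    se <- stats::sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - 0.5), 3 * se)
  }
})

test_that("the neutrality regression handles exact and degenerate inputs", {
  gc3 <- c(20, 30, 40, 50, 60)
  fit <- neutrality_fit(gc3, gc3)
  expect_equal(fit$slope, 1)
  expect_equal(fit$r, 1)
  expect_equal(coef(fit), c(intercept = 0, slope = 1))
  flat <- neutrality_fit(gc3, rep(42, 5))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r, 0)
  expect_equal(flat$selection_share, 1)
  expect_error(neutrality_fit(c(1, 2), c(1, 2)), "at least 3")
})

test_that("the neutrality fit recovers the generator's slope", {
  sim <- simulate_cds(sim_config(n_genes = 200, slope = 0.15,
                                 gc12_sd = 0.02, seed = 23))
  fit <- neutrality_fit(100 * sim$truth$gc3_realized,
                        100 * sim$truth$gc12_realized)
  expect_gt(fit$slope, 0.12)
  expect_lt(fit$slope, 0.18)
  expect_lt(fit$p, 0.001)
})

test_that("correlations match a brute-force estimator and behave under the null", {
  df <- data.frame(ENC = rnorm(30), CAI = rnorm(30))
  df$GC3 <- df$ENC            # x vs x copy
  df$AT3 <- -df$ENC           # x vs -x
  out <- correlate_indices(df, vars = c("ENC", "CAI", "GC3", "AT3"))
  get <- function(a, b) out[out$var1 == a & out$var2 == b, ]
  expect_equal(get("ENC", "GC3")$r, 1)
  expect_lt(get("ENC", "GC3")$p, 1e-15)
  expect_equal(get("ENC", "AT3")$r, -1)
  rmat <- attr(out, "r_matrix")
  expect_equal(rmat, t(rmat))
  expect_equal(unname(diag(rmat)), rep(1, 4))
  # brute-force covariance/sd oracle
  set.seed(12)
  x <- rnorm(200); y <- rnorm(200)
  r_pkg <- correlate_indices(data.frame(a = x, b = y),
                             vars = c("a", "b"))$r
  r_brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r_pkg, r_brute, tolerance = 1e-12)
  # null calibration: p-values approximately uniform
  set.seed(34)
  pvals <- replicate(200, {
    d <- data.frame(a = rnorm(50), b = rnorm(50))
    correlate_indices(d, vars = c("a", "b"))$p
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  set.seed(56)
  big <- data.frame(a = rnorm(1000), b = rnorm(1000))
  expect_lt(abs(correlate_indices(big, vars = c("a", "b"))$r), 0.1)
})

test_that("Spearman correlations are available by flag", {
  set.seed(9)
  d <- data.frame(a = rexp(40), b = rexp(40))
  out <- suppressWarnings(correlate_indices(d, vars = c("a", "b"),
                                            method = "spearman"))
  expect_equal(out$r, stats::cor(d$a, d$b, method = "spearman"),
               tolerance = 1e-12)
})
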