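tally_fixture <- function(effects, mafs, labels = NULL) {
  n <- length(effects)
  data.frame(gene_symbol = rep("G", n), chrom = rep("c", n), pos = seq_len(n),
             ref_allele = rep("A", n), alt_allele = rep("G", n),
             effect = effects,
             maf_all = mafs, maf_ea = mafs, maf_aa = mafs,
             filter_status = rep("PASS", n),
             pp2_label = if (is.null(labels)) rep(NA_character_, n) else labels,
             pp2_score = rep(NA_real_, n), stringsAsFactors = FALSE)
}

test_that("per-gene X and Y follow their definitions", {
  recs <- tally_fixture(c("missense", "missense", "coding-synonymous",
                          "stop-gained"),
                        c(0.2, 0.05, 5, 0.3))
  t <- tally_gene(recs, rho = 0.1)
  expect_equal(t$x_total, 4)
  expect_equal(t$y_common_functional, 2)

  empty <- tally_fixture(character(0), numeric(0))
  t0 <- tally_gene(empty)
  expect_equal(t0$x_total, 0L)
  expect_equal(t0$y_common_functional, 0L)

  # pp2 mode: benign missense leaves Y but stays in X
  pp2 <- tally_fixture(c("missense", "missense"), c(0.5, 0.5),
                       labels = c("benign", "probably"))
  tp <- tally_gene(pp2, rho = 0.1, mode = "pp2")
  expect_equal(tp$x_total, 2)
  expect_equal(tp$y_common_functional, 1)

  multi <- recs
  multi$gene_symbol[1] <- "OTHER"
  expect_error(tally_gene(multi), "multiple genes")
})

test_that("the regression matches a normal-equations oracle", {
  tal <- data.frame(gene_symbol = sprintf("G%d", 1:6),
                    x_total = c(10, 20, 30, 40, 50, 60),
                    y_common_functional = c(1, 3, 2, 6, 4, 8))
  fit <- fit_regression(tal)
  o <- oracle_ols(tal$x_total, tal$y_common_functional)
  expect_equal(fit$intercept, o$intercept, tolerance = 1e-12)
  expect_equal(fit$slope, o$slope, tolerance = 1e-12)
  expect_equal(fit$residual_std, o$sigma, tolerance = 1e-12)
  expect_equal(unname(fit$leverage), o$leverage, tolerance = 1e-12)
  expect_equal(sum(fit$leverage), 2, tolerance = 1e-10)  # intercept + slope

  # adding a point exactly on the fitted line leaves the line unchanged
  x_new <- 70
  y_new <- o$intercept + o$slope * x_new
  tal2 <- rbind(tal, data.frame(gene_symbol = "G7", x_total = x_new,
                                y_common_functional = y_new))
  fit2 <- fit_regression(tal2)
  expect_equal(fit2$slope, fit$slope, tolerance = 1e-10)
  expect_equal(fit2$intercept, fit$intercept, tolerance = 1e-10)

  expect_error(fit_regression(tal[1:2, ]), "insufficient")
  tal$x_total <- 5
  expect_error(fit_regression(tal), "degenerate design")
})

test_that("studentized scores match the explicit hat-matrix oracle", {
  set.seed(21)
  for (n in c(6, 50, 1000)) {
    x <- stats::rpois(n, 40)
    x[1:2] <- c(1, 200)              # force a leverage spread
    y <- 0.1 * x + stats::rnorm(n, 0, 2)
    tal <- data.frame(gene_symbol = sprintf("G%d", 1:n), x_total = x,
                      y_common_functional = y)
    fit <- fit_regression(tal)
    s <- studentize(fit)
    o <- oracle_ols(x, y)
    expect_equal(unname(s), o$student, tolerance = 1e-10)
  }
})

test_that("score signs and degeneracies behave as defined", {
  tal <- data.frame(gene_symbol = sprintf("G%d", 1:6),
                    x_total = c(10, 20, 30, 40, 50, 60),
                    y_common_functional = c(1, 3, 2, 6, 4, 8))
  fit <- fit_regression(tal)
  s <- studentize(fit)
  r <- fit$residuals
  expect_true(all(sign(s[r != 0]) == sign(r[r != 0])))
  # a gene exactly on the line scores 0
  o <- oracle_ols(tal$x_total, tal$y_common_functional)
  tal2 <- rbind(tal, data.frame(gene_symbol = "G7", x_total = 70,
                                y_common_functional = o$intercept + o$slope * 70))
  s2 <- studentize(fit_regression(tal2))
  expect_equal(unname(s2["G7"]), 0, tolerance = 1e-10)
  # perfect collinearity -> zero residual_std -> degenerate-fit error
  exact <- data.frame(gene_symbol = sprintf("G%d", 1:5),
                      x_total = c(10, 20, 30, 40, 50),
                      y_common_functional = 0.1 * c(10, 20, 30, 40, 50))
  fit0 <- fit_regression(exact)
  expect_equal(fit0$slope, 0.1, tolerance = 1e-12)
  expect_equal(fit0$intercept, 0, tolerance = 1e-10)
  expect_error(studentize(fit0), "degenerate fit")
})

test_that("external studentization differs but agrees in sign and order", {
  set.seed(8)
  x <- stats::rpois(100, 30)
  y <- 0.1 * x + stats::rnorm(100)
  fit <- fit_regression(data.frame(gene_symbol = sprintf("G%d", 1:100),
                                   x_total = x, y_common_functional = y))
  si <- studentize(fit, "internal")
  se <- studentize(fit, "external")
  expect_false(isTRUE(all.equal(si, se)))
  expect_equal(sign(si), sign(se))
  expect_equal(order(si), order(se))
})

test_that("percentiles use average ranks with the lowest score lowest", {
  expect_equal(percentile_rank(c(-2, -1, 0, 1)), c(25, 50, 75, 100))
  expect_equal(percentile_rank(rep(1.5, 7)), rep(100 * 4 / 7, 7))
  expect_equal(percentile_rank(c(-1, -1, 2)), c(50, 50, 100))
  set.seed(2)
  for (n in c(1, 10, 501)) {
    p <- percentile_rank(stats::rnorm(n))
    expect_true(all(p > 0 & p <= 100))
    expect_equal(mean(p), 100 * (n + 1) / (2 * n), tolerance = 1e-12)
  }
})

test_that("raw residuals are centered and orthogonal to burden; S rises with Y", {
  sim <- simulate_exome(sim_config(n_genes = 600, seed = 13))
  res <- compute_rvis(sim$variants, sim$transcripts, sim$coverage)
  tal <- res$scores
  fit <- fit_regression(tal)
  expect_lt(abs(sum(fit$residuals)), 1e-8)
  expect_lt(abs(stats::cor(fit$residuals, tal$x_total)), 1e-10)
  expect_lt(abs(stats::cor(tal$score, tal$x_total)), 0.05)

  # holding X fixed, S strictly increases in Y
  i <- which.max(tal$x_total)
  bump <- tal
  bump$y_common_functional[i] <- bump$y_common_functional[i] + 1L
  s_before <- studentize(fit)[i]
  s_after <- studentize(fit_regression(bump))[i]
  expect_gt(s_after, s_before)
})

test_that("the pipeline is deterministic and input-order invariant", {
  d <- make_tiny_dataset(n_genes = 6)
  sim <- simulate_exome(sim_config(n_genes = 200, seed = 4))
  res1 <- compute_rvis(sim$variants, sim$transcripts, sim$coverage)
  res2 <- compute_rvis(sim$variants, sim$transcripts, sim$coverage)
  expect_identical(res1$scores, res2$scores)
  shuf <- sample(nrow(sim$variants))
  res3 <- compute_rvis(sim$variants[shuf, ], sim$transcripts, sim$coverage)
  expect_equal(res1$scores, res3$scores, tolerance = 1e-12)

  # tiny fixture ties out against the hand-built counts
  tiny <- compute_rvis(d$variants, d$transcripts, d$coverage)
  expect_equal(tiny$scores$x_total, d$x)
  expect_equal(tiny$scores$y_common_functional, d$y)
  o <- oracle_ols(d$x, d$y)
  expect_equal(tiny$scores$score, o$student, tolerance = 1e-10)
})

test_that("scores under different frequency thresholds are positively correlated", {
  sim <- simulate_exome(sim_config(n_genes = 800, seed = 6))
  lo <- compute_rvis(sim$variants, sim$transcripts, sim$coverage,
                     rvis_config(rho = 0.01))
  hi <- compute_rvis(sim$variants, sim$transcripts, sim$coverage,
                     rvis_config(rho = 1))
  r <- score_correlation(lo, hi)
  expect_gt(r$r, 0)
  expect_equal(r$n_joined, 800L)
})

test_that("unassessable genes are excluded and reported with reasons", {
  d <- make_tiny_dataset(n_genes = 6)
  # starve the last gene's coverage below 70%
  g6 <- d$transcripts[6, ]
  cov <- rbind(data.frame(chrom = "chrT", start = 0L, end = g6$start,
                          mean_depth = 50),
               data.frame(chrom = "chrT", start = g6$start,
                          end = g6$start + 100L, mean_depth = 50))
  res <- compute_rvis(d$variants, d$transcripts, cov)
  expect_equal(res$unassessable$gene_symbol, "G06")
  expect_match(res$unassessable$reason, "covered fraction")
  expect_false("G06" %in% res$scores$gene_symbol)
  expect_equal(nrow(res$scores), 5L)
})
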