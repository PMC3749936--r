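dn <- function(proband, gene, effect, pp2 = NA_real_, pct = NA_real_,
               cohort = "case") {
  data.frame(proband_id = proband, cohort = cohort, gene_symbol = gene,
             effect = effect, pp2_score = pp2, rvis_percentile = pct,
             stringsAsFactors = FALSE)
}

test_that("effects recode onto the damaging scale", {
  expect_equal(damaging_score("LGD"), 1.0)
  expect_equal(damaging_score("silent"), 0.0)
  expect_equal(damaging_score("missense", 0.97), 0.97)
  expect_equal(damaging_score(c("missense", "LGD", "silent"),
                              c(0.5, NA, NA)), c(0.5, 1, 0))
  expect_error(damaging_score("missense"), "without a PolyPhen-2 score")
  expect_error(damaging_score("frameshift"), "unknown")
})

test_that("each proband is represented by the most intolerant-gene mutation", {
  one <- dn("P1", "A", "missense", 0.5, 40)
  one$damaging <- damaging_score(one$effect, one$pp2_score)
  expect_equal(nrow(select_representative(one)), 1L)
  expect_equal(select_representative(one)$gene_symbol, "A")

  two <- rbind(dn("P1", "A", "missense", 0.5, 40),
               dn("P1", "B", "missense", 0.3, 10))
  two$damaging <- damaging_score(two$effect, two$pp2_score)
  expect_equal(select_representative(two)$gene_symbol, "B")

  tie <- rbind(dn("P1", "A", "missense", 0.2, 10),
               dn("P1", "B", "missense", 0.9, 10))
  tie$damaging <- damaging_score(tie$effect, tie$pp2_score)
  expect_equal(select_representative(tie)$pp2_score, 0.9)

  tie2 <- rbind(dn("P1", "B", "missense", 0.7, 10),
                dn("P1", "A", "missense", 0.7, 10))
  tie2$damaging <- damaging_score(tie2$effect, tie2$pp2_score)
  expect_equal(select_representative(tie2)$gene_symbol, "A")

  # missense_only mode ignores LGD/silent; probands without an eligible
  # mutation drop out of the denominator
  lgd <- rbind(dn("P1", "A", "LGD", NA, 5),
               dn("P2", "B", "missense", 0.6, 50))
  lgd$damaging <- damaging_score(lgd$effect, lgd$pp2_score)
  expect_equal(select_representative(lgd, "missense_only")$proband_id, "P2")
  expect_equal(nrow(select_representative(lgd, "recoded")), 2L)
})

test_that("hot-zone boundaries are inclusive and the flag is monotone", {
  expect_true(hot_zone_flag(25.0, 0.95))
  expect_false(hot_zone_flag(26.0, 1.0))
  expect_false(hot_zone_flag(25.0, 0.949))
  expect_true(hot_zone_flag(10.0, damaging_score("LGD")))

  set.seed(19)
  pct <- stats::runif(200, 0, 100)
  dmg <- stats::runif(200)
  base <- hot_zone_flag(pct, dmg)
  better <- hot_zone_flag(pmax(0, pct - stats::runif(200, 0, 20)),
                          pmin(1, dmg + stats::runif(200, 0, 0.2)))
  expect_true(all(better[base]))   # improving both axes never leaves the zone
})

test_that("hot-zone enrichment matches the hypergeometric oracle and label swap inverts OR", {
  mk_cohort <- function(n_in, n_out, cohort) {
    d <- rbind(
      if (n_in) do.call(rbind, lapply(seq_len(n_in), function(i)
        dn(sprintf("%s_in%d", cohort, i), "A", "missense", 0.99, 5, cohort))),
      if (n_out) do.call(rbind, lapply(seq_len(n_out), function(i)
        dn(sprintf("%s_out%d", cohort, i), "B", "missense", 0.2, 80, cohort))))
    d$damaging <- damaging_score(d$effect, d$pp2_score)
    d
  }
  case <- mk_cohort(8, 2, "case")
  ctrl <- mk_cohort(2, 8, "ctrl")
  hz <- hot_zone_enrichment(case, ctrl)
  expect_equal(unname(hz$table[1, "case"]), 8L)
  expect_equal(hz$p, oracle_fisher_p(hz$table), tolerance = 1e-9)
  swapped <- hot_zone_enrichment(ctrl, case)
  expect_equal(swapped$p, hz$p, tolerance = 1e-12)
  expect_equal(swapped$odds_ratio, 1 / hz$odds_ratio, tolerance = 1e-6)

  # identical proportions -> OR 1; shuffling probands changes nothing
  even <- hot_zone_enrichment(mk_cohort(3, 3, "a"), mk_cohort(3, 3, "b"))
  expect_equal(even$odds_ratio, 1, tolerance = 1e-9)
  shuf <- case[sample(nrow(case)), ]
  expect_equal(hot_zone_enrichment(shuf, ctrl)$p, hz$p)

  # degenerate margin: all cases in zone, no controls
  degen <- hot_zone_enrichment(mk_cohort(5, 0, "a"), mk_cohort(0, 5, "b"))
  expect_true(is.infinite(degen$odds_ratio))
  expect_true(degen$or_undefined)
  expect_equal(degen$p, oracle_fisher_p(degen$table), tolerance = 1e-9)
})

test_that("quartile binomial test matches outcome enumeration", {
  got <- intolerant_quartile_binomial(10, 12, p0 = 0.38)
  expect_equal(got$p, oracle_binom_p(10, 12, 0.38), tolerance = 1e-12)
  expect_equal(got$proportion, 10 / 12)

  at_expectation <- intolerant_quartile_binomial(38, 100, p0 = 0.38)
  expect_gt(at_expectation$p, 0.9)
  expect_error(intolerant_quartile_binomial(0, 0), "positive")
})

test_that("the null success probability is recomputable as quartile real estate", {
  # four genes, sizes arranged so the bottom-quartile gene holds exactly 38%
  mk_region <- function(g, len) {
    ex <- data.frame(gene_symbol = g, transcript_id = "T", chrom = "c",
                     start = 0L, end = len)
    apply_coverage(merge_transcripts(ex, 0),
                   data.frame(chrom = "c", start = 0L, end = len,
                              mean_depth = 30), 10, 0.7)
  }
  regions <- list(A = mk_region("A", 380L), B = mk_region("B", 200L),
                  C = mk_region("C", 220L), D = mk_region("D", 200L))
  scores <- data.frame(gene_symbol = c("A", "B", "C", "D"),
                       score = c(-2, 0, 1, 2),
                       percentile = c(25, 50, 75, 100))
  expect_equal(quartile_real_estate(scores, regions), 0.38)
})

test_that("per-effect quartile reporting aggregates events, not probands", {
  d <- rbind(dn("P1", "A", "missense", 0.9, 10), dn("P1", "B", "LGD", NA, 90),
             dn("P2", "C", "silent", NA, 15), dn("P3", "D", "missense", 0.1, 80))
  d$damaging <- damaging_score(d$effect, d$pp2_score)
  rep_tab <- quartile_enrichment_by_effect(d, p0 = 0.38)
  expect_equal(sort(rep_tab$effect), c("LGD", "missense", "silent"))
  expect_equal(rep_tab$n[rep_tab$effect == "missense"], 2L)
  expect_equal(rep_tab$k_intolerant[rep_tab$effect == "missense"], 1L)
  mis_p <- rep_tab$p[rep_tab$effect == "missense"]
  expect_equal(mis_p, oracle_binom_p(1, 2, 0.38), tolerance = 1e-12)
})
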