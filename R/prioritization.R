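# De novo mutation prioritization: recode effects onto a [0,1] damaging
# scale, pick one representative mutation per proband, flag the 2D
# "hot zone" (damaging >= 0.95, gene percentile <= 25), and test cohort
# enrichment with exact tests.

#' Probabilistic damaging score for a de novo mutation
#'
#' Missense mutations keep their PolyPhen-2 quantitative score; likely
#' gene-disrupting (LGD: nonsense, splice-site, frameshift-class) events
#' are recoded to 1; silent mutations to 0.
#'
#' @param effect character vector in \{missense, LGD, silent\}.
#' @param pp2_score numeric PolyPhen-2 scores (required where effect is
#'   missense).
#' @return numeric vector in [0, 1].
#' @export
damaging_score <- function(effect, pp2_score = NULL) {
  effect <- as.character(effect)
  bad <- !effect %in% c("missense", "LGD", "silent")
  if (any(bad))
    stop("unknown de novo effect(s): ", paste(unique(effect[bad]), collapse = ", "))
  out <- numeric(length(effect))
  out[effect == "LGD"] <- 1
  out[effect == "silent"] <- 0
  mis <- effect == "missense"
  if (any(mis)) {
    if (is.null(pp2_score) || anyNA(pp2_score[mis]))
      stop("missense de novo mutation(s) without a PolyPhen-2 score")
    if (any(pp2_score[mis] < 0 | pp2_score[mis] > 1))
      stop("PolyPhen-2 scores must lie in [0, 1]")
    out[mis] <- pp2_score[mis]
  }
  out
}

#' Join gene-score percentiles onto a de novo mutation table
#'
#' @param denovo data.frame with columns \code{proband_id}, \code{cohort},
#'   \code{gene_symbol}, \code{effect}, \code{pp2_score}.
#' @param scores an \code{rvis_scores} object or score data.frame with
#'   \code{gene_symbol} and \code{percentile}.
#' @return the de novo table with \code{rvis_percentile} and
#'   \code{damaging} columns; mutations in unscored genes are dropped with
#'   a message.
#' @export
annotate_denovo <- function(denovo, scores) {
  if (inherits(scores, "rvis_scores")) scores <- scores$scores
  idx <- match(as.character(denovo$gene_symbol), scores$gene_symbol)
  dropped <- is.na(idx)
  if (any(dropped))
    message(sum(dropped), " de novo mutation(s) in unscored genes dropped")
  out <- denovo[!dropped, , drop = FALSE]
  out$rvis_percentile <- scores$percentile[idx[!dropped]]
  out$damaging <- damaging_score(out$effect, out$pp2_score)
  out
}

#' Select each proband's single representative de novo mutation
#'
#' Under a single-causal-mutation model, a proband with several de novo
#' mutations is represented by the one in the most intolerant gene (lowest
#' score percentile); ties break toward the higher damaging score, then
#' the lexicographically first gene symbol.  Probands with no eligible
#' mutation are omitted (they leave downstream denominators).
#'
#' @param denovo annotated de novo table (see \code{\link{annotate_denovo}}).
#' @param mode \code{"missense_only"} (only missense mutations eligible,
#'   as in the 2D plots) or \code{"recoded"} (missense, LGD and silent all
#'   eligible under the recoded damaging scale).
#' @return one-row-per-proband data.frame.
#' @export
select_representative <- function(denovo, mode = c("missense_only", "recoded")) {
  mode <- match.arg(mode)
  eligible <- if (mode == "missense_only") denovo$effect == "missense"
              else denovo$effect %in% c("missense", "LGD", "silent")
  d <- denovo[eligible, , drop = FALSE]
  if (nrow(d) == 0L)
    return(d)
  ord <- order(d$proband_id, d$rvis_percentile, -d$damaging,
               as.character(d$gene_symbol))
  d <- d[ord, , drop = FALSE]
  d[!duplicated(d$proband_id), , drop = FALSE]
}

#' Is a mutation in the high-interest hot zone?
#'
#' TRUE when the gene's score percentile is at or below \code{y_max}
#' (default 25th percentile, expressed as 0.25) and the damaging score is
#' at or above \code{x_min} (default 0.95); both boundaries inclusive.
#'
#' @param rvis_percentile gene score percentile in (0, 100].
#' @param damaging damaging score in [0, 1].
#' @param x_min,y_max hot-zone thresholds.
#' @return logical vector.
#' @export
hot_zone_flag <- function(rvis_percentile, damaging, x_min = 0.95, y_max = 0.25) {
  stopifnot(all(rvis_percentile >= 0 & rvis_percentile <= 100),
            all(damaging >= 0 & damaging <= 1))
  (rvis_percentile / 100) <= y_max & damaging >= x_min
}

#' Hot-zone enrichment of a case cohort against controls
#'
#' Each cohort is reduced to one representative mutation per proband; the
#' 2x2 table of in-zone versus not by case versus control is tested with a
#' two-tailed Fisher exact test.
#'
#' @param case,control annotated de novo tables for the two cohorts.
#' @param mode representative-selection mode (see
#'   \code{\link{select_representative}}).
#' @param x_min,y_max hot-zone thresholds.
#' @return list with per-cohort counts and proportions, \code{odds_ratio}
#'   (conditional MLE; \code{Inf} flagged on a degenerate margin),
#'   \code{p} (two-tailed Fisher), and the 2x2 \code{table}.
#' @export
hot_zone_enrichment <- function(case, control, mode = "recoded",
                                x_min = 0.95, y_max = 0.25) {
  rc <- select_representative(case, mode = mode)
  rk <- select_representative(control, mode = mode)
  if (nrow(rc) == 0L || nrow(rk) == 0L)
    stop("both cohorts need >= 1 proband with a representative mutation")
  zc <- hot_zone_flag(rc$rvis_percentile, rc$damaging, x_min, y_max)
  zk <- hot_zone_flag(rk$rvis_percentile, rk$damaging, x_min, y_max)
  tab <- matrix(c(sum(zc), sum(!zc), sum(zk), sum(!zk)), nrow = 2,
                dimnames = list(zone = c("in", "out"),
                                cohort = c("case", "control")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  degenerate <- any(rowSums(tab) == 0L) || any(colSums(tab) == 0L) ||
    !is.finite(ft$estimate)
  list(case = list(n_individuals = nrow(rc), n_in_zone = sum(zc),
                   proportion = mean(zc)),
       control = list(n_individuals = nrow(rk), n_in_zone = sum(zk),
                      proportion = mean(zk)),
       odds_ratio = unname(ft$estimate), p = ft$p.value,
       or_undefined = degenerate, table = tab)
}

#' Exact binomial test of de novo enrichment in the intolerant quartile
#'
#' Two-tailed exact binomial test of k mutations landing in the most
#' intolerant 25 percent of genes out of n, against a success probability
#' p0 that accounts for the genomic real estate those genes occupy
#' (0.38 for the published gene set; recomputable from a score table and
#' regions via \code{\link{quartile_real_estate}}).
#'
#' @param k_in_intolerant mutations in bottom-quartile genes.
#' @param n_total total mutations.
#' @param p0 null success probability.
#' @return list with \code{p}, \code{proportion}, \code{expected}.
#' @export
intolerant_quartile_binomial <- function(k_in_intolerant, n_total, p0 = 0.38) {
  if (n_total == 0L) stop("n_total must be positive")
  stopifnot(k_in_intolerant >= 0, k_in_intolerant <= n_total,
            p0 > 0, p0 < 1)
  bt <- stats::binom.test(k_in_intolerant, n_total, p = p0,
                          alternative = "two.sided")
  list(p = bt$p.value, proportion = k_in_intolerant / n_total,
       expected = p0 * n_total)
}

#' Covered-site fraction occupied by the most intolerant quartile
#'
#' The null success probability for
#' \code{\link{intolerant_quartile_binomial}}: the share of all covered
#' coding sites held by genes at or below the percentile cutoff.  Larger
#' genes both attract more de novo mutations and tend to be intolerant, so
#' the null must be size-adjusted.
#'
#' @param scores an \code{rvis_scores} object or score data.frame.
#' @param regions named list of coverage-masked \code{gene_region}s.
#' @param percentile_cutoff quartile boundary (default 25).
#' @return fraction in [0, 1].
#' @export
quartile_real_estate <- function(scores, regions, percentile_cutoff = 25) {
  if (inherits(scores, "rvis_scores")) scores <- scores$scores
  sizes <- vapply(regions, function(r) as.numeric(r$covered_sites), numeric(1))
  sizes <- sizes[names(sizes) %in% scores$gene_symbol]
  if (!length(sizes)) stop("no scored gene has a region")
  low <- scores$gene_symbol[scores$percentile <= percentile_cutoff]
  sum(sizes[names(sizes) %in% low]) / sum(sizes)
}

#' Per-effect-type quartile enrichment report
#'
#' For each effect class in a cohort's annotated de novo table, the count
#' and proportion of mutations in the most intolerant quartile with the
#' size-adjusted exact binomial p.
#'
#' @param denovo annotated de novo table.
#' @param p0 null success probability (see
#'   \code{\link{quartile_real_estate}}).
#' @param percentile_cutoff quartile boundary (default 25).
#' @return data.frame, one row per effect class.
#' @export
quartile_enrichment_by_effect <- function(denovo, p0 = 0.38,
                                          percentile_cutoff = 25) {
  res <- lapply(split(denovo, as.character(denovo$effect)), function(d) {
    k <- sum(d$rvis_percentile <= percentile_cutoff)
    bt <- intolerant_quartile_binomial(k, nrow(d), p0 = p0)
    data.frame(effect = d$effect[1], n = nrow(d), k_intolerant = k,
               proportion = bt$proportion, p = bt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
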