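# Synthetic exome and trio-cohort generator.  Emulates the statistical
# structure the score assumes — common functional variation roughly
# proportional to total mutational burden genome-wide, with a designated
# fraction of intolerant genes whose common functional variation is
# suppressed — so the whole pipeline is testable with known ground truth.

#' Simulation configuration
#'
#' @param n_genes number of genes (>= 10).
#' @param length_meanlog,length_sdlog log-normal coding-length parameters
#'   (bp); defaults give a median footprint of ~1.5 kb.
#' @param variant_rate expected qualifying site-alleles per coding base
#'   across the cohort.
#' @param functional_fraction probability a variant is functional
#'   (missense/nonsense/splice) rather than synonymous.
#' @param common_fraction probability a variant is common (MAF > rho)
#'   before any suppression.
#' @param intolerant_fraction fraction of genes designated intolerant.
#' @param suppression multiplier in [0, 1] on the probability that a
#'   functional variant in an intolerant gene is common (1 = no
#'   suppression, 0 = no common functional variation at all).
#' @param rho common/rare MAF threshold in percent.
#' @param n_cases,n_controls trio-cohort sizes.
#' @param causal_hit_rate probability a case proband carries one planted
#'   damaging de novo mutation in an intolerant gene.
#' @param seed integer random seed threaded through all draws.
#' @return validated configuration list.
#' @export
sim_config <- function(n_genes = 2000, length_meanlog = log(1500),
                       length_sdlog = 0.6, variant_rate = 0.02,
                       functional_fraction = 0.7, common_fraction = 0.15,
                       intolerant_fraction = 0.1, suppression = 0.2,
                       rho = 0.1, n_cases = 200, n_controls = 200,
                       causal_hit_rate = 0.5, seed = 1L) {
  stopifnot(n_genes >= 10, variant_rate > 0,
            functional_fraction >= 0, functional_fraction <= 1,
            common_fraction >= 0, common_fraction <= 1,
            intolerant_fraction >= 0, intolerant_fraction <= 1,
            suppression >= 0, suppression <= 1,
            rho > 0, rho < 100, n_cases >= 1, n_controls >= 1,
            causal_hit_rate >= 0, causal_hit_rate <= 1)
  list(n_genes = as.integer(n_genes), length_meanlog = length_meanlog,
       length_sdlog = length_sdlog, variant_rate = variant_rate,
       functional_fraction = functional_fraction,
       common_fraction = common_fraction,
       intolerant_fraction = intolerant_fraction,
       suppression = suppression, rho = rho,
       n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
       causal_hit_rate = causal_hit_rate, seed = as.integer(seed))
}

.sim_effects <- function(n, functional) {
  # empirical-flavored split: missense dominates functional variation,
  # synonymous splits between plain and near-splice
  fun_effects <- c("missense", "stop-gained", "splice-5", "splice-3",
                   "missense-near-splice", "stop-lost")
  fun_w <- c(0.82, 0.06, 0.04, 0.04, 0.03, 0.01)
  non_effects <- c("coding-synonymous", "coding-synonymous-near-splice")
  non_w <- c(0.95, 0.05)
  out <- character(n)
  out[functional] <- sample(fun_effects, sum(functional), replace = TRUE,
                            prob = fun_w)
  out[!functional] <- sample(non_effects, sum(!functional), replace = TRUE,
                             prob = non_w)
  out
}

#' Simulate an exome-scale variant dataset with known intolerant genes
#'
#' Per gene: a log-normal coding length split over 1-3 exons laid end to
#' end along one synthetic chromosome; full 30-fold coverage by default; a
#' Poisson(rate x length) number of qualifying site-alleles, each assigned
#' an effect class and a MAF from a two-component rare/common mixture.  In
#' genes designated intolerant, a functional variant that drew "common"
#' keeps that status only with probability \code{suppression} — total
#' burden X is untouched while common functional variation Y is thinned.
#' Missense variants get PolyPhen-2 labels and scores (roughly a third
#' benign, mirroring cohort-scale annotation).  Deterministic given the
#' config seed.
#'
#' @param config a \code{\link{sim_config}} list.
#' @return list with \code{transcripts}, \code{coverage}, \code{variants}
#'   (data.frames in the package's standard input layouts) and
#'   \code{truth} (data.frame: gene_symbol, intolerant, length).
#' @export
simulate_exome <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("GENE%04d", seq_len(n))
  len <- pmax(150L, as.integer(round(stats::rlnorm(
    n, config$length_meanlog, config$length_sdlog))))
  intolerant <- stats::runif(n) < config$intolerant_fraction

  # lay genes end to end with 10 kb gaps; split each into 1-3 exons
  gap <- 10000L
  gene_start <- cumsum(c(0L, utils::head(len + gap, -1L)))
  tx <- lapply(seq_len(n), function(i) {
    k <- sample(1:3, 1)
    cuts <- sort(sample(seq_len(len[i] - 1L), k - 1L))
    bounds <- c(0L, cuts, len[i])
    # spread exons apart by 500 bp introns inside the gene's slot
    offs <- cumsum(c(0L, rep(500L, k - 1L)))
    data.frame(gene_symbol = genes[i], transcript_id = paste0(genes[i], ".1"),
               chrom = "chrS", strand = "+",
               start = gene_start[i] + bounds[-(k + 1L)] + offs,
               end = gene_start[i] + bounds[-1L] + offs,
               stringsAsFactors = FALSE)
  })
  transcripts <- do.call(rbind, tx)

  coverage <- data.frame(chrom = "chrS", start = 0L,
                         end = max(transcripts$end) + 10L, mean_depth = 30)

  n_var <- stats::rpois(n, config$variant_rate * len)
  gi <- rep(seq_len(n), n_var)
  total <- sum(n_var)
  # positions uniform over each gene's exonic bases
  pos <- unlist(lapply(seq_len(n), function(i) {
    if (n_var[i] == 0L) return(integer(0))
    ex <- tx[[i]]
    sites <- unlist(mapply(seq, ex$start, ex$end - 1L, SIMPLIFY = FALSE))
    sample(sites, n_var[i], replace = TRUE)
  }), use.names = FALSE)
  functional <- stats::runif(total) < config$functional_fraction
  effect <- .sim_effects(total, functional)
  common <- stats::runif(total) < config$common_fraction
  thin <- functional & common & intolerant[gi] &
    stats::runif(total) >= config$suppression
  common <- common & !thin
  rho <- config$rho
  maf <- ifelse(common,
                stats::runif(total, rho * 1.5, 30),
                stats::runif(total, 1e-3 * rho, rho))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, total, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  is_mis <- effect %in% c("missense", "missense-near-splice")
  pp2_label <- rep(NA_character_, total)
  pp2_score <- rep(NA_real_, total)
  if (any(is_mis)) {
    lab <- sample(c("benign", "possibly", "probably"), sum(is_mis),
                  replace = TRUE, prob = c(0.33, 0.27, 0.40))
    pp2_label[is_mis] <- lab
    pp2_score[is_mis] <- ifelse(lab == "benign",
                                stats::runif(sum(is_mis), 0, 0.4),
                                ifelse(lab == "possibly",
                                       stats::runif(sum(is_mis), 0.4, 0.9),
                                       stats::runif(sum(is_mis), 0.9, 1)))[
                                         seq_len(sum(is_mis))]
  }
  variants <- data.frame(
    gene_symbol = genes[gi], chrom = "chrS", pos = pos,
    ref_allele = ref, alt_allele = unname(alt), effect = effect,
    maf_all = maf, maf_ea = maf, maf_aa = maf,
    filter_status = "PASS", pp2_label = pp2_label, pp2_score = pp2_score,
    stringsAsFactors = FALSE)

  list(transcripts = transcripts, coverage = coverage, variants = variants,
       truth = data.frame(gene_symbol = genes, intolerant = intolerant,
                          length = len, stringsAsFactors = FALSE))
}

#' Simulate case and control trio de novo mutation tables
#'
#' Control probands draw de novo mutations from genes in proportion to
#' coding length, with effects mostly missense (PolyPhen-2 scores from a
#' bimodal background) and occasional LGD/silent events.  Case probands
#' receive the same background plus, with probability
#' \code{causal_hit_rate}, one planted damaging mutation (PolyPhen-2 >=
#' 0.95 missense or LGD) in a truth-intolerant gene.  Deterministic given
#' the config seed.
#'
#' @param truth truth table from \code{\link{simulate_exome}}.
#' @param config a \code{\link{sim_config}} list.
#' @return list with \code{case} and \code{control} de novo data.frames
#'   (proband_id, cohort, gene_symbol, effect, pp2_score).
#' @export
simulate_trios <- function(truth, config = sim_config()) {
  set.seed(config$seed + 1L)
  genes <- truth$gene_symbol
  w <- truth$length / sum(truth$length)
  intol <- truth$gene_symbol[truth$intolerant]
  if (!length(intol)) stop("truth table has no intolerant genes to plant in")

  draw_background <- function(proband, cohort) {
    k <- 1L + stats::rpois(1, 1)
    g <- sample(genes, k, replace = TRUE, prob = w)
    eff <- sample(c("missense", "LGD", "silent"), k, replace = TRUE,
                  prob = c(0.70, 0.08, 0.22))
    # bimodal background, as PolyPhen-2 scores are in cohort data
    pp2 <- ifelse(eff == "missense",
                  ifelse(stats::runif(k) < 0.6, stats::rbeta(k, 1, 4),
                         stats::rbeta(k, 4, 1)), NA_real_)
    data.frame(proband_id = proband, cohort = cohort, gene_symbol = g,
               effect = eff, pp2_score = pp2, stringsAsFactors = FALSE)
  }
  control <- do.call(rbind, lapply(seq_len(config$n_controls), function(i)
    draw_background(sprintf("CTL%04d", i), "control")))
  case <- do.call(rbind, lapply(seq_len(config$n_cases), function(i) {
    d <- draw_background(sprintf("CASE%04d", i), "case")
    if (stats::runif(1) < config$causal_hit_rate) {
      lgd <- stats::runif(1) < 0.3
      d <- rbind(d, data.frame(
        proband_id = d$proband_id[1], cohort = "case",
        gene_symbol = sample(intol, 1),
        effect = if (lgd) "LGD" else "missense",
        pp2_score = if (lgd) NA_real_ else stats::runif(1, 0.95, 1),
        stringsAsFactors = FALSE))
    }
    d
  }))
  rownames(case) <- rownames(control) <- NULL
  list(case = case, control = control)
}
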