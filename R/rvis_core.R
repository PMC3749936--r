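# Core of the intolerance score: per-gene tallies (X, Y), the genome-wide
# regression of Y on X, studentized residuals S, and percentile ranks.

#' Tally a gene's predictor and response counts
#'
#' X is the total number of qualifying protein-coding site-alleles in the
#' gene — functional and synonymous alike, regardless of frequency (in pp2
#' mode, benign-relabeled missense still count toward X).  Y is the number
#' of common (MAF > rho) FUNCTIONAL site-alleles.  X measures mutational
#' burden; Y is the quantity whose shortfall, given X, signals intolerance.
#'
#' @param records qualifying variant records of one gene.
#' @inheritParams is_common
#' @inheritParams classify_variant
#' @return list with \code{gene_symbol}, \code{x_total},
#'   \code{y_common_functional}.
#' @export
tally_gene <- function(records, rho = 0.1, population = "ALL",
                       mode = "standard", missing_pp2 = "error") {
  if (nrow(records) == 0L) {
    return(list(gene_symbol = NA_character_, x_total = 0L,
                y_common_functional = 0L))
  }
  gene <- unique(as.character(records$gene_symbol))
  if (length(gene) != 1L)
    stop("tally_gene received records spanning multiple genes: ",
         paste(gene, collapse = ", "))
  cls <- classify_variant(records, mode = mode, missing_pp2 = missing_pp2)
  counted <- cls %in% c("FUNCTIONAL", "NON_FUNCTIONAL")
  common <- is_common(records, rho = rho, population = population)
  list(gene_symbol = gene,
       x_total = sum(counted),
       y_common_functional = sum(cls == "FUNCTIONAL" & common))
}

#' Fit the genome-wide regression of common functional variation on burden
#'
#' Ordinary least squares of Y on X with intercept, across all scored
#' genes.  The fitted line is the genome-wide expectation of common
#' functional variation for a given mutational burden; per-gene leverages
#' (hat diagonal) and the residual standard deviation feed studentization.
#'
#' @param tallies data.frame with columns \code{gene_symbol},
#'   \code{x_total}, \code{y_common_functional}.
#' @return list with \code{intercept}, \code{slope}, \code{residual_std}
#'   (\eqn{\sqrt{SSE/(n-2)}}), \code{leverage} (named per-gene),
#'   \code{residuals} (raw, named), \code{n_genes}, and the underlying
#'   \code{lm} fit.
#' @export
fit_regression <- function(tallies) {
  n <- nrow(tallies)
  if (n < 3L) stop("insufficient data: regression needs >= 3 genes")
  x <- as.numeric(tallies$x_total)
  y <- as.numeric(tallies$y_common_functional)
  if (length(unique(x)) < 2L)
    stop("degenerate design: X is constant across genes")
  fit <- stats::lm(y ~ x)
  r <- stats::residuals(fit)
  h <- stats::hatvalues(fit)
  names(r) <- names(h) <- as.character(tallies$gene_symbol)
  list(intercept = unname(stats::coef(fit)[1L]),
       slope = unname(stats::coef(fit)[2L]),
       residual_std = sqrt(sum(r^2) / (n - 2L)),
       leverage = h,
       residuals = r,
       n_genes = n,
       lm_fit = fit)
}

#' Studentize the regression residuals into intolerance scores
#'
#' The raw residual is divided by an estimate of its standard deviation,
#' which shrinks with leverage, so genes at extreme mutational burdens are
#' not over- or under-penalized.  Internal studentization (default) uses
#' the overall residual standard deviation:
#' \eqn{S_i = r_i / (\hat\sigma \sqrt{1 - h_{ii}})}.  External
#' studentization re-estimates \eqn{\hat\sigma} excluding gene i.
#'
#' @param fit a \code{\link{fit_regression}} result.
#' @param studentization \code{"internal"} or \code{"external"}.
#' @return named numeric vector of scores S (negative = less common
#'   functional variation than predicted, i.e. intolerant).
#' @export
studentize <- function(fit, studentization = c("internal", "external")) {
  studentization <- match.arg(studentization)
  r <- fit$residuals
  h <- fit$leverage
  scale <- max(1, abs(stats::fitted(fit$lm_fit)))
  if (fit$residual_std <= 1e-10 * scale)
    stop("degenerate fit: residual standard deviation is (numerically) zero")
  if (any(1 - h <= .Machine$double.eps^0.5))
    stop("undefined score: leverage of 1 for gene(s) ",
         paste(names(h)[1 - h <= .Machine$double.eps^0.5], collapse = ", "))
  if (studentization == "internal") {
    r / (fit$residual_std * sqrt(1 - h))
  } else {
    n <- fit$n_genes
    sse <- sum(r^2)
    s_i <- sqrt((sse - r^2 / (1 - h)) / (n - 3L))
    r / (s_i * sqrt(1 - h))
  }
}

#' Percentile ranks of intolerance scores
#'
#' \code{100 * rank / N} with average ranks for ties; the lowest score
#' (most intolerant gene) receives the lowest percentile.
#'
#' @param scores numeric vector of scores S.
#' @return numeric vector of percentiles in (0, 100].
#' @export
percentile_rank <- function(scores) {
  if (!length(scores)) stop("no scores to rank")
  100 * rank(scores, ties.method = "average") / length(scores)
}

#' Default scoring configuration
#'
#' @param rho common/rare MAF threshold in percent.
#' @param population MAF population: ALL, EA or AA.
#' @param mode variant classification mode: standard or pp2.
#' @param min_depth minimum mean depth for a site to be assessed.
#' @param min_fraction minimum covered fraction for gene assessability.
#' @param splice_pad exon widening in bp for splice sites.
#' @param studentization internal or external.
#' @param hot_zone_x minimum damaging score of the hot zone.
#' @param hot_zone_y maximum percentile/100 of the hot zone.
#' @param missing_pp2 handling of unlabeled missense in pp2 mode.
#' @return a validated list of settings.
#' @export
rvis_config <- function(rho = 0.1, population = "ALL", mode = "standard",
                        min_depth = 10, min_fraction = 0.70, splice_pad = 2L,
                        studentization = "internal",
                        hot_zone_x = 0.95, hot_zone_y = 0.25,
                        missing_pp2 = "error") {
  population <- match.arg(population, c("ALL", "EA", "AA"))
  mode <- match.arg(mode, c("standard", "pp2"))
  studentization <- match.arg(studentization, c("internal", "external"))
  missing_pp2 <- match.arg(missing_pp2, c("error", "exclude"))
  stopifnot(rho > 0, rho < 100, min_depth > 0,
            min_fraction > 0, min_fraction <= 1, splice_pad >= 0,
            hot_zone_x >= 0, hot_zone_x <= 1,
            hot_zone_y > 0, hot_zone_y <= 1)
  list(rho = rho, population = population, mode = mode,
       min_depth = min_depth, min_fraction = min_fraction,
       splice_pad = as.integer(splice_pad), studentization = studentization,
       hot_zone_x = hot_zone_x, hot_zone_y = hot_zone_y,
       missing_pp2 = missing_pp2)
}

#' Compute intolerance scores for a whole variant table
#'
#' End-to-end pipeline: consolidate transcripts into splice-padded gene
#' footprints, mask by coverage and drop unassessable genes, filter and
#' classify qualifying variants, tally per-gene (X, Y), fit the
#' genome-wide regression, studentize, and rank.  Deterministic given
#' inputs and configuration; genes with no qualifying variants are
#' retained with X = Y = 0 and scored.
#'
#' @param variants variant record data.frame (see \code{\link{qualify}}).
#' @param transcripts exon table (see \code{\link{merge_transcripts}}).
#' @param coverage depth intervals (see \code{\link{apply_coverage}}).
#' @param config a \code{\link{rvis_config}} list.
#' @param verbose log filtering-stage counts and the fitted line.
#' @return object of class \code{rvis_scores}: list with \code{scores}
#'   (data.frame: gene_symbol, x_total, y_common_functional, score,
#'   percentile), \code{unassessable} (data.frame with reasons),
#'   \code{fit}, \code{config}, and per-stage \code{counts}.
#' @export
compute_rvis <- function(variants, transcripts, coverage,
                         config = rvis_config(), verbose = FALSE) {
  regions <- build_gene_regions(transcripts, coverage,
                                splice_pad = config$splice_pad,
                                min_depth = config$min_depth,
                                min_fraction = config$min_fraction)
  assessable <- vapply(regions, function(r) isTRUE(r$assessable), logical(1))
  unassessable <- if (any(!assessable)) {
    data.frame(gene_symbol = names(regions)[!assessable],
               reason = sprintf("covered fraction %.3f < %.2f",
                                vapply(regions[!assessable],
                                       function(r) r$covered_sites / r$total_sites,
                                       numeric(1)),
                                config$min_fraction),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(gene_symbol = character(0), reason = character(0))
  }
  regions <- regions[assessable]
  if (length(regions) < 3L)
    stop("fewer than 3 assessable genes; cannot fit the regression")

  genes <- sort(names(regions))
  variants$gene_symbol <- as.character(variants$gene_symbol)
  by_gene <- split(variants, variants$gene_symbol)
  n_input <- nrow(variants)
  n_qual <- 0L
  tallies <- lapply(genes, function(g) {
    recs <- by_gene[[g]]
    if (is.null(recs) || nrow(recs) == 0L)
      return(list(gene_symbol = g, x_total = 0L, y_common_functional = 0L))
    q <- qualify(recs, regions[[g]])
    n_qual <<- n_qual + sum(q)
    t <- tally_gene(recs[q, , drop = FALSE], rho = config$rho,
                    population = config$population, mode = config$mode,
                    missing_pp2 = config$missing_pp2)
    t$gene_symbol <- g
    t
  })
  tallies <- data.frame(
    gene_symbol = vapply(tallies, `[[`, character(1), "gene_symbol"),
    x_total = vapply(tallies, `[[`, numeric(1), "x_total"),
    y_common_functional = vapply(tallies, `[[`, numeric(1),
                                 "y_common_functional"),
    stringsAsFactors = FALSE
  )

  fit <- fit_regression(tallies)
  s <- studentize(fit, studentization = config$studentization)
  pct <- percentile_rank(s)
  scores <- data.frame(gene_symbol = tallies$gene_symbol,
                       x_total = as.integer(tallies$x_total),
                       y_common_functional = as.integer(tallies$y_common_functional),
                       score = unname(s), percentile = unname(pct),
                       stringsAsFactors = FALSE)
  if (verbose) {
    message(sprintf(
      "genes: %d assessable, %d dropped; variants: %d in, %d qualifying; fit: Y = %.4f + %.4f X",
      length(genes), nrow(unassessable), n_input, n_qual,
      fit$intercept, fit$slope))
  }
  out <- list(scores = scores, unassessable = unassessable,
              fit = fit[c("intercept", "slope", "residual_std", "n_genes")],
              config = config,
              counts = c(n_variants_in = n_input, n_qualifying = n_qual,
                         n_genes_assessable = length(genes),
                         n_genes_dropped = nrow(unassessable)))
  class(out) <- "rvis_scores"
  out
}

#' @export
print.rvis_scores <- function(x, ...) {
  cat(sprintf(
    "<rvis_scores> %d genes (rho=%g%%, %s, %s mode)\n  fit: Y = %.4f + %.4f X, sigma = %.4f\n",
    nrow(x$scores), x$config$rho, x$config$population, x$config$mode,
    x$fit$intercept, x$fit$slope, x$fit$residual_std))
  most <- x$scores[order(x$scores$score), ][seq_len(min(5L, nrow(x$scores))), ]
  cat("  most intolerant:\n")
  for (i in seq_len(nrow(most)))
    cat(sprintf("    %-12s S=%8.4f  pct=%6.2f\n", most$gene_symbol[i],
                most$score[i], most$percentile[i]))
  invisible(x)
}
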