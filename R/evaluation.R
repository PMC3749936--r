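# Evaluation of a score table against curated gene lists: logistic
# association, ROC/AUC with DeLong CIs, rank-sum comparison, score-table
# correlations and disorder-class style group summaries.

.score_vector <- function(scores) {
  if (inherits(scores, "rvis_scores")) scores <- scores$scores
  stopifnot(is.data.frame(scores),
            all(c("gene_symbol", "score") %in% names(scores)))
  stats::setNames(scores$score, as.character(scores$gene_symbol))
}

.membership <- function(s, members, background = NULL) {
  members <- unique(as.character(members))
  unresolved <- setdiff(members, names(s))
  if (length(unresolved))
    message(length(unresolved), " list symbol(s) not scored: ",
            paste(utils::head(unresolved, 10), collapse = ", "),
            if (length(unresolved) > 10) ", ..." else "")
  inlist <- names(s) %in% members
  keep <- if (is.null(background)) rep(TRUE, length(s))
          else inlist | names(s) %in% as.character(background)
  list(y = as.integer(inlist[keep]), s = s[keep], unresolved = unresolved)
}

#' Logistic association between list membership and intolerance score
#'
#' Regresses the presence/absence of each scored gene in the list on its
#' score (single covariate plus intercept).  A negative coefficient means
#' list genes have lower (more intolerant) scores than the background.
#'
#' @param scores an \code{rvis_scores} object or its \code{scores}
#'   data.frame (columns \code{gene_symbol}, \code{score}).
#' @param members character vector of list gene symbols.
#' @param background optional character vector restricting the comparison
#'   genes; default is all scored genes not in the list.
#' @return list with \code{beta}, \code{beta_ci95}, \code{p},
#'   \code{n_members_scored}, \code{n_background}, \code{separation}
#'   (TRUE when the fit is unreliable due to perfect separation).
#' @export
logistic_association <- function(scores, members, background = NULL) {
  m <- .membership(.score_vector(scores), members, background)
  if (sum(m$y) < 2L || sum(1 - m$y) < 2L)
    stop("need >= 2 scored members and >= 2 background genes")
  fit <- suppressWarnings(stats::glm(m$y ~ m$s, family = stats::binomial()))
  co <- summary(fit)$coefficients
  beta <- co["m$s", "Estimate"]
  se <- co["m$s", "Std. Error"]
  sep <- !fit$converged || se > 1e3
  if (sep) warning("possible perfect separation: coefficient unreliable")
  list(beta = beta,
       beta_ci95 = beta + c(-1, 1) * stats::qnorm(0.975) * se,
       p = co["m$s", "Pr(>|z|)"],
       n_members_scored = sum(m$y), n_background = sum(1 - m$y),
       separation = sep)
}

#' ROC AUC with DeLong confidence interval for a gene list
#'
#' Area under the empirical ROC curve for the score as a predictor of
#' list membership, with ties at the midpoint convention and the DeLong
#' nonparametric variance for the 95 percent CI.  By default low scores
#' (intolerance) predict membership, so an informative list yields
#' AUC > 0.5.
#'
#' @inheritParams logistic_association
#' @param direction \code{"lower"} (default: lower score predicts
#'   membership) or \code{"higher"}.
#' @return list with \code{auc}, \code{auc_ci95}, \code{n_members_scored},
#'   \code{n_background}.
#' @export
roc_auc_delong <- function(scores, members, background = NULL,
                           direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  m <- .membership(.score_vector(scores), members, background)
  if (sum(m$y) == 0L || sum(1 - m$y) == 0L)
    stop("both classes must be non-empty for a ROC curve")
  roc <- pROC::roc(response = m$y, predictor = as.numeric(m$s),
                   levels = c(0, 1),
                   direction = if (direction == "lower") ">" else "<",
                   quiet = TRUE)
  ci <- pROC::ci.auc(roc, method = "delong")
  list(auc = as.numeric(pROC::auc(roc)),
       auc_ci95 = as.numeric(ci[c(1, 3)]),
       n_members_scored = sum(m$y), n_background = sum(1 - m$y))
}

#' Mann-Whitney U comparison of list and background scores
#'
#' Two-tailed rank-sum test of the list genes' scores against the
#' background genes' scores, with tie correction; exact below 25 total
#' observations (no ties), normal approximation with continuity
#' correction otherwise.  U is reported for the list genes oriented so
#' that \eqn{U/(n_1 n_2)} equals the AUC of the higher-predicts-member
#' direction.
#'
#' @inheritParams logistic_association
#' @return list with \code{u}, \code{p}, \code{n_members_scored},
#'   \code{n_background}.
#' @export
mann_whitney <- function(scores, members, background = NULL) {
  m <- .membership(.score_vector(scores), members, background)
  xs <- as.numeric(m$s[m$y == 1])
  ys <- as.numeric(m$s[m$y == 0])
  if (!length(xs) || !length(ys)) stop("both groups must be non-empty")
  exact <- (length(xs) + length(ys)) < 25
  wt <- suppressWarnings(stats::wilcox.test(xs, ys, exact = exact,
                                            correct = TRUE))
  list(u = unname(wt$statistic), p = wt$p.value,
       n_members_scored = length(xs), n_background = length(ys))
}

#' Pearson correlation between two score tables
#'
#' Joins on gene symbol and reports Pearson's r with a Fisher-z 95
#' percent CI — the sensitivity comparison used across frequency
#' thresholds and subpopulations.
#'
#' @param table_a,table_b \code{rvis_scores} objects or score data.frames.
#' @return list with \code{r}, \code{r_ci95}, \code{n_joined},
#'   \code{n_dropped}.
#' @export
score_correlation <- function(table_a, table_b) {
  a <- .score_vector(table_a)
  b <- .score_vector(table_b)
  common <- intersect(names(a), names(b))
  if (length(common) < 3L)
    stop("need >= 3 genes in the intersection of the two tables")
  ct <- stats::cor.test(a[common], b[common], method = "pearson")
  list(r = unname(ct$estimate), r_ci95 = as.numeric(ct$conf.int),
       n_joined = length(common),
       n_dropped = length(a) + length(b) - 2L * length(common))
}

#' Summarize a gene list's position in the score distribution
#'
#' Mean score of the list members; the percentile at which that mean falls
#' within the full score distribution (empirical CDF x 100, i.e. a score
#' value mapped onto the genome-wide ranking); and the proportion of
#' members in each 25-percentile bin of the ranking.
#'
#' @inheritParams logistic_association
#' @param bin_edges internal percentile cut points (default quartiles).
#' @return list with \code{mean_score}, \code{percentile_of_mean},
#'   \code{bin_proportions} (named, summing to 1),
#'   \code{n_members_scored}, \code{unresolved}.
#' @export
group_summary <- function(scores, members, bin_edges = c(25, 50, 75)) {
  if (inherits(scores, "rvis_scores")) scores <- scores$scores
  stopifnot(all(c("gene_symbol", "score", "percentile") %in% names(scores)))
  members <- unique(as.character(members))
  hit <- scores$gene_symbol %in% members
  unresolved <- setdiff(members, scores$gene_symbol)
  if (!any(hit))
    stop("no list member was scored; unresolved symbols: ",
         paste(unresolved, collapse = ", "))
  mean_s <- mean(scores$score[hit])
  pct_of_mean <- 100 * mean(scores$score <= mean_s)
  edges <- c(0, sort(bin_edges), 100)
  bins <- cut(scores$percentile[hit], breaks = edges,
              include.lowest = TRUE, right = TRUE)
  prop <- as.numeric(table(bins)) / sum(hit)
  names(prop) <- sprintf("(%g,%g]", edges[-length(edges)], edges[-1])
  list(mean_score = mean_s, percentile_of_mean = pct_of_mean,
       bin_proportions = prop, n_members_scored = sum(hit),
       unresolved = unresolved)
}
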