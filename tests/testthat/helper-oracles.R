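# Independent oracles used across the suite.  Each recomputes a quantity
# by brute force / first principles, never through the code path it checks.

# per-base set union of padded exons (0-based half-open intervals)
oracle_union_sites <- function(starts, ends, pad = 0L) {
  sites <- unlist(mapply(function(s, e) seq(s - pad, e + pad - 1L),
                         starts, ends, SIMPLIFY = FALSE))
  sort(unique(sites))
}

# OLS of y on x via explicit normal equations, with hat diagonal and
# internally studentized residuals
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% y
  H <- X %*% XtX_inv %*% t(X)
  r <- as.numeric(y - X %*% beta)
  n <- length(y)
  sigma <- sqrt(sum(r^2) / (n - 2))
  list(intercept = beta[1], slope = beta[2], residuals = r,
       leverage = diag(H), sigma = sigma,
       student = r / (sigma * sqrt(1 - diag(H))))
}

# AUC by exhaustive pair counting, ties = 1/2; "positive" scores predicted
# by LOWER values when direction = "lower"
oracle_auc <- function(pos_scores, neg_scores, direction = "lower") {
  won <- if (direction == "lower") outer(pos_scores, neg_scores, "<")
         else outer(pos_scores, neg_scores, ">")
  tie <- outer(pos_scores, neg_scores, "==")
  (sum(won) + 0.5 * sum(tie)) / (length(pos_scores) * length(neg_scores))
}

# two-tailed Fisher exact p by hypergeometric tail summation over all
# tables with the observed margins
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# two-tailed exact binomial p: sum of outcome probabilities <= P(observed)
oracle_binom_p <- function(k, n, p0) {
  probs <- stats::dbinom(0:n, n, p0)
  p_obs <- probs[k + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# logistic regression by hand-rolled iteratively reweighted least squares
oracle_irls_logistic <- function(y, x, tol = 1e-12, maxit = 100) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (i in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(t(X) %*% (w * X), t(X) %*% (w * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  as.numeric(beta)
}

# a small fully covered multi-gene fixture built directly from the types
make_tiny_dataset <- function(n_genes = 6, seed = 42,
                              x_counts = NULL, y_counts = NULL) {
  set.seed(seed)
  genes <- sprintf("G%02d", seq_len(n_genes))
  gene_len <- 400L
  start <- (seq_len(n_genes) - 1L) * 10000L
  transcripts <- data.frame(gene_symbol = genes, transcript_id = paste0(genes, ".1"),
                            chrom = "chrT", start = start,
                            end = start + gene_len, strand = "+",
                            stringsAsFactors = FALSE)
  coverage <- data.frame(chrom = "chrT", start = 0L,
                         end = max(start) + gene_len + 10L, mean_depth = 50)
  if (is.null(x_counts)) x_counts <- 10L * seq_len(n_genes)
  if (is.null(y_counts)) y_counts <- pmin(x_counts, c(1, 3, 2, 6, 4, 8)[seq_len(n_genes)])
  rows <- lapply(seq_len(n_genes), function(i) {
    nx <- x_counts[i]; ny <- y_counts[i]
    eff <- c(rep("missense", ny), rep("coding-synonymous", nx - ny))
    maf <- c(rep(5, ny), rep(0.01, nx - ny))
    data.frame(gene_symbol = genes[i], chrom = "chrT",
               pos = start[i] + seq_len(nx) - 1L,
               ref_allele = "A", alt_allele = "G", effect = eff,
               maf_all = maf, maf_ea = maf, maf_aa = maf,
               filter_status = "PASS", pp2_label = NA_character_,
               pp2_score = NA_real_, stringsAsFactors = FALSE)
  })
  list(transcripts = transcripts, coverage = coverage,
       variants = do.call(rbind, rows),
       x = x_counts, y = y_counts, genes = genes)
}
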