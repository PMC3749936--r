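# Shared readers and writers.  TSV everywhere with '#'-prefixed header
# metadata; gene symbols are case-sensitive unless uppercase normalization
# is requested.  BED inputs keep their native 0-based half-open
# coordinates, which is also the package's internal convention.

.default_variant_columns <- c(
  gene_symbol = "gene_symbol", chrom = "chrom", pos = "pos",
  ref_allele = "ref_allele", alt_allele = "alt_allele", effect = "effect",
  maf_all = "maf_all", maf_ea = "maf_ea", maf_aa = "maf_aa",
  filter_status = "filter_status", pp2_label = "pp2_label",
  pp2_score = "pp2_score")

#' Read a cohort variant-site table (EVS-style TSV)
#'
#' Tab-separated with a header line; a configurable column map translates
#' the file's column names onto the package's record fields.  A combined
#' \code{maf_percent} column of the form \code{"EA/AA/All"} is split into
#' the three population MAFs.  Lines whose MAF or position fail to parse
#' are skipped with a line-numbered warning.
#'
#' @param path file path.
#' @param column_map named character vector mapping record fields (names)
#'   to file columns (values); defaults assume the package's own layout.
#' @param uppercase_genes normalize gene symbols to upper case.
#' @return data.frame of variant records; attribute \code{n_skipped}
#'   counts dropped lines.
#' @export
read_variant_table <- function(path, column_map = NULL,
                               uppercase_genes = FALSE) {
  if (!file.exists(path)) stop("variant table not found: ", path)
  cm <- .default_variant_columns
  if (!is.null(column_map)) cm[names(column_map)] <- column_map
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE)
  has_combined <- "maf_percent" %in% names(cm) && cm[["maf_percent"]] %in% names(raw)
  required <- c("gene_symbol", "chrom", "pos", "ref_allele", "alt_allele",
                "effect", "filter_status",
                if (!has_combined) "maf_all")
  miss <- required[!cm[required] %in% names(raw)]
  if (length(miss))
    stop("variant table missing required column(s): ",
         paste(cm[miss], collapse = ", "))
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (f in names(.default_variant_columns)) {
    src <- cm[[f]]
    out[[f]] <- if (!is.null(src) && src %in% names(raw)) raw[[src]]
                else NA
  }
  if (has_combined) {
    parts <- strsplit(as.character(raw[[cm[["maf_percent"]]]]), "/", fixed = TRUE)
    grab <- function(i) suppressWarnings(
      as.numeric(vapply(parts, function(p) if (length(p) >= i) p[i] else NA_character_,
                        character(1))))
    out$maf_ea <- grab(1); out$maf_aa <- grab(2); out$maf_all <- grab(3)
  }
  for (f in c("gene_symbol", "chrom", "ref_allele", "alt_allele", "effect",
              "filter_status", "pp2_label"))
    out[[f]] <- as.character(out[[f]])
  out$pos <- suppressWarnings(as.integer(out$pos))
  for (f in c("maf_all", "maf_ea", "maf_aa", "pp2_score"))
    out[[f]] <- suppressWarnings(as.numeric(out[[f]]))
  bad <- is.na(out$pos) | is.na(out$maf_all)
  if (any(bad))
    warning(sum(bad), " line(s) skipped (unparseable position or MAF): ",
            paste(utils::head(which(bad) + 1L, 10), collapse = ", "))
  out <- out[!bad, , drop = FALSE]
  if (uppercase_genes) out$gene_symbol <- toupper(out$gene_symbol)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Read a site-level VCF into variant records
#'
#' Minimal VCF support: the fixed columns plus INFO keys named by
#' \code{info_map} (effect, per-population MAFs, optional PolyPhen-2
#' label/score).  Multi-allelic sites expand to one record per alternate
#' allele, with comma-separated per-allele INFO values split accordingly.
#' The FILTER column drives PASS logic.  VCF POS is 1-based; records are
#' converted to the package's 0-based convention.
#'
#' @param path VCF file path (uncompressed).
#' @param info_map named character vector mapping fields
#'   (\code{gene_symbol}, \code{effect}, \code{maf_all}, \code{maf_ea},
#'   \code{maf_aa}, \code{pp2_label}, \code{pp2_score}) to INFO keys.
#' @param uppercase_genes normalize gene symbols to upper case.
#' @return data.frame of variant records.
#' @export
read_variant_vcf <- function(path,
                             info_map = c(gene_symbol = "GENE",
                                          effect = "FG", maf_all = "MAF_ALL",
                                          maf_ea = "MAF_EA", maf_aa = "MAF_AA",
                                          pp2_label = "PP2_LABEL",
                                          pp2_score = "PP2_SCORE"),
                             uppercase_genes = FALSE) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) stop("VCF contains no variant records: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 8L)) stop("malformed VCF line(s) in ", path)
  info_get <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
           character(1))
  }
  rows <- lapply(fields, function(f) {
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    info <- f[8]
    vals <- lapply(info_map, function(k) {
      v <- info_get(info, k)
      strsplit(ifelse(is.na(v), NA_character_, v), ",", fixed = TRUE)[[1]]
    })
    per_alt <- function(v, i) {
      if (length(v) == 0L || all(is.na(v))) NA_character_
      else if (length(v) >= i) v[i] else v[1]
    }
    do.call(rbind, lapply(seq_along(alts), function(i) {
      data.frame(gene_symbol = per_alt(vals$gene_symbol, i),
                 chrom = f[1], pos = as.integer(f[2]) - 1L,
                 ref_allele = f[4], alt_allele = alts[i],
                 effect = per_alt(vals$effect, i),
                 maf_all = suppressWarnings(as.numeric(per_alt(vals$maf_all, i))),
                 maf_ea = suppressWarnings(as.numeric(per_alt(vals$maf_ea, i))),
                 maf_aa = suppressWarnings(as.numeric(per_alt(vals$maf_aa, i))),
                 filter_status = f[7],
                 pp2_label = per_alt(vals$pp2_label, i),
                 pp2_score = suppressWarnings(as.numeric(per_alt(vals$pp2_score, i))),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (uppercase_genes) out$gene_symbol <- toupper(out$gene_symbol)
  rownames(out) <- NULL
  out
}

#' Read transcript exon definitions from BED
#'
#' BED4+ where the name column is \code{gene|transcript} (or just the gene
#' symbol); coordinates stay 0-based half-open.
#'
#' @param path BED file path.
#' @return exon data.frame for \code{\link{merge_transcripts}}.
#' @export
read_transcripts_bed <- function(path) {
  if (!file.exists(path)) stop("transcript BED not found: ", path)
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(bed) < 4L) stop("transcript BED needs 4+ columns (name = gene|transcript)")
  name <- strsplit(as.character(bed[[4]]), "|", fixed = TRUE)
  data.frame(gene_symbol = vapply(name, `[`, character(1), 1),
             transcript_id = vapply(name, function(x)
               if (length(x) > 1L) x[2] else x[1], character(1)),
             chrom = as.character(bed[[1]]),
             start = as.integer(bed[[2]]), end = as.integer(bed[[3]]),
             strand = if (ncol(bed) >= 6L) as.character(bed[[6]]) else "+",
             stringsAsFactors = FALSE)
}

#' Read a coverage summary (BED-like TSV of mean depths)
#'
#' @param path file with columns chrom, start, end, mean_depth.
#' @return coverage data.frame for \code{\link{apply_coverage}}.
#' @export
read_coverage_bed <- function(path) {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(bed) < 4L) stop("coverage file needs chrom, start, end, mean_depth")
  data.frame(chrom = as.character(bed[[1]]), start = as.integer(bed[[2]]),
             end = as.integer(bed[[3]]), mean_depth = as.numeric(bed[[4]]),
             stringsAsFactors = FALSE)
}

#' Read a plain-text gene list
#'
#' One symbol per line, '#' comments allowed; duplicates removed with a
#' warning.
#'
#' @param path file path.
#' @param uppercase_genes normalize symbols to upper case.
#' @return character vector of unique symbols.
#' @export
read_gene_list <- function(path, uppercase_genes = FALSE) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (uppercase_genes) lines <- toupper(lines)
  dup <- duplicated(lines)
  if (any(dup))
    warning(sum(dup), " duplicate symbol(s) removed from ", basename(path))
  unique(lines)
}

#' Read a de novo mutation table
#'
#' TSV with columns proband_id, cohort, gene_symbol, effect (missense /
#' LGD / silent), pp2_score.
#'
#' @param path file path.
#' @param uppercase_genes normalize symbols to upper case.
#' @return data.frame.
#' @export
read_denovo_table <- function(path, uppercase_genes = FALSE) {
  if (!file.exists(path)) stop("de novo table not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         comment.char = "#", stringsAsFactors = FALSE)
  need <- c("proband_id", "cohort", "gene_symbol", "effect", "pp2_score")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("de novo table missing column(s): ", paste(miss, collapse = ", "))
  if (uppercase_genes) d$gene_symbol <- toupper(d$gene_symbol)
  d$pp2_score <- suppressWarnings(as.numeric(d$pp2_score))
  d
}

#' Write a score table to TSV
#'
#' Scores print to 4 decimals and percentiles to 2; run configuration is
#' stamped in '#'-prefixed header lines so a table is self-describing.
#'
#' @param result an \code{rvis_scores} object.
#' @param path output path.
#' @export
write_score_table <- function(result, path) {
  stopifnot(inherits(result, "rvis_scores"))
  cfg <- result$config
  hdr <- c(sprintf("# rvis score table"),
           sprintf("# rho=%g population=%s mode=%s studentization=%s",
                   cfg$rho, cfg$population, cfg$mode, cfg$studentization),
           sprintf("# min_depth=%g min_fraction=%g splice_pad=%d",
                   cfg$min_depth, cfg$min_fraction, cfg$splice_pad),
           sprintf("# fit intercept=%.10g slope=%.10g residual_std=%.10g n=%d",
                   result$fit$intercept, result$fit$slope,
                   result$fit$residual_std, result$fit$n_genes))
  tab <- result$scores
  tab$score <- sprintf("%.4f", tab$score)
  tab$percentile <- sprintf("%.2f", tab$percentile)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score table written by \code{\link{write_score_table}}
#'
#' Also accepts any TSV with at least \code{gene_symbol}, \code{score} and
#' \code{percentile} columns (e.g. an externally published score table).
#'
#' @param path file path.
#' @return score data.frame.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop("score table not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene_symbol", "score", "percentile")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("score table missing column(s): ", paste(miss, collapse = ", "))
  tab$score <- as.numeric(tab$score)
  tab$percentile <- as.numeric(tab$percentile)
  tab
}

#' Write a generic result table with a comment header
#'
#' @param table data.frame to write.
#' @param path output path.
#' @param header character vector of '#'-prefixed metadata lines.
#' @export
write_report <- function(table, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", sub("^#\\s*", "", header)), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the simulator's outputs in the package's standard input formats
#'
#' @param sim result of \code{\link{simulate_exome}}.
#' @param dir output directory (created if needed).
#' @return named vector of file paths (transcripts.bed, coverage.bed,
#'   variants.tsv, truth.tsv).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(transcripts = file.path(dir, "transcripts.bed"),
             coverage = file.path(dir, "coverage.bed"),
             variants = file.path(dir, "variants.tsv"),
             truth = file.path(dir, "truth.tsv"))
  tx <- sim$transcripts
  bed <- data.frame(tx$chrom, tx$start, tx$end,
                    paste(tx$gene_symbol, tx$transcript_id, sep = "|"),
                    0L, tx$strand)
  utils::write.table(bed, paths["transcripts"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$coverage, paths["coverage"], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$variants, paths["variants"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}
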