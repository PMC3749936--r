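# Internal convention: genomic intervals are 0-based half-open everywhere
# inside the package; IRanges (1-based closed) is used for the arithmetic
# and converted at the boundary.  File readers/writers translate to the
# convention of the format they speak (BED is already 0-based half-open).

.to_iranges <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

.from_iranges <- function(ir) {
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Merge a gene's transcript exons into one consolidated coding footprint
#'
#' All exons of one gene symbol (across any number of transcripts) are
#' widened by \code{splice_pad} bases on each side, to admit splice
#' acceptor/donor sites, and their union taken.  Overlapping or bookended
#' padded exons coalesce, so a variant annotated against several
#' transcripts occupies a single consolidated position.
#'
#' @param exons data.frame with columns \code{gene_symbol},
#'   \code{transcript_id}, \code{chrom}, \code{start}, \code{end} and
#'   optionally \code{strand}; coordinates 0-based half-open.
#' @param splice_pad non-negative integer widening applied to both ends of
#'   every exon (default 2, the splice acceptor/donor allowance).
#' @return A \code{gene_region} object: list with \code{gene_symbol},
#'   \code{chrom}, \code{intervals} (data.frame of disjoint sorted 0-based
#'   half-open intervals), \code{total_sites}, and unset coverage fields
#'   (\code{covered_sites = NA}, \code{assessable = NA}).
#' @examples
#' exons <- data.frame(gene_symbol = "G1", transcript_id = "T1",
#'                     chrom = "chr1", start = 100, end = 200)
#' merge_transcripts(exons, splice_pad = 2)$total_sites  # 104
#' @export
merge_transcripts <- function(exons, splice_pad = 2L) {
  if (!is.data.frame(exons) || nrow(exons) == 0L)
    stop("empty exon set: at least one exon is required")
  need <- c("gene_symbol", "chrom", "start", "end")
  miss <- setdiff(need, names(exons))
  if (length(miss))
    stop("exon table missing column(s): ", paste(miss, collapse = ", "))
  if (splice_pad < 0) stop("splice_pad must be >= 0")
  gene <- unique(as.character(exons$gene_symbol))
  if (length(gene) != 1L)
    stop("mixed gene symbols in one merge: ", paste(gene, collapse = ", "))
  chrom <- unique(as.character(exons$chrom))
  if (length(chrom) != 1L)
    stop("gene '", gene, "' spans multiple chromosomes (",
         paste(chrom, collapse = ", "), "); symbol collisions are rejected")
  if (any(exons$start >= exons$end))
    stop("exon with start >= end for gene '", gene, "'")
  padded <- .to_iranges(as.integer(exons$start) - as.integer(splice_pad),
                        as.integer(exons$end) + as.integer(splice_pad))
  merged <- IRanges::reduce(padded)
  region <- list(
    gene_symbol   = gene,
    chrom         = chrom,
    intervals     = .from_iranges(merged),
    total_sites   = sum(IRanges::width(merged)),
    covered       = NULL,      # IRanges mask set by apply_coverage()
    covered_sites = NA_integer_,
    assessable    = NA
  )
  class(region) <- "gene_region"
  region
}

#' Apply a coverage mask to a gene region and decide assessability
#'
#' Restricts the consolidated footprint to sites whose mean sequencing
#' depth reaches \code{min_depth}; a gene is assessable when at least
#' \code{min_fraction} of its footprint survives (defaults: 10-fold depth
#' over at least 70 percent of sites).  Sites absent from the coverage
#' profile are treated as depth 0.  The surviving-site mask is retained so
#' variant filtering can reject variants at uncovered positions.
#'
#' @param region a \code{gene_region} from \code{\link{merge_transcripts}}.
#' @param coverage data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open) and \code{mean_depth}.
#' @param min_depth minimum mean depth for a site to count (> 0).
#' @param min_fraction minimum covered fraction for assessability (0,1].
#' @return the region with \code{covered}, \code{covered_sites} and
#'   \code{assessable} filled in.
#' @export
apply_coverage <- function(region, coverage, min_depth = 10, min_fraction = 0.70) {
  stopifnot(inherits(region, "gene_region"))
  if (region$total_sites == 0L) stop("empty region")
  if (min_depth <= 0) stop("min_depth must be > 0")
  if (min_fraction <= 0 || min_fraction > 1) stop("min_fraction must be in (0, 1]")
  footprint <- .to_iranges(region$intervals$start, region$intervals$end)
  if (is.null(coverage) || nrow(coverage) == 0L) {
    deep <- IRanges::IRanges()
  } else {
    keep <- coverage$chrom == region$chrom & coverage$mean_depth >= min_depth
    cov <- coverage[keep, , drop = FALSE]
    deep <- IRanges::reduce(.to_iranges(cov$start, cov$end))
  }
  mask <- IRanges::intersect(footprint, deep)
  region$covered <- mask
  region$covered_sites <- sum(IRanges::width(mask))
  region$assessable <- (region$covered_sites / region$total_sites) >= min_fraction
  region
}

#' Build coverage-masked regions for every gene in a transcript table
#'
#' @param transcripts exon table for many genes (columns as in
#'   \code{\link{merge_transcripts}}).
#' @param coverage depth intervals (columns as in
#'   \code{\link{apply_coverage}}).
#' @inheritParams apply_coverage
#' @inheritParams merge_transcripts
#' @return named list of \code{gene_region} objects, one per gene symbol.
#' @export
build_gene_regions <- function(transcripts, coverage,
                               splice_pad = 2L, min_depth = 10,
                               min_fraction = 0.70) {
  by_gene <- split(transcripts, as.character(transcripts$gene_symbol))
  lapply(by_gene, function(ex) {
    apply_coverage(merge_transcripts(ex, splice_pad = splice_pad),
                   coverage, min_depth = min_depth,
                   min_fraction = min_fraction)
  })
}

#' Is a position inside a region's covered-site mask?
#'
#' @param region a coverage-masked \code{gene_region}.
#' @param pos 0-based genomic position(s).
#' @return logical vector.
#' @keywords internal
site_covered <- function(region, pos) {
  if (is.null(region$covered)) stop("region is not coverage-masked")
  if (!length(pos)) return(logical(0))
  q <- IRanges::IRanges(start = pos + 1L, width = 1L)
  IRanges::overlapsAny(q, region$covered)
}

#' Summarize gene regions as a data.frame
#'
#' One row per gene: interval count, footprint size, covered sites and the
#' assessability call — the audit table behind coverage-corrected gene size.
#'
#' @param regions named list of \code{gene_region} objects.
#' @return data.frame with columns gene_symbol, chrom, n_intervals,
#'   total_sites, covered_sites, assessable.
#' @export
region_summary <- function(regions) {
  do.call(rbind, lapply(unname(regions), function(r) {
    data.frame(gene_symbol = r$gene_symbol, chrom = r$chrom,
               n_intervals = nrow(r$intervals),
               total_sites = r$total_sites,
               covered_sites = r$covered_sites,
               assessable = r$assessable,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.gene_region <- function(x, ...) {
  cat(sprintf("<gene_region> %s (%s): %d interval(s), %d sites",
              x$gene_symbol, x$chrom, nrow(x$intervals), x$total_sites))
  if (!is.na(x$assessable))
    cat(sprintf(", %d covered (%.1f%%), assessable=%s",
                x$covered_sites, 100 * x$covered_sites / x$total_sites,
                x$assessable))
  cat("\n")
  invisible(x)
}
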