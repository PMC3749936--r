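# Controlled effect-annotation vocabulary (EVS/ESP dialect).  Functional =
# protein-altering or splice-disrupting; non-functional = synonymous.

#' @rdname classify_variant
#' @export
FUNCTIONAL_EFFECTS <- c(
  "missense", "stop-gained", "missense-near-splice", "stop-lost",
  "splice-5", "splice-3", "stop-gained-near-splice", "stop-lost-near-splice"
)

#' @rdname classify_variant
#' @export
NON_FUNCTIONAL_EFFECTS <- c("coding-synonymous", "coding-synonymous-near-splice")

CODING_EFFECTS <- c(FUNCTIONAL_EFFECTS, NON_FUNCTIONAL_EFFECTS)

.is_snv <- function(ref, alt) {
  ok <- function(a) !is.na(a) & nchar(a) == 1L & toupper(a) %in% c("A", "C", "G", "T")
  ok(as.character(ref)) & ok(as.character(alt))
}

#' Does a variant record qualify for intolerance scoring?
#'
#' A site-allele qualifies when it passed the cohort's quality filters
#' (\code{PASS}), is a single-nucleotide substitution (indels are excluded
#' as less reliably called), falls inside the gene's covered-site mask, and
#' carries a coding effect annotation from the controlled vocabulary.
#' All disqualifying conditions return \code{FALSE} rather than erroring.
#'
#' @param records data.frame of variant records (columns \code{gene_symbol},
#'   \code{chrom}, \code{pos}, \code{ref_allele}, \code{alt_allele},
#'   \code{effect}, \code{filter_status}, MAF columns, optional PP2 fields).
#' @param region the gene's coverage-masked \code{gene_region}.
#' @return logical vector, one element per record.
#' @export
qualify <- function(records, region) {
  if (!is.data.frame(records))
    stop("records must be a data.frame of variant records")
  if (nrow(records) == 0L) return(logical(0))
  need <- c("pos", "ref_allele", "alt_allele", "effect", "filter_status")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("malformed variant records; missing: ", paste(miss, collapse = ", "))
  as.character(records$filter_status) == "PASS" &
    .is_snv(records$ref_allele, records$alt_allele) &
    site_covered(region, as.integer(records$pos)) &
    as.character(records$effect) %in% CODING_EFFECTS
}

#' Classify qualifying variants as functional or non-functional
#'
#' Standard mode partitions the vocabulary: missense, nonsense (stop
#' gained/lost) and splice acceptor/donor annotations are FUNCTIONAL;
#' synonymous annotations are NON_FUNCTIONAL.  The PolyPhen-2-informed
#' mode (\code{mode = "pp2"}) additionally treats missense variants with a
#' "benign" qualitative PolyPhen-2 assessment as NON_FUNCTIONAL, while
#' "probably", "possibly" and "unknown" missense stay FUNCTIONAL;
#' truncating and splice classes are never relabeled.  Effect strings
#' outside the vocabulary are EXCLUDED with a warning.
#'
#' @param records data.frame of variant records; \code{pp2_label} required
#'   for missense records in pp2 mode.
#' @param mode \code{"standard"} or \code{"pp2"}.
#' @param missing_pp2 what to do with a missense record lacking a
#'   PolyPhen-2 label in pp2 mode: \code{"error"} (default) or
#'   \code{"exclude"}.
#' @return character vector in \{FUNCTIONAL, NON_FUNCTIONAL, EXCLUDED\}.
#' @export
classify_variant <- function(records, mode = c("standard", "pp2"),
                             missing_pp2 = c("error", "exclude")) {
  mode <- match.arg(mode)
  missing_pp2 <- match.arg(missing_pp2)
  eff <- as.character(records$effect)
  cls <- rep("EXCLUDED", length(eff))
  cls[eff %in% FUNCTIONAL_EFFECTS] <- "FUNCTIONAL"
  cls[eff %in% NON_FUNCTIONAL_EFFECTS] <- "NON_FUNCTIONAL"
  unknown <- !(eff %in% CODING_EFFECTS)
  if (any(unknown))
    warning(sum(unknown), " record(s) with effect outside the vocabulary ",
            "excluded: ", paste(unique(eff[unknown]), collapse = ", "))
  if (mode == "pp2") {
    is_missense <- eff %in% c("missense", "missense-near-splice")
    label <- if ("pp2_label" %in% names(records))
      as.character(records$pp2_label) else rep(NA_character_, length(eff))
    no_label <- is_missense & (is.na(label) | label == "")
    if (any(no_label)) {
      if (missing_pp2 == "error")
        stop(sum(no_label), " missense record(s) lack a PolyPhen-2 label ",
             "in pp2 mode")
      cls[no_label] <- "EXCLUDED"
    }
    cls[is_missense & !no_label & label == "benign"] <- "NON_FUNCTIONAL"
  }
  cls
}

#' Is a variant common at the chosen frequency threshold?
#'
#' Common means minor allele frequency strictly greater than \code{rho}
#' (in percent) in the selected population.
#'
#' @param records data.frame with \code{maf_all}, \code{maf_ea},
#'   \code{maf_aa} columns (percent scale, 0-100).
#' @param rho common/rare threshold in percent; default 0.1.
#' @param population which cohort's MAF to use: combined (\code{"ALL"}),
#'   European American (\code{"EA"}) or African American (\code{"AA"}).
#' @return logical vector.
#' @export
is_common <- function(records, rho = 0.1, population = c("ALL", "EA", "AA")) {
  population <- match.arg(population)
  if (rho <= 0 || rho >= 100) stop("rho must be in (0, 100) percent")
  col <- switch(population, ALL = "maf_all", EA = "maf_ea", AA = "maf_aa")
  if (!col %in% names(records))
    stop("MAF column '", col, "' missing for population ", population)
  maf <- as.numeric(records[[col]])
  if (anyNA(maf))
    stop("missing MAF value(s) for population ", population)
  maf > rho
}
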