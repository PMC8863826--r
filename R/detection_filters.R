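# Mutation-detection filter cascade for deep targeted panel calls from
# low-tumor-content FFPE material.  Four stages, each a per-call predicate:
#   1. low-confidence elimination (quality, depths, minimum VAF, caller FILTER)
#   2. common-SNV exclusion by population allele frequency (>= 1% anywhere)
#   3. retention of protein-affecting consequence classes
#   4. reproducibility floor: VAF >= 3% defines a valid mutation
# All boundary comparisons are literal: elimination uses strict "<", so a
# value exactly at a threshold passes; validity uses ">=".  VAF thresholds
# compare the exact fraction depth_alt / depth_total, never a rounded
# percentage.

.reason_codes <- c("QUAL_LT_20", "DEPTH_LT_100", "ALT_DEPTH_LT_5",
                   "VAF_LT_0.5PCT", "CALLER_FILTER_NOT_PASS",
                   "COMMON_SNV", "NON_PROTEIN_AFFECTING", "VAF_LT_3PCT")

.protein_affecting <- c(
  "missense_variant",
  "splice_acceptor_variant",
  "splice_donor_variant",
  "splice_region_variant",
  "stop_gained",
  "stop_lost",
  "stop_retained_variant",
  "5_prime_UTR_premature_start_codon_gain_variant",
  "exon_loss_variant",
  "disruptive_inframe_deletion",
  "disruptive_inframe_insertion",
  "frameshift_variant",
  "inframe_deletion",
  "inframe_insertion",
  "initiator_codon_variant"
)

.non_protein_affecting <- c(
  "synonymous_variant", "intron_variant", "intergenic_variant",
  "3_prime_UTR_variant", "5_prime_UTR_variant", "upstream_gene_variant",
  "downstream_gene_variant", "non_coding_transcript_exon_variant",
  "intragenic_variant"
)

#' The retained protein-affecting consequence classes
#'
#' The fifteen consequence classes considered to affect protein structure
#' and therefore retained by the detection cascade.
#'
#' @return Character vector of 15 Sequence-Ontology-style class names.
#' @export
protein_affecting_classes <- function() .protein_affecting

# exact VAF as a fraction, falling back to the stored vaf at zero depth
.exact_vaf <- function(calls) {
  ifelse(calls$depth_total > 0L, calls$depth_alt / calls$depth_total,
         calls$vaf)
}

#' Eliminate low-confidence calls
#'
#' Applies the five low-confidence elimination criteria: (1) quality score
#' < 20; (2) depth of coverage < 100; (3) alternate-allele depth < 5;
#' (4) VAF < 0.5%; (5) caller FILTER not "PASS".  Values exactly at a
#' threshold pass (strict less-than elimination).
#'
#' @param calls Variant-call table.
#' @param min_quality,min_depth,min_alt_depth,min_vaf Elimination thresholds;
#'   defaults 20, 100, 5, 0.005.
#' @return A data frame with one row per call: logical `passed` and a
#'   `reasons` column (semicolon-joined codes from `QUAL_LT_20`,
#'   `DEPTH_LT_100`, `ALT_DEPTH_LT_5`, `VAF_LT_0.5PCT`,
#'   `CALLER_FILTER_NOT_PASS`); `passed` is `TRUE` iff `reasons` is empty.
#' @export
eliminate_low_confidence <- function(calls, min_quality = 20, min_depth = 100,
                                     min_alt_depth = 5, min_vaf = 0.005) {
  validate_calls(calls)
  flags <- cbind(
    QUAL_LT_20 = calls$quality < min_quality,
    DEPTH_LT_100 = calls$depth_total < min_depth,
    ALT_DEPTH_LT_5 = calls$depth_alt < min_alt_depth,
    VAF_LT_0.5PCT = .exact_vaf(calls) < min_vaf,
    CALLER_FILTER_NOT_PASS = calls$caller_filter != "PASS"
  )
  .verdict_frame(flags)
}

.verdict_frame <- function(flags) {
  reasons <- apply(flags, 1, function(f) paste(colnames(flags)[f], collapse = ";"))
  rownames(flags) <- NULL
  data.frame(passed = unname(rowSums(flags) == 0),
             reasons = if (nrow(flags)) unname(reasons) else character(),
             flags, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Exclude common SNVs by population allele frequency
#'
#' A call is excluded as a common SNV when its allele frequency is
#' `min_af` (default 1%) or more in any of the consulted databases
#' (1000 Genomes global or East Asia, ExAC, gnomAD).  Databases from which
#' the variant is absent (`NA`) never exclude it.
#'
#' @param calls Variant-call table.
#' @param databases Which population-AF columns to consult; defaults to all
#'   of [pop_af_columns()].
#' @param min_af Exclusion boundary (inclusive), default 0.01.
#' @return Logical vector, `TRUE` = excluded.
#' @export
exclude_common_snv <- function(calls, databases = pop_af_columns(),
                               min_af = 0.01) {
  validate_calls(calls)
  databases <- match.arg(databases, pop_af_columns(), several.ok = TRUE)
  af <- as.matrix(calls[databases])
  if (any(af < 0, na.rm = TRUE)) stop("negative population allele frequency")
  if (nrow(calls) == 0) return(logical())
  unname(apply(af >= min_af, 1, any, na.rm = TRUE))
}

#' Keep protein-affecting consequence classes
#'
#' `TRUE` exactly for the fifteen classes of [protein_affecting_classes()].
#' Consequence strings outside the recognized vocabulary (protein-affecting
#' plus common silent/non-coding classes) raise an error listing the
#' accepted classes.
#'
#' @param calls Variant-call table, or a character vector of consequence
#'   class names.
#' @return Logical vector, `TRUE` = retained.
#' @export
keep_protein_affecting <- function(calls) {
  csq <- if (is.character(calls)) calls else {
    validate_calls(calls)
    calls$consequence
  }
  known <- c(.protein_affecting, .non_protein_affecting)
  unknown <- setdiff(unique(csq), known)
  if (length(unknown) > 0) {
    stop("unrecognized consequence class(es): ",
         paste(unknown, collapse = ", "),
         "\naccepted classes: ", paste(known, collapse = ", "))
  }
  csq %in% .protein_affecting
}

#' Valid-mutation floor on VAF
#'
#' Mutations with VAF >= 3% are defined as valid; the comparison uses the
#' exact fraction `depth_alt / depth_total`.
#'
#' @param calls Variant-call table.
#' @param min_vaf Validity boundary (inclusive), default 0.03.
#' @return Logical vector, `TRUE` = valid.
#' @export
is_valid_mutation <- function(calls, min_vaf = 0.03) {
  validate_calls(calls)
  .exact_vaf(calls) >= min_vaf
}

#' Run the full detection filter cascade
#'
#' Applies, in order: [eliminate_low_confidence()], [exclude_common_snv()],
#' [keep_protein_affecting()] and [is_valid_mutation()].  All four stages
#' are per-call predicates, so the surviving set does not depend on stage
#' order.  Per-call verdicts with reason codes are attached as the
#' `"verdicts"` attribute for reporting.
#'
#' @param calls Variant-call table.
#' @param databases,min_db_af Passed to [exclude_common_snv()].
#' @param min_quality,min_depth,min_alt_depth,min_vaf Passed to
#'   [eliminate_low_confidence()].
#' @param min_valid_vaf Passed to [is_valid_mutation()].
#' @return The surviving calls, with a `"verdicts"` attribute (data frame of
#'   `passed`, `reasons` and one logical column per reason code).
#' @examples
#' calls <- variant_call("chr1", c(100, 200), "A", "T",
#'                       depth_total = 500, depth_alt = c(50, 4))
#' surviving <- detect(calls)
#' attr(surviving, "verdicts")$reasons
#' @export
detect <- function(calls, databases = pop_af_columns(), min_db_af = 0.01,
                   min_quality = 20, min_depth = 100, min_alt_depth = 5,
                   min_vaf = 0.005, min_valid_vaf = 0.03) {
  validate_calls(calls)
  low <- eliminate_low_confidence(calls, min_quality, min_depth,
                                  min_alt_depth, min_vaf)
  flags <- cbind(
    as.matrix(low[.reason_codes[1:5]]),
    COMMON_SNV = exclude_common_snv(calls, databases, min_db_af),
    NON_PROTEIN_AFFECTING = !keep_protein_affecting(calls),
    VAF_LT_3PCT = !is_valid_mutation(calls, min_valid_vaf)
  )
  verdicts <- .verdict_frame(flags)
  out <- calls[verdicts$passed, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "verdicts") <- cbind(
    calls[c("chrom", "pos", "ref", "alt")], verdicts)
  out
}
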