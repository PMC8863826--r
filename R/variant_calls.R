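#' @keywords internal
"_PACKAGE"

# Population-frequency databases consulted by the common-SNV filter.
# Internal column name -> VCF INFO key.
.pop_af_info_keys <- c(
  af_kg_global = "AF_KG_GLOBAL",
  af_kg_eas    = "AF_KG_EAS",
  af_exac      = "AF_EXAC",
  af_gnomad    = "AF_GNOMAD"
)

.call_columns <- c(
  "chrom", "pos", "ref", "alt", "quality", "depth_total", "depth_alt",
  "vaf", "caller_filter", "consequence", names(.pop_af_info_keys)
)

#' Population-frequency database columns
#'
#' Names of the per-database population allele-frequency columns carried on a
#' variant-call table: 1000 Genomes global, 1000 Genomes East Asia, ExAC and
#' gnomAD.  `NA` in one of these columns means the variant is absent from
#' that database.
#'
#' @return Character vector of column names.
#' @export
pop_af_columns <- function() names(.pop_af_info_keys)

#' Construct a table of variant calls
#'
#' Builds the data frame of per-fraction variant calls used throughout the
#' package.  One row is one called variant in one sample.  VAFs are stored as
#' fractions in `[0, 1]` everywhere inside the package; report writers convert
#' to percent at the output boundary only.
#'
#' @param chrom Chromosome names (character).
#' @param pos 1-based positions (integer, `>= 1`).
#' @param ref,alt Reference and alternate alleles (uppercase, `ref != alt`).
#' @param depth_total Total read depth per call (integer, reads).
#' @param depth_alt Alternate-allele read depth (integer, `<= depth_total`).
#' @param vaf Variant allele frequency as a fraction; defaults to
#'   `depth_alt / depth_total`.
#' @param quality Phred-like caller quality score (non-negative).
#' @param caller_filter The caller's FILTER string (`"PASS"` when clean).
#' @param consequence Consequence class, e.g. `"missense_variant"`.
#' @param af_kg_global,af_kg_eas,af_exac,af_gnomad Population allele
#'   frequencies (fractions); `NA` = absent from that database.
#'
#' @return A `data.frame` with one row per call, validated by
#'   [validate_calls()].
#' @examples
#' variant_call("chr1", 100, "A", "T", depth_total = 200, depth_alt = 10)
#' @export
variant_call <- function(chrom, pos, ref, alt, depth_total, depth_alt,
                         vaf = NULL, quality = 60, caller_filter = "PASS",
                         consequence = "missense_variant",
                         af_kg_global = NA_real_, af_kg_eas = NA_real_,
                         af_exac = NA_real_, af_gnomad = NA_real_) {
  n <- length(pos)
  r <- function(x) rep_len(x, n)
  depth_total <- r(as.integer(depth_total))
  depth_alt <- r(as.integer(depth_alt))
  if (is.null(vaf)) {
    vaf <- ifelse(depth_total > 0, depth_alt / depth_total, 0)
  }
  calls <- data.frame(
    chrom = r(as.character(chrom)), pos = r(as.integer(pos)),
    ref = r(as.character(ref)), alt = r(as.character(alt)),
    quality = r(as.numeric(quality)),
    depth_total = r(as.integer(depth_total)),
    depth_alt = r(as.integer(depth_alt)),
    vaf = r(as.numeric(vaf)),
    caller_filter = r(as.character(caller_filter)),
    consequence = r(as.character(consequence)),
    af_kg_global = r(as.numeric(af_kg_global)),
    af_kg_eas = r(as.numeric(af_kg_eas)),
    af_exac = r(as.numeric(af_exac)),
    af_gnomad = r(as.numeric(af_gnomad)),
    stringsAsFactors = FALSE
  )
  validate_calls(calls)
}

#' Validate a variant-call table
#'
#' Checks the structural invariants of a call table: required columns,
#' 1-based positions, `ref != alt`, non-negative quality,
#' `0 <= depth_alt <= depth_total`, VAF in `[0, 1]` and consistent with
#' `depth_alt / depth_total` (to 1e-9) wherever depth is positive.
#'
#' @param calls A variant-call `data.frame`.
#' @return `calls`, invisibly unchanged, on success; otherwise an error.
#' @export
validate_calls <- function(calls) {
  if (!is.data.frame(calls)) stop("`calls` must be a data.frame")
  missing_cols <- setdiff(.call_columns, names(calls))
  if (length(missing_cols) > 0) {
    stop("call table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(calls) == 0) return(invisible(calls))
  bad <- function(what, which) {
    stop("invalid call record(s) ", paste(utils::head(which, 5), collapse = ", "),
         ": ", what)
  }
  if (any(calls$pos < 1L)) bad("pos must be >= 1 (1-based)", which(calls$pos < 1L))
  if (any(calls$ref == calls$alt)) bad("ref == alt", which(calls$ref == calls$alt))
  if (any(calls$quality < 0)) bad("negative quality", which(calls$quality < 0))
  bad_depth <- calls$depth_alt < 0L | calls$depth_alt > calls$depth_total
  if (any(bad_depth)) bad("depth_alt outside [0, depth_total]", which(bad_depth))
  if (any(calls$vaf < 0 | calls$vaf > 1)) {
    bad("vaf outside [0, 1]", which(calls$vaf < 0 | calls$vaf > 1))
  }
  pos_depth <- calls$depth_total > 0L
  drift <- abs(calls$vaf - calls$depth_alt / calls$depth_total) > 1e-9
  if (any(pos_depth & drift)) {
    bad("vaf inconsistent with depth_alt / depth_total", which(pos_depth & drift))
  }
  af <- as.matrix(calls[pop_af_columns()])
  if (any(af < 0 | af > 1, na.rm = TRUE)) {
    bad("population AF outside [0, 1]",
        which(apply(af < 0 | af > 1, 1, any, na.rm = TRUE)))
  }
  invisible(calls)
}

#' Variant key strings
#'
#' Collapses the identifying fields (chrom, pos, ref, alt) of a call, key or
#' truth table into one string per row, the unit of matching across
#' fractions and against the blood reference.
#'
#' @param x A data frame with `chrom`, `pos`, `ref`, `alt` columns.
#' @return Character vector of `chrom:pos:ref>alt` keys.
#' @export
variant_key <- function(x) {
  if (length(x$pos) == 0) return(character())
  paste0(x$chrom, ":", x$pos, ":", x$ref, ">", x$alt)
}

.check_unique_keys <- function(calls, label = "call set") {
  k <- variant_key(calls)
  if (anyDuplicated(k)) {
    stop("duplicate variant keys in ", label, ": ",
         paste(utils::head(unique(k[duplicated(k)]), 5), collapse = ", "))
  }
  invisible(k)
}

#' Bundle a patient's three cell fractions
#'
#' A patient contributes three call sets from the same FFPE section: the
#' untouched suspension (`unseparated`), the tumor-cell-enriched capture
#' (`tumor`) and the depleted flow-through (`residual`).  Optionally a set of
#' blood-derived variant keys (from whole-exome sequencing of peripheral
#' blood) defines ground-truth germline status.
#'
#' @param patient_id Patient identifier string.
#' @param unseparated,tumor,residual Variant-call tables (see
#'   [variant_call()]); keys must be unique within each fraction.
#' @param blood_keys Optional data frame of germline variant keys
#'   (`chrom`, `pos`, `ref`, `alt`).
#' @return An object of class `fraction_trio`.
#' @export
fraction_trio <- function(patient_id, unseparated, tumor, residual,
                          blood_keys = NULL) {
  fr <- list(unseparated = unseparated, tumor = tumor, residual = residual)
  for (nm in names(fr)) {
    validate_calls(fr[[nm]])
    .check_unique_keys(fr[[nm]], paste0(nm, " fraction of ", patient_id))
  }
  if (!is.null(blood_keys)) {
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% names(blood_keys))) {
      stop("blood_keys must have columns chrom, pos, ref, alt")
    }
  }
  structure(
    list(patient_id = as.character(patient_id),
         unseparated = unseparated, tumor = tumor, residual = residual,
         blood_keys = blood_keys),
    class = "fraction_trio"
  )
}

#' @export
print.fraction_trio <- function(x, ...) {
  cat("<fraction_trio> patient", x$patient_id, "\n")
  for (nm in c("unseparated", "tumor", "residual")) {
    cat(sprintf("  %-12s %4d calls\n", nm, nrow(x[[nm]])))
  }
  cat("  blood keys  ",
      if (is.null(x$blood_keys)) "none" else nrow(x$blood_keys), "\n")
  invisible(x)
}

#' Names of the three cell fractions
#' @return `c("unseparated", "tumor", "residual")`.
#' @export
fraction_names <- function() c("unseparated", "tumor", "residual")
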