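# Reader/writer for the minimal VCF 4.2 dialect used by this package:
# FORMAT DP (total depth), AD (ref,alt depths), AF (allele fraction);
# INFO keys CSQ_CLASS plus the population-AF keys AF_KG_GLOBAL, AF_KG_EAS,
# AF_EXAC, AF_GNOMAD, each optional.  Multi-allelic records are split into
# one call per alternate allele so that keys stay atomic for set operations.

# exact decimal round-trip for doubles
.fmt_dbl <- function(x) sprintf("%.17g", x)

.info_num <- function(info, key) {
  # pull `KEY=value` out of a semicolon-joined INFO string; NA when absent
  pat <- paste0("(?:^|;)", key, "=([^;]+)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(g) if (length(g) == 2) suppressWarnings(as.numeric(g[2])) else NA_real_, 0)
}

.info_chr <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]+)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(g) if (length(g) == 2) g[2] else NA_character_, "")
}

#' Read variant calls from a VCF file
#'
#' Parses a VCF 4.2 file carrying the dialect documented above and returns a
#' validated variant-call table.  The VAF is taken from the `AF` FORMAT field
#' when present, otherwise computed as `AD[alt] / DP`.  Multi-allelic records
#' are split into one row per alternate allele.  Missing population-AF INFO
#' keys yield `NA` (absent from that database).
#'
#' @param path Path to a plain-text VCF file.
#' @param fraction_label Optional label recorded in the `fraction` attribute
#'   of the result (purely informational).
#' @return A variant-call `data.frame` (see [variant_call()]).
#' @export
read_vcf <- function(path, fraction_label = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e))
  )
  fix <- v@fix
  if (nrow(fix) == 0) {
    out <- variant_call(character(), integer(), character(), character(),
                        integer(), integer())
    attr(out, "fraction") <- fraction_label
    return(out)
  }
  if (ncol(v@gt) < 2) stop("malformed VCF '", path, "': no sample column")
  gt <- v@gt[, 2, drop = TRUE]
  fmt <- v@gt[, 1, drop = TRUE]

  rec <- function(field, i) {
    keys <- strsplit(fmt[i], ":", fixed = TRUE)[[1]]
    vals <- strsplit(gt[i], ":", fixed = TRUE)[[1]]
    j <- match(field, keys)
    if (is.na(j) || j > length(vals)) NA_character_ else vals[j]
  }

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    fx <- function(col) unname(fix[i, col])
    alts <- strsplit(fx("ALT"), ",", fixed = TRUE)[[1]]
    pos <- suppressWarnings(as.integer(fx("POS")))
    if (is.na(pos)) stop("record ", i, ": unparseable POS '", fx("POS"), "'")
    dp <- suppressWarnings(as.integer(rec("DP", i)))
    ad_str <- rec("AD", i)
    if (is.na(ad_str)) stop("record ", i, ": missing AD field")
    ad <- suppressWarnings(as.integer(strsplit(ad_str, ",", fixed = TRUE)[[1]]))
    if (length(ad) != length(alts) + 1L || anyNA(ad)) {
      stop("record ", i, ": AD must hold ref plus one depth per alt allele")
    }
    af_str <- rec("AF", i)
    af <- if (is.na(af_str)) rep(NA_real_, length(alts)) else
      suppressWarnings(as.numeric(strsplit(af_str, ",", fixed = TRUE)[[1]]))
    if (length(af) != length(alts)) af <- rep(af, length.out = length(alts))
    info <- fx("INFO")
    qual <- suppressWarnings(as.numeric(fx("QUAL")))
    if (is.na(qual)) qual <- 0
    alt_dp <- ad[-1]
    if (!is.na(dp) && any(alt_dp > dp)) {
      stop("record ", i, ": AD alternate depth exceeds DP")
    }
    vaf <- ifelse(is.na(af),
                  ifelse(!is.na(dp) & dp > 0, alt_dp / dp, 0),
                  af)
    pop <- lapply(.pop_af_info_keys, function(k) .info_num(info, k))
    csq <- .info_chr(info, "CSQ_CLASS")
    rows[[i]] <- data.frame(
      chrom = fx("CHROM"), pos = pos, ref = fx("REF"), alt = alts,
      quality = qual,
      depth_total = if (is.na(dp)) sum(ad) else dp,
      depth_alt = alt_dp, vaf = vaf,
      caller_filter = fx("FILTER"),
      consequence = if (is.na(csq)) "missense_variant" else csq,
      af_kg_global = pop$af_kg_global, af_kg_eas = pop$af_kg_eas,
      af_exac = pop$af_exac, af_gnomad = pop$af_gnomad,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  tryCatch(validate_calls(out),
           error = function(e) stop("invalid VCF '", path, "': ",
                                    conditionMessage(e)))
  attr(out, "fraction") <- fraction_label
  out
}

#' Write variant calls to a VCF file
#'
#' Writes the package's VCF 4.2 dialect, sorted by (chrom, pos).  The file
#' round-trips exactly: `read_vcf(write_vcf(x))` reproduces every field the
#' pipeline uses, including full double precision on VAFs and population
#' allele frequencies.
#'
#' @param calls Variant-call table with unique keys.
#' @param path Output path.
#' @param sample_name Sample column name in the VCF.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, sample_name = "SAMPLE") {
  validate_calls(calls)
  .check_unique_keys(calls)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=fractionvaf",
    "##INFO=<ID=CSQ_CLASS,Number=1,Type=String,Description=\"Consequence class\">",
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"Population allele frequency (%s)\">",
            .pop_af_info_keys, names(.pop_af_info_keys)),
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Read depths (ref,alt)\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_name), collapse = "\t")
  )
  if (nrow(calls) > 0) {
    ord <- order(calls$chrom, calls$pos, calls$ref, calls$alt)
    calls <- calls[ord, , drop = FALSE]
    info <- sprintf("CSQ_CLASS=%s", calls$consequence)
    for (col in pop_af_columns()) {
      has <- !is.na(calls[[col]])
      info[has] <- paste0(info[has], ";", .pop_af_info_keys[[col]], "=",
                          .fmt_dbl(calls[[col]][has]))
    }
    records <- paste(
      calls$chrom, calls$pos, ".", calls$ref, calls$alt,
      .fmt_dbl(calls$quality), calls$caller_filter, info, "DP:AD:AF",
      paste0(calls$depth_total, ":",
             calls$depth_total - calls$depth_alt, ",", calls$depth_alt, ":",
             .fmt_dbl(calls$vaf)),
      sep = "\t"
    )
  } else {
    records <- character()
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, records), con, sep = "\n")
  invisible(path)
}

#' Write a tab-separated report table
#'
#' Writes records as a TSV with a header row.  Numeric columns are rendered
#' with at least six significant digits.  Columns named in `percent_cols`
#' (by default any column whose name contains `vaf` but not `ratio`, `log`
#' or `fold`) hold VAF fractions internally and are converted to percent
#' units in the report, e.g. an internal `0.0242` prints as `2.42`.
#'
#' @param rows A data frame, or a list of identically named rows.
#' @param path Output path.
#' @param percent_cols Character vector of fraction-valued columns to render
#'   in percent, or `NULL` for the default VAF-column heuristic.
#' @return `path`, invisibly.
#' @export
write_report <- function(rows, path, percent_cols = NULL) {
  if (!is.data.frame(rows)) {
    if (!is.list(rows)) stop("`rows` must be a data.frame or list of rows")
    if (length(rows) > 0) {
      schemas <- lapply(rows, names)
      if (!all(vapply(schemas, identical, TRUE, y = schemas[[1]]))) {
        stop("ragged rows: all rows must share one column schema")
      }
    }
    rows <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  }
  if (is.null(percent_cols)) {
    nm <- names(rows)
    percent_cols <- nm[grepl("vaf", nm, ignore.case = TRUE) &
                         !grepl("ratio|log|fold", nm, ignore.case = TRUE)]
  }
  out <- rows
  for (col in intersect(percent_cols, names(out))) {
    out[[col]] <- out[[col]] * 100
  }
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- vapply(out[[col]], function(x) {
        if (is.na(x)) NA_character_
        else format(x, digits = 8, scientific = FALSE, trim = TRUE)
      }, "")
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
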