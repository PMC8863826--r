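# Synthetic two-fraction cohort generator.  Emulates sectioned FFPE tumor
# suspensions separated into a tumor-enriched and a residual (depleted)
# fraction, sequenced on a deep targeted panel: germline and somatic
# mutations mixed by tumor purity, negative-binomial depth, binomial read
# sampling with a small miscall rate, plus sporadic low-VAF artifact calls.

#' Parameters of a synthetic enrichment cohort
#'
#' Defaults reproduce the study conditions this package is built around:
#' four gastric-cancer patients with unseparated tumor-cell contents of 20,
#' 20, 50 and 60%, magnetic-bead enrichment to 80% purity in the tumor
#' fraction and depletion to 5% in the residual fraction, 100 somatic
#' mutations (cancer-cell fraction uniform on (0.2, 1]) and 25 heterozygous
#' germline mutations per patient, panel depth ~ negative binomial with mean
#' 500 and CV about 0.3, and a 0.1% per-base miscall rate.
#'
#' @param n_patients Number of patients.
#' @param purity_unseparated Per-patient tumor-cell fraction of the
#'   unseparated suspension (recycled to `n_patients`).
#' @param purity_tumor Tumor-cell fraction after enrichment.
#' @param purity_residual Tumor-cell fraction of the residual fraction.
#' @param n_somatic,n_germline Somatic / germline mutations per patient.
#' @param frac_germline_loh Probability that a germline mutation has lost
#'   its mutant allele in the tumor (LOH).
#' @param n_common_snv Additional database-registered germline SNVs per
#'   patient (population AF >= 1%), exercising the common-SNV filter.
#' @param ccf_range Interval of somatic cancer-cell fractions, drawn
#'   uniformly.
#' @param depth_mean Mean panel read depth (reads).
#' @param depth_dispersion Negative-binomial size parameter; the default
#'   11.1 gives a depth CV of about 0.3 at mean 500.
#' @param error_rate Per-base sequencing miscall rate.
#' @param artifact_rate Expected number of spurious low-VAF artifact calls
#'   injected per fraction (Poisson).
#' @param seed Integer random seed; the whole cohort is reproducible from it.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 4,
                          purity_unseparated = c(0.2, 0.2, 0.5, 0.6),
                          purity_tumor = 0.8,
                          purity_residual = 0.05,
                          n_somatic = 100, n_germline = 25,
                          frac_germline_loh = 0.04,
                          n_common_snv = 0,
                          ccf_range = c(0.2, 1),
                          depth_mean = 500, depth_dispersion = 11.1,
                          error_rate = 0.001, artifact_rate = 3,
                          seed = 1L) {
  p <- list(
    n_patients = as.integer(n_patients),
    purity_unseparated = rep_len(purity_unseparated, n_patients),
    purity_tumor = rep_len(purity_tumor, n_patients),
    purity_residual = rep_len(purity_residual, n_patients),
    n_somatic = as.integer(n_somatic), n_germline = as.integer(n_germline),
    frac_germline_loh = frac_germline_loh,
    n_common_snv = as.integer(n_common_snv),
    ccf_range = ccf_range,
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    error_rate = error_rate, artifact_rate = artifact_rate,
    seed = as.integer(seed)
  )
  probs <- c(p$purity_unseparated, p$purity_tumor, p$purity_residual,
             p$frac_germline_loh, p$error_rate, p$ccf_range)
  if (any(probs < 0 | probs > 1)) {
    stop("purities, rates and CCF bounds must lie in [0, 1]")
  }
  if (any(c(p$n_patients, p$n_somatic, p$n_germline, p$n_common_snv) < 0)) {
    stop("counts must be non-negative")
  }
  if (p$ccf_range[1] > p$ccf_range[2]) stop("ccf_range must be increasing")
  ok <- p$purity_residual <= p$purity_unseparated &
    p$purity_unseparated <= p$purity_tumor
  if (!all(ok)) {
    stop("enrichment contract violated: need purity_residual <= ",
         "purity_unseparated <= purity_tumor for every patient")
  }
  structure(p, class = "cohort_params")
}

#' @export
print.cohort_params <- function(x, ...) {
  cat("<cohort_params>", x$n_patients, "patients, seed", x$seed, "\n")
  cat("  purities (unsep/tumor/residual):",
      paste(sprintf("%.2f/%.2f/%.2f", x$purity_unseparated, x$purity_tumor,
                    x$purity_residual), collapse = ", "), "\n")
  cat(sprintf("  %d somatic + %d germline per patient; depth NB(%g, size %g)\n",
              x$n_somatic, x$n_germline, x$depth_mean, x$depth_dispersion))
  invisible(x)
}

.origins <- c("SOMATIC", "GERMLINE_HET", "GERMLINE_LOH")

.validate_truth <- function(truth) {
  need <- c("origin", "g", "m", "cn_t", "ccf")
  if (!all(need %in% names(truth))) {
    stop("truth table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(truth$origin %in% .origins)) {
    stop("unknown origin; expected one of ", paste(.origins, collapse = ", "))
  }
  with(truth, {
    som <- origin == "SOMATIC"; het <- origin == "GERMLINE_HET"
    loh <- origin == "GERMLINE_LOH"
    if (any(som & g != 0)) stop("SOMATIC requires g = 0")
    if (any(het & (g != 1 | m != 1 | cn_t != 2 | ccf != 1))) {
      stop("GERMLINE_HET requires g = 1, m = 1, cn_t = 2, ccf = 1")
    }
    if (any(loh & (g != 1 | m != 0 | cn_t != 1 | ccf != 1))) {
      stop("GERMLINE_LOH requires g = 1, m = 0, cn_t = 1, ccf = 1")
    }
    if (any(m > cn_t)) stop("mutant copies m cannot exceed cn_t")
    if (any(ccf <= 0 | ccf > 1)) stop("ccf must lie in (0, 1]")
  })
  invisible(truth)
}

#' Expected VAF under the purity mixture model
#'
#' For a specimen of tumor purity `p`, reads at a locus come from normal
#' cells (diploid, `g` mutant copies) and tumor cells (`cn_t` total copies,
#' `m` mutant copies in the `ccf` fraction of tumor cells that carry the
#' mutation):
#'
#' `VAF = (g (1 - p) + m ccf p) / (2 (1 - p) + cn_t p)`
#'
#' Consequences used throughout: a heterozygous germline variant
#' (`g = 1, m = 1, cn_t = 2`) has VAF 1/2 at every purity; a clonal
#' heterozygous somatic variant has VAF `p / 2`, increasing with purity; a
#' germline variant under tumor LOH (`m = 0, cn_t = 1`) has VAF
#' `(1 - p) / (2 - p)`, decreasing with purity.
#'
#' @param truth Truth table (or single row) with columns `g`, `m`, `cn_t`,
#'   `ccf` (and optionally `origin`, which is validated against them).
#' @param purity Tumor purity in `[0, 1]` (scalar or per-row vector).
#' @return Expected VAF fraction(s) in `[0, 1]`.
#' @export
expected_vaf <- function(truth, purity) {
  if (any(purity < 0 | purity > 1)) stop("purity must lie in [0, 1]")
  if ("origin" %in% names(truth)) .validate_truth(as.data.frame(truth))
  (truth$g * (1 - purity) + truth$m * truth$ccf * purity) /
    (2 * (1 - purity) + truth$cn_t * purity)
}

# one patient's ground-truth mutation set
.simulate_truth <- function(params, patient_id) {
  n_s <- params$n_somatic; n_g <- params$n_germline; n_c <- params$n_common_snv
  n <- n_s + n_g + n_c
  if (n == 0) {
    return(data.frame(patient_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      origin = character(), g = integer(), m = integer(),
                      cn_t = integer(), ccf = numeric(), db_af = numeric(),
                      stringsAsFactors = FALSE))
  }
  pos <- sample.int(5e7, n)          # unique positions keep keys unique
  chrom <- paste0("chr", sample.int(22, n, replace = TRUE))
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  origin <- c(rep("SOMATIC", n_s),
              ifelse(stats::runif(n_g) < params$frac_germline_loh,
                     "GERMLINE_LOH", "GERMLINE_HET"),
              rep("GERMLINE_HET", n_c))
  g <- ifelse(origin == "SOMATIC", 0L, 1L)
  m <- ifelse(origin == "GERMLINE_LOH", 0L, 1L)
  cn_t <- ifelse(origin == "GERMLINE_LOH", 1L, 2L)
  ccf <- ifelse(origin == "SOMATIC",
                stats::runif(n, params$ccf_range[1], params$ccf_range[2]), 1)
  db_af <- c(rep(NA_real_, n_s + n_g),
             if (n_c > 0) stats::runif(n_c, 0.01, 0.5) else numeric())
  truth <- data.frame(patient_id = patient_id, chrom = chrom, pos = pos,
                      ref = ref, alt = alt, origin = origin, g = g, m = m,
                      cn_t = cn_t, ccf = ccf, db_af = db_af,
                      stringsAsFactors = FALSE)
  .validate_truth(truth)
}

#' Sample one fraction's variant calls from ground truth
#'
#' Draws a call set as deep targeted sequencing of a specimen with the given
#' tumor purity would produce it.  Per truth record: total depth from a
#' negative binomial (floored at 1), alternate depth from
#' `Binomial(depth, q)` with
#' `q = E[VAF] (1 - e) + (1 - E[VAF]) e / 3` for miscall rate `e`.
#' Calls carry passing quality/filter defaults and a protein-affecting
#' consequence class; germline truths are database-absent (private SNVs)
#' unless the truth row carries a `db_af`, which is written to the gnomAD
#' column.  Additionally `Poisson(artifact_rate)` spurious calls are
#' injected at fresh keys with underlying allele fraction ~ Beta(1, 150).
#'
#' Sampling uses R's global RNG; seed upstream (as [generate_cohort()] does)
#' for reproducibility.
#'
#' @param truth Truth table from the generator.
#' @param purity Tumor purity of this fraction, in `[0, 1]`.
#' @param params A [cohort_params()] object.
#' @return A variant-call table.
#' @export
sample_fraction_calls <- function(truth, purity, params) {
  if (length(purity) != 1 || purity < 0 || purity > 1) {
    stop("purity must be a single value in [0, 1]")
  }
  e <- params$error_rate
  n <- nrow(truth)
  ev <- if (n > 0) expected_vaf(truth, purity) else numeric()
  q <- ev * (1 - e) + (1 - ev) * e / 3
  depth <- pmax(1L, stats::rnbinom(n, mu = params$depth_mean,
                                   size = params$depth_dispersion))
  alt <- stats::rbinom(n, depth, q)
  csq <- sample(protein_affecting_classes(), n, replace = TRUE)
  calls <- variant_call(
    chrom = truth$chrom, pos = truth$pos, ref = truth$ref, alt = truth$alt,
    depth_total = depth, depth_alt = alt, quality = 60,
    caller_filter = "PASS", consequence = csq,
    af_gnomad = if ("db_af" %in% names(truth)) truth$db_af else NA_real_
  )
  n_art <- stats::rpois(1, params$artifact_rate)
  if (n_art > 0) {
    f <- stats::rbeta(n_art, 1, 150)
    ad <- pmax(1L, stats::rnbinom(n_art, mu = params$depth_mean,
                                  size = params$depth_dispersion))
    aa <- stats::rbinom(n_art, ad, f)
    ref <- sample(c("A", "C", "G", "T"), n_art, replace = TRUE)
    art <- variant_call(
      chrom = paste0("chr", sample.int(22, n_art, replace = TRUE)),
      pos = 5e7 + sample.int(5e7, n_art),   # disjoint from truth positions
      ref = ref,
      alt = vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), ""),
      depth_total = ad, depth_alt = aa, quality = 60,
      caller_filter = "PASS",
      consequence = sample(protein_affecting_classes(), n_art, replace = TRUE)
    )
    calls <- rbind(calls, art)
  }
  rownames(calls) <- NULL
  calls
}

#' Generate a synthetic enrichment cohort
#'
#' Produces one [fraction_trio()] per patient, all three fractions sampled
#' from the same per-patient ground truth at that patient's unseparated,
#' tumor-fraction and residual purities.  `blood_keys` of each trio contains
#' the keys of all germline truths, emulating their detection by whole-exome
#' sequencing of peripheral blood.  Fully reproducible from `params$seed`.
#'
#' @param params A [cohort_params()] object.
#' @return A list with elements `trios` (list of `fraction_trio`), `truth`
#'   (pooled truth table with per-fraction expected VAF columns) and
#'   `params`.
#' @examples
#' cohort <- generate_cohort(cohort_params(n_patients = 2, n_somatic = 10,
#'                                         n_germline = 3, seed = 7))
#' cohort$trios[[1]]
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  trios <- vector("list", params$n_patients)
  truths <- vector("list", params$n_patients)
  for (i in seq_len(params$n_patients)) {
    pid <- sprintf("P%d", i)
    truth <- .simulate_truth(params, pid)
    calls_u <- sample_fraction_calls(truth, params$purity_unseparated[i], params)
    calls_t <- sample_fraction_calls(truth, params$purity_tumor[i], params)
    calls_r <- sample_fraction_calls(truth, params$purity_residual[i], params)
    germ <- truth[truth$origin != "SOMATIC",
                  c("chrom", "pos", "ref", "alt"), drop = FALSE]
    trios[[i]] <- fraction_trio(pid, calls_u, calls_t, calls_r,
                                blood_keys = germ)
    truth$ev_unseparated <- expected_vaf(truth, params$purity_unseparated[i])
    truth$ev_tumor <- expected_vaf(truth, params$purity_tumor[i])
    truth$ev_residual <- expected_vaf(truth, params$purity_residual[i])
    truths[[i]] <- truth
  }
  truth_all <- do.call(rbind, truths)
  rownames(truth_all) <- NULL
  list(trios = trios, truth = truth_all, params = params)
}
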