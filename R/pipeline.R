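# End-to-end orchestration: simulate (or load) -> detect -> compare ->
# classify-germline -> estimate-purity -> summarize, with a run manifest,
# per-stage outputs and full determinism under a fixed seed.  Output files
# carry no timestamps so repeated runs with the same config are
# byte-identical.

#' Build and validate a pipeline run configuration
#'
#' Exactly one input source must be given: a [cohort_params()] object (the
#' cohort is simulated) or `vcf_paths`, a named list with one entry per
#' patient, each a named character vector/list of VCF paths with elements
#' `unseparated`, `tumor`, `residual` and optionally `blood`.
#'
#' Filter thresholds default to the detection cascade's standard values;
#' any override is recorded in the run manifest.
#'
#' @param cohort A [cohort_params()] object, or `NULL`.
#' @param vcf_paths Named list of per-patient VCF path sets, or `NULL`.
#' @param out_dir Output directory for the run.
#' @param seed Integer seed for the run (overrides `cohort$seed` when a
#'   cohort is simulated).
#' @param databases,min_db_af,min_quality,min_depth,min_alt_depth,min_vaf,min_valid_vaf
#'   Detection-filter settings, see [detect()].
#' @param threshold_criterion `"youden"` (choose on the ROC) or `"fixed"`.
#' @param fixed_threshold Log2-ratio cutoff used when
#'   `threshold_criterion = "fixed"`.
#' @param log_level `"info"` or `"quiet"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = NULL, vcf_paths = NULL, out_dir, seed = 1L,
                       databases = pop_af_columns(), min_db_af = 0.01,
                       min_quality = 20, min_depth = 100, min_alt_depth = 5,
                       min_vaf = 0.005, min_valid_vaf = 0.03,
                       threshold_criterion = c("youden", "fixed"),
                       fixed_threshold = NULL, log_level = c("info", "quiet")) {
  if (is.null(cohort) == is.null(vcf_paths)) {
    stop("config error: exactly one of `cohort` and `vcf_paths` must be set")
  }
  if (!is.null(cohort) && !inherits(cohort, "cohort_params")) {
    stop("config error: `cohort` must be a cohort_params object")
  }
  if (!is.null(vcf_paths)) {
    ok <- vapply(vcf_paths, function(p)
      all(fraction_names() %in% names(p)), TRUE)
    if (!all(ok)) {
      stop("config error: every vcf_paths entry needs unseparated, tumor ",
           "and residual paths")
    }
  }
  threshold_criterion <- match.arg(threshold_criterion)
  if (threshold_criterion == "fixed" && is.null(fixed_threshold)) {
    stop("config error: fixed_threshold required when threshold_criterion = 'fixed'")
  }
  structure(list(
    cohort = cohort, vcf_paths = vcf_paths, out_dir = out_dir,
    seed = as.integer(seed), databases = databases, min_db_af = min_db_af,
    min_quality = min_quality, min_depth = min_depth,
    min_alt_depth = min_alt_depth, min_vaf = min_vaf,
    min_valid_vaf = min_valid_vaf,
    threshold_criterion = threshold_criterion,
    fixed_threshold = fixed_threshold,
    log_level = match.arg(log_level)
  ), class = "run_config")
}

.log <- function(config, ...) {
  if (identical(config$log_level, "info")) message("[fractionvaf] ", ...)
  invisible(NULL)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

.detect_call <- function(config, calls) {
  detect(calls, databases = config$databases, min_db_af = config$min_db_af,
         min_quality = config$min_quality, min_depth = config$min_depth,
         min_alt_depth = config$min_alt_depth, min_vaf = config$min_vaf,
         min_valid_vaf = config$min_valid_vaf)
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, detect, compare, classify-germline and
#' estimate-purity as one reproducible run.  Each stage writes its outputs
#' under `out_dir/<stage>/`; a `manifest.json` records the package version,
#' seed, configuration (with an MD5 of the serialized config) and every
#' output path.  A failing stage aborts with an error naming the stage and
#' leaves a `FAILED` marker file; completed stage outputs are retained.
#'
#' Degenerate inputs are handled explicitly: when the ratio scores contain a
#' single truth class (e.g. no germline mutations simulated), the
#' classification stage records "single class, ROC skipped" and the run
#' still succeeds.
#'
#' @param config A [run_config()].
#' @return The run manifest (list), invisibly; all outputs on disk under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out, "FAILED"))
  manifest <- list(package = "fractionvaf",
                   version = as.character(utils::packageVersion("fractionvaf")),
                   seed = config$seed, stages = list())
  cfg_for_record <- config
  cfg_for_record$cohort <- if (!is.null(config$cohort)) unclass(config$cohort)
  cfg_path <- file.path(out, "config.yaml")
  yaml::write_yaml(unclass(cfg_for_record), cfg_path)
  manifest$config <- unclass(cfg_for_record)
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))

  stage <- function(name, fun) {
    .log(config, "stage ", name)
    tryCatch(fun(), error = function(e) {
      writeLines(paste0("stage ", name, " failed: ", conditionMessage(e)),
                 file.path(out, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- simulate / load ------------------------------------------------------
  truth <- NULL
  trios <- stage("simulate", function() {
    d <- file.path(out, "simulate")
    dir.create(d, showWarnings = FALSE)
    if (!is.null(config$cohort)) {
      params <- config$cohort
      params$seed <- config$seed
      cohort <- generate_cohort(params)
      truth <<- cohort$truth
      tcols <- c("patient_id", "chrom", "pos", "ref", "alt", "origin", "ccf",
                 "ev_unseparated", "ev_tumor", "ev_residual")
      write_report(cohort$truth[tcols], file.path(d, "truth.tsv"),
                   percent_cols = character())
      for (trio in cohort$trios) {
        for (nm in fraction_names()) {
          write_vcf(trio[[nm]],
                    file.path(d, sprintf("%s_%s.vcf", trio$patient_id, nm)))
        }
      }
      manifest$stages$simulate <<- list(dir = d,
                                        n_patients = length(cohort$trios))
      cohort$trios
    } else {
      lapply(seq_along(config$vcf_paths), function(i) {
        p <- config$vcf_paths[[i]]
        pid <- names(config$vcf_paths)[i]
        if (is.null(pid) || pid == "") pid <- sprintf("P%d", i)
        blood <- if ("blood" %in% names(p))
          read_vcf(p[["blood"]])[c("chrom", "pos", "ref", "alt")]
        fraction_trio(pid,
                      read_vcf(p[["unseparated"]], "unseparated"),
                      read_vcf(p[["tumor"]], "tumor"),
                      read_vcf(p[["residual"]], "residual"),
                      blood_keys = blood)
      })
    }
  })

  # -- detect ---------------------------------------------------------------
  detected <- stage("detect", function() {
    d <- file.path(out, "detect")
    dir.create(d, showWarnings = FALSE)
    counts <- list()
    res <- lapply(trios, function(trio) {
      fr <- list()
      for (nm in fraction_names()) {
        kept <- .detect_call(config, trio[[nm]])
        verd <- attr(kept, "verdicts")
        base <- sprintf("%s_%s", trio$patient_id, nm)
        write_vcf(kept, file.path(d, paste0(base, ".filtered.vcf")))
        write_report(verd, file.path(d, paste0(base, ".verdicts.tsv")),
                     percent_cols = character())
        counts[[base]] <<- c(n_in = nrow(trio[[nm]]), n_out = nrow(kept))
        fr[[nm]] <- kept
      }
      fraction_trio(trio$patient_id, fr$unseparated, fr$tumor, fr$residual,
                    blood_keys = trio$blood_keys)
    })
    manifest$stages$detect <<- list(dir = d, counts = counts)
    res
  })

  # -- compare --------------------------------------------------------------
  matched <- stage("compare", function() {
    d <- file.path(out, "compare")
    dir.create(d, showWarnings = FALSE)
    m <- do.call(rbind, lapply(detected, match_across_fractions))
    rownames(m) <- NULL
    write_report(m, file.path(d, "matched.tsv"))
    vc <- venn_counts(m)
    write_report(data.frame(region = names(vc$regions),
                            count = unname(vc$regions),
                            label = unname(.venn_labels[names(vc$regions)])),
                 file.path(d, "venn_counts.tsv"))
    fc <- fold_change_low_vaf(m, truth = truth)
    write_report(fc$summary, file.path(d, "fold_change_summary.tsv"),
                 percent_cols = character())
    write_report(fc$per_variant, file.path(d, "fold_change_variants.tsv"))
    # group (a) vs (b)+(c) contrasts in the tumor fraction, VAF and depth,
    # Bonferroni over the two comparisons
    tests <- NULL
    in_a <- m$group_label == "a"
    in_bc <- m$group_label %in% c("b", "c")
    if (sum(in_a) >= 2 && sum(in_bc) >= 2) {
      wv <- welch_t(m$vaf_tumor[in_a], m$vaf_tumor[in_bc], m = 2)
      wd <- welch_t(m$depth_tumor[in_a], m$depth_tumor[in_bc], m = 2)
      tests <- data.frame(
        comparison = c("vaf_a_vs_bc", "depth_a_vs_bc"),
        statistic = c(wv$statistic, wd$statistic),
        df = c(wv$df, wd$df),
        p_value = c(wv$p_value, wd$p_value),
        adjusted_alpha = c(wv$adjusted_alpha, wd$adjusted_alpha))
      write_report(tests, file.path(d, "welch_tests.tsv"),
                   percent_cols = character())
    }
    manifest$stages$compare <<- list(dir = d, venn = as.list(vc$labels),
                                     n_matched = nrow(m))
    m
  })

  # -- classify-germline ----------------------------------------------------
  stage("classify-germline", function() {
    d <- file.path(out, "classify")
    dir.create(d, showWarnings = FALSE)
    scores <- suppressMessages(score_shared(matched))
    blood <- do.call(rbind, lapply(detected, function(t) t$blood_keys))
    have_truth <- !is.null(blood)
    if (have_truth) scores <- attach_blood_truth(scores, blood)
    summary <- list(n_scored = nrow(scores))
    classified <- scores
    if (config$threshold_criterion == "fixed") {
      classified <- classify_origin(scores, config$fixed_threshold)
      summary$threshold <- config$fixed_threshold
      summary$criterion <- "fixed"
    } else if (!have_truth || length(unique(scores$truth_label)) < 2 ||
               nrow(scores) == 0) {
      summary$note <- "single class, ROC skipped"
      .log(config, "classify-germline: single class, ROC skipped")
    } else {
      curve <- roc_curve(scores)
      thr <- choose_threshold(curve)
      classified <- classify_origin(scores, thr)
      write_report(data.frame(threshold = curve$thresholds,
                              fpr = curve$fpr, tpr = curve$tpr),
                   file.path(d, "roc_points.tsv"), percent_cols = character())
      summary$criterion <- "youden"
      summary$auc <- curve$auc
      summary$threshold_log2_ratio <- thr$threshold
      summary$threshold_ratio <- 2^thr$threshold
      summary$sensitivity <- thr$sensitivity
      summary$specificity <- thr$specificity
      cm <- attr(classified, "confusion")
      summary$confusion <- list(
        germline_as_germline = cm["GERMLINE", "GERMLINE"],
        germline_as_somatic = cm["GERMLINE", "SOMATIC"],
        somatic_as_germline = cm["SOMATIC", "GERMLINE"],
        somatic_as_somatic = cm["SOMATIC", "SOMATIC"])
    }
    write_report(classified, file.path(d, "scores.tsv"))
    .write_json(summary, file.path(d, "classification.json"))
    manifest$stages$classify <<- list(dir = d, summary = summary)
    NULL
  })

  # -- estimate-purity ------------------------------------------------------
  stage("estimate-purity", function() {
    d <- file.path(out, "purity")
    dir.create(d, showWarnings = FALSE)
    res <- lapply(detected, function(trio) {
      pf <- purity_by_fraction(trio)
      list(patient_id = trio$patient_id, p_hat = as.list(pf$p_hat),
           tumor_exceeds_unseparated = pf$tumor_exceeds_unseparated)
    })
    names(res) <- vapply(res, `[[`, "", "patient_id")
    .write_json(res, file.path(d, "purity.json"))
    manifest$stages$purity <<- list(dir = d, estimates = res)
    NULL
  })

  .write_json(manifest, file.path(out, "manifest.json"))
  .log(config, "run complete: ", out)
  invisible(manifest)
}

#' Summarize a completed pipeline run
#'
#' Collects the machine-readable summary of a run directory produced by
#' [run_pipeline()]: per-fraction detected-mutation counts, Venn/label
#' counts, the low-VAF fold-change summary (percentages accompanied by
#' numerator/denominator, e.g. `"27/28"`), ROC AUC with chosen threshold,
#' the confusion matrix when truth was available, and per-fraction purity
#' estimates.  Written to `summary.json` in the run directory.
#'
#' @param run_dir A completed run directory.
#' @return The summary, invisibly (also written to
#'   `<run_dir>/summary.json`).
#' @export
summarize_run <- function(run_dir) {
  manifest_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("not a completed run: missing manifest.json in ", run_dir)
  }
  manifest <- jsonlite::read_json(manifest_path)
  for (st in c("detect", "compare", "classify", "purity")) {
    if (is.null(manifest$stages[[st]])) {
      stop("incomplete run: stage '", st, "' missing from manifest")
    }
  }
  fc_path <- file.path(run_dir, "compare", "fold_change_summary.tsv")
  fc <- utils::read.delim(fc_path, stringsAsFactors = FALSE)
  fc$fraction_display <- sprintf("%d/%d", fc$n_increased, fc$n)
  summary <- list(
    seed = manifest$seed,
    detected_counts = manifest$stages$detect$counts,
    venn_labels = manifest$stages$compare$venn,
    fold_change = fc,
    classification = manifest$stages$classify$summary,
    purity = manifest$stages$purity$estimates
  )
  .write_json(summary, file.path(run_dir, "summary.json"))
  invisible(summary)
}
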