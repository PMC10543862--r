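#' A-priori interrater criteria from two manual measurement series
#'
#' Computes, per spatial parameter, the interrater Bland-Altman bias and
#' precision (the +/- 1.96 SD half-width of the interrater limits of
#' agreement) and the ICC(A,k) of the two rater series. The precision
#' serves downstream as the maximum method-comparison bias/precision that
#' still indicates acceptable agreement.
#'
#' @param rater1_df,rater2_df Measurement tables of the two raters, same
#'   (array, electrode) coverage.
#' @return An object of class `apriori_criteria`: per parameter, `bias`,
#'   `precision` (1.96 SD), `icc`, plus `n_pairs`.
#' @export
run_apriori <- function(rater1_df, rater2_df) {
  out <- list()
  for (param in c("emd", "adoi")) {
    pd <- paired_differences(rater1_df, rater2_df, param)
    ba <- bland_altman(pd$diff)
    out[[param]] <- list(
      bias = ba$bias,
      precision = 1.96 * ba$sd,
      icc = icc_two_way_mixed_absolute(cbind(pd$a, pd$b)))
  }
  out$n_pairs <- nrow(paired_differences(rater1_df, rater2_df, "emd"))
  structure(out, class = "apriori_criteria")
}

#' @export
print.apriori_criteria <- function(x, ...) {
  cat(sprintf("<apriori_criteria> %d interrater pairs\n", x$n_pairs))
  cat(sprintf("  EMD : bias %.4f mm, precision +/- %.3f mm, ICC(A,k) %.4f\n",
              x$emd$bias, x$emd$precision, x$emd$icc))
  cat(sprintf("  aDOI: bias %.3f deg, precision +/- %.2f deg, ICC(A,k) %.4f\n",
              x$adoi$bias, x$adoi$precision, x$adoi$icc))
  invisible(x)
}

#' Round-trip a-priori criteria through JSON
#'
#' @param criteria An `apriori_criteria` object.
#' @param path JSON path.
#' @return For `write_criteria_json`, `path` invisibly; for
#'   `read_criteria_json`, the restored `apriori_criteria`.
#' @export
write_criteria_json <- function(criteria, path) {
  jsonlite::write_json(unclass(criteria), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_criteria_json
#' @export
read_criteria_json <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "apriori_criteria")
}

#' Full method comparison, optionally with post-hoc axis collocation
#'
#' Runs the comparison workflow on two measurement tables: agreement
#' reports for EMD and aDOI as measured ("pre"), then — if
#' `with_collocation` — one translation-only axis collocation per array
#' (the moving set's electrodes are registered toward the reference set's
#' axis by [collocate_cohort()]) and agreement reports of the collocated
#' measurements ("post"), pooling all electrode-level differences across
#' arrays. Verdict flags compare the method bias against the interrater
#' precision criteria when supplied.
#'
#' @param moving_df Measurement table of the method being evaluated (the
#'   one whose axis is shifted during collocation; the automatic method in
#'   the intended use).
#' @param reference_df Measurement table of the established (manual)
#'   reference method.
#' @param criteria Optional `apriori_criteria` from [run_apriori()].
#' @param with_collocation Run the per-array collocation stage?
#' @param search_bound,n_starts,tolerance Optimizer settings, see
#'   [optimize_shift()].
#' @param confidence Confidence level for correlation CIs.
#' @return An object of class `comparison_report`: `pre` and (optionally)
#'   `post` lists of [agreement_report()]s keyed by parameter, `shifts`
#'   (per-array shift estimates), and `verdict` (per parameter, `TRUE` if
#'   `|bias| <= precision criterion`).
#' @export
run_comparison <- function(moving_df, reference_df, criteria = NULL,
                           with_collocation = TRUE, search_bound = 2.0,
                           n_starts = 5, tolerance = 1e-4,
                           confidence = 0.95) {
  pre <- list(emd = agreement_report(moving_df, reference_df, "emd", confidence),
              adoi = agreement_report(moving_df, reference_df, "adoi", confidence))
  post <- NULL
  shifts <- NULL
  if (with_collocation) {
    col <- collocate_cohort(moving_df, reference_df,
                            search_bound = search_bound,
                            n_starts = n_starts, tolerance = tolerance)
    shifts <- col$shifts
    post <- list(
      emd = agreement_report(col$collocated, reference_df, "emd", confidence),
      adoi = agreement_report(col$collocated, reference_df, "adoi", confidence))
  }
  verdict <- NULL
  if (!is.null(criteria)) {
    verdict <- list(
      emd = abs(pre$emd$bias) <= criteria$emd$precision,
      adoi = abs(pre$adoi$bias) <= criteria$adoi$precision)
  }
  structure(list(pre = pre, post = post, shifts = shifts,
                 criteria = criteria, verdict = verdict),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n== As measured ==\n")
  print(x$pre$emd)
  print(x$pre$adoi)
  if (!is.null(x$post)) {
    cat("== After axis collocation ==\n")
    print(x$post$emd)
    print(x$post$adoi)
  }
  if (!is.null(x$verdict)) {
    cat(sprintf("verdict: EMD bias acceptable: %s; aDOI bias acceptable: %s\n",
                x$verdict$emd, x$verdict$adoi))
  }
  invisible(x)
}

report_to_list <- function(rep) {
  rep$differences <- NULL
  unclass(rep)
}

#' Serialize a comparison report to JSON
#'
#' Writes the scalar content of every agreement report (per-pair
#' differences excluded), the per-array shifts and the verdicts.
#'
#' @param report A `comparison_report`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- list(
    pre = lapply(report$pre, report_to_list),
    post = if (!is.null(report$post)) lapply(report$post, report_to_list),
    shifts = report$shifts,
    criteria = if (!is.null(report$criteria)) unclass(report$criteria),
    verdict = report$verdict)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}

#' Render the standard figure and summary set for a comparison report
#'
#' Writes, with deterministic names under `dir`: a scatter and a
#' Bland-Altman plot per parameter for the pre-collocation comparison
#' (`scatter_emd.png`, `bland_altman_emd.png`, ...), the same pair for the
#' post-collocation comparison when present, a polar per-electrode mean
#' plot (`polar_means.png`), the report JSON (`report.json`) and a
#' plain-text summary (`summary.txt`). If the report has no
#' post-collocation section the post plots are omitted and the summary
#' notes it.
#'
#' @param report A `comparison_report`.
#' @param dir Output directory (created if absent).
#' @param moving_df,reference_df The measurement tables the report was
#'   computed from (needed for the polar means plot); optional.
#' @return Character vector of written file paths, invisibly.
#' @export
render_outputs <- function(report, dir, moving_df = NULL,
                           reference_df = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  for (param in c("emd", "adoi")) {
    written <- c(written,
      plot_scatter(report$pre[[param]], file.path(dir,
        sprintf("scatter_%s.png", param))),
      plot_bland_altman(report$pre[[param]], file.path(dir,
        sprintf("bland_altman_%s.png", param))))
    if (!is.null(report$post)) {
      written <- c(written,
        plot_bland_altman(report$post[[param]], file.path(dir,
          sprintf("bland_altman_%s_post.png", param))))
    }
  }
  if (!is.null(moving_df) && !is.null(reference_df)) {
    written <- c(written,
                 plot_polar_means(moving_df, reference_df,
                                  file.path(dir, "polar_means.png")))
  }
  json_path <- file.path(dir, "report.json")
  write_report_json(report, json_path)
  summary_path <- file.path(dir, "summary.txt")
  lines <- c(utils::capture.output(print(report)),
             if (is.null(report$post)) "note: no post-collocation section")
  writeLines(lines, summary_path)
  written <- c(written, json_path, summary_path)
  invisible(written)
}
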