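# Plain-text output of ranking runs and stability reports.

#' Write a ranking run to a directory
#'
#' Emits \code{ranking.tsv} (rank, feature_id, weight — weights are the
#' full-model weights where available, NA otherwise), \code{error_curve.tsv}
#' (size, error, mcc), \code{selected.txt} (one feature id per line) and
#' \code{provenance.json} (method, mode, tuned hyperparameters, chosen
#' size).
#'
#' @param run a \code{ranking_run} from \code{\link{erfe_rank}} or
#'   \code{\link{bootstrap_rank}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_ranking_run <- function(run, dir) {
  stopifnot(inherits(run, "ranking_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- rep(NA_real_, length(run$ranking))
  if (!is.null(names(run$weights)))
    w <- unname(run$weights[match(run$ranking, names(run$weights))])
  utils::write.table(
    data.frame(rank = seq_along(run$ranking), feature_id = run$ranking,
               weight = w),
    file.path(dir, "ranking.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(size = run$sizes, error = run$errors, mcc = run$mcc),
    file.path(dir, "error_curve.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  writeLines(run$selected, file.path(dir, "selected.txt"))
  sp <- run$spec
  jsonlite::write_json(
    list(method = sp$name, mode = run$mode, n_star = run$n_star,
         B = run$B %||% NULL,
         hyperparameters = list(c = sp$c, sigma = sp$sigma, alpha = sp$alpha)),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}

#' Write a stability report as JSON
#'
#' @param report a \code{stability_report} from
#'   \code{\link{stability_indicator}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_stability_report <- function(report, path) {
  stopifnot(inherits(report, "stability_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
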