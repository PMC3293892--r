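#' Measurement-noise model
#'
#' Gene-wise error variances are drawn from a lognormal distribution whose
#' variate mean and standard deviation are \code{mean} and \code{sd}
#' (defaults 0.22 and 0.35, matching within-group error variances observed
#' on real microarray data). The underlying log-scale parameters are
#' obtained from the exact moment identities
#' \eqn{\mu = \log(m^2/\sqrt{m^2+s^2})}, \eqn{\sigma^2 = \log(1+s^2/m^2)}.
#' Noise is additive Gaussian with mean 0 and per-gene standard deviation
#' \eqn{\sqrt{variance}}, shared by all samples of a dataset.
#'
#' @param mean,sd mean and standard deviation of the variance variate.
#' @return An object of class \code{noise_model} with fields \code{mean},
#'   \code{sd}, \code{meanlog}, \code{sdlog}.
#' @export
noise_model <- function(mean = 0.22, sd = 0.35) {
  stop_if_not_(mean > 0 && sd >= 0, "need mean > 0 and sd >= 0")
  meanlog <- log(mean^2 / sqrt(mean^2 + sd^2))
  sdlog <- sqrt(log(1 + sd^2 / mean^2))
  structure(list(mean = mean, sd = sd, meanlog = meanlog, sdlog = sdlog),
            class = "noise_model")
}

#' Sample per-gene error variances
#'
#' @param p number of genes.
#' @param model a \code{\link{noise_model}}.
#' @param seed RNG seed.
#' @return Vector of \code{p} strictly positive variances.
#' @export
sample_gene_variances <- function(p, model = noise_model(), seed = NULL) {
  stopifnot(inherits(model, "noise_model"))
  with_seed_(seed, {
    if (model$sdlog == 0) rep(model$mean, p)
    else stats::rlnorm(p, model$meanlog, model$sdlog)
  })
}

#' Add gene-wise Gaussian measurement noise
#'
#' Adds \code{N(0, sqrt(variances[i]))} noise to every entry of row (gene)
#' \code{i}; the same gene-wise standard deviation applies to all samples.
#' Values are left unclipped by default (set \code{clip_negative} to
#' truncate negative noisy expressions at 0).
#'
#' @param x genes x samples expression matrix.
#' @param variances per-gene noise variances (length \code{nrow(x)}).
#' @param seed RNG seed.
#' @param clip_negative truncate negative values at 0?
#' @return The noisy matrix.
#' @export
add_noise <- function(x, variances, seed = NULL, clip_negative = FALSE) {
  stop_if_not_(length(variances) == nrow(x),
               "variances (%d) must match the feature count (%d)",
               length(variances), nrow(x))
  with_seed_(seed, {
    noisy <- x + matrix(stats::rnorm(length(x),
                                     sd = rep(sqrt(variances), ncol(x))),
                        nrow(x), ncol(x))
    if (clip_negative) noisy[noisy < 0] <- 0
    noisy
  })
}

#' Study design
#'
#' Replicated benchmark datasets: for each group size in \code{sizes},
#' \code{n_datasets} balanced datasets whose subject sets are pairwise
#' disjoint within the size-set.
#'
#' @param sizes subjects per group for each size-set (default 50, 20, 15,
#'   10).
#' @param n_datasets datasets per size-set (default 10).
#' @return An object of class \code{study_design}.
#' @export
study_design <- function(sizes = c(50, 20, 15, 10), n_datasets = 10) {
  structure(list(sizes = as.integer(sizes),
                 n_datasets = as.integer(n_datasets)),
            class = "study_design")
}

#' Partition subject pools into non-overlapping balanced datasets
#'
#' Within each size-set, draws \code{n_datasets} disjoint subject sets of
#' \code{size} per class from the healthy and diseased pools.
#'
#' @param healthy_ids,diseased_ids available subject identifiers per class.
#' @param design a \code{\link{study_design}}.
#' @param seed RNG seed.
#' @return A list (one element per size) of lists of \code{n_datasets}
#'   elements, each with \code{healthy} and \code{diseased} id vectors.
#' @export
partition_cohorts <- function(healthy_ids, diseased_ids, design, seed = NULL) {
  stopifnot(inherits(design, "study_design"))
  for (s in design$sizes) {
    need <- design$n_datasets * s
    if (need > length(healthy_ids) || need > length(diseased_ids))
      stop(sprintf(paste0("size-set %d needs %d subjects per class but pools ",
                          "have %d/%d"), s, need,
                   length(healthy_ids), length(diseased_ids)), call. = FALSE)
  }
  with_seed_(seed, {
    out <- lapply(design$sizes, function(s) {
      h <- sample(healthy_ids, design$n_datasets * s)
      d <- sample(diseased_ids, design$n_datasets * s)
      lapply(seq_len(design$n_datasets), function(k) {
        idx <- (k - 1) * s + seq_len(s)
        list(healthy = h[idx], diseased = d[idx])
      })
    })
    names(out) <- paste0("size_", design$sizes)
    out
  })
}

#' Expression dataset
#'
#' A features x samples expression matrix with binary group labels and an
#' optional reference to the ground-truth biomarker set.
#'
#' @param x features x samples numeric matrix (rownames = feature ids,
#'   colnames = sample ids; defaults are generated when absent).
#' @param labels factor (or coercible) of length \code{ncol(x)} with two
#'   levels, conventionally \code{healthy}/\code{diseased}.
#' @param truth optional vector of true biomarker feature ids, or a
#'   \code{biomarker_truth}.
#' @param provenance optional named list (seeds, configuration hash, ...).
#' @return An object of class \code{expression_dataset}.
#' @export
expression_dataset <- function(x, labels, truth = NULL, provenance = list()) {
  x <- as.matrix(x)
  stop_if_not_(all(is.finite(x)), "expression matrix has non-finite entries")
  stop_if_not_(length(labels) == ncol(x),
               "labels (%d) must match the sample count (%d)",
               length(labels), ncol(x))
  labels <- as.factor(labels)
  stop_if_not_(nlevels(labels) == 2, "labels must have exactly two classes")
  if (is.null(rownames(x))) rownames(x) <- paste0("g", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("s", seq_len(ncol(x)))
  stop_if_not_(!anyDuplicated(rownames(x)), "duplicated feature ids")
  stop_if_not_(!anyDuplicated(colnames(x)), "duplicated sample ids")
  if (inherits(truth, "biomarker_truth")) truth <- truth$genes
  structure(list(x = x, labels = labels,
                 truth = if (is.null(truth)) NULL else as.character(truth),
                 provenance = provenance),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("Expression dataset: %d features x %d samples (%s)\n",
              nrow(x$x), ncol(x$x),
              paste(sprintf("%s: %d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  if (!is.null(x$truth))
    cat(sprintf("  ground truth: %d biomarkers\n", length(x$truth)))
  invisible(x)
}

#' Write / read an expression dataset
#'
#' The on-disk dialect is a directory with \code{expression.tsv} (first
#' column \code{feature_id}, remaining columns one per sample),
#' \code{labels.tsv} (\code{sample_id}, \code{group}), optionally
#' \code{truth.txt} (one feature id per line) and \code{manifest.json}
#' (provenance). The matrix round-trips to 12 significant digits; labels and
#' truth round-trip exactly. Malformed files (ragged rows, duplicated
#' feature ids, missing label entries) raise errors naming the problem.
#'
#' @param ds an \code{expression_dataset}.
#' @param dir dataset directory.
#' @return \code{read_dataset} returns an \code{expression_dataset};
#'   \code{write_dataset} returns \code{dir} invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "expression_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- as.data.frame(apply(ds$x, 2, format_sig_))
  names(m) <- colnames(ds$x)
  utils::write.table(cbind(feature_id = rownames(ds$x), m),
                     file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = colnames(ds$x),
                                group = as.character(ds$labels)),
                     file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(ds$truth))
    writeLines(ds$truth, file.path(dir, "truth.txt"))
  jsonlite::write_json(ds$provenance, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  ep <- file.path(dir, "expression.tsv")
  lines <- strsplit(readLines(ep), "\t", fixed = TRUE)
  widths <- lengths(lines)
  if (length(unique(widths)) != 1)
    stop(sprintf("ragged expression table in %s at line %d", ep,
                 which(widths != widths[1])[1]), call. = FALSE)
  header <- lines[[1]]
  stop_if_not_(header[1] == "feature_id",
               "expression table must start with a feature_id column")
  body <- lines[-1]
  feat <- vapply(body, `[`, character(1), 1)
  if (anyDuplicated(feat))
    stop(sprintf("duplicated feature id '%s' at line %d", feat[duplicated(feat)][1],
                 which(duplicated(feat))[1] + 1L), call. = FALSE)
  x <- matrix(as.numeric(unlist(lapply(body, `[`, -1))),
              nrow = length(body), byrow = TRUE,
              dimnames = list(feat, header[-1]))
  if (anyNA(x)) stop("non-numeric expression value", call. = FALSE)
  lab <- utils::read.table(file.path(dir, "labels.tsv"), sep = "\t",
                           header = TRUE, colClasses = "character")
  miss <- setdiff(colnames(x), lab$sample_id)
  if (length(miss))
    stop(sprintf("sample '%s' has no label entry", miss[1]), call. = FALSE)
  labels <- lab$group[match(colnames(x), lab$sample_id)]
  tp <- file.path(dir, "truth.txt")
  truth <- if (file.exists(tp)) readLines(tp) else NULL
  mp <- file.path(dir, "manifest.json")
  prov <- if (file.exists(mp)) jsonlite::read_json(mp) else list()
  expression_dataset(x, labels, truth = truth, provenance = prov)
}
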