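## Differential-expression statistics for transcript arrays and label-free
## proteome intensity tables.
##
## Transcript contrasts use the unequal-variance (Welch) t-test with a raw
## p < alpha significance rule; proteome contrasts use a two-sample t-test
## (Welch by default, strict Student optional) with Benjamini-Hochberg
## q < alpha.  Sample columns are named condition_replicate (e.g. T26_1).

#' Read an expression matrix from TSV
#'
#' First column `feature_id`, remaining columns one sample each, named
#' `condition_replicate`.
#'
#' @param path Input TSV.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_expression <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1L] != "feature_id")
    stop("expression TSV must start with a feature_id column")
  if (anyDuplicated(d$feature_id)) stop("duplicate feature_id values")
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d$feature_id
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix as TSV
#'
#' @param mat Numeric matrix with feature rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  d <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Condition label of each sample column
#'
#' @param labels Sample names of the form `condition_replicate`.
#' @return Character vector of condition labels.
#' @export
condition_of <- function(labels) sub("_[^_]*$", "", labels)

#' Welch unequal-variance two-sample t-test
#'
#' Thin wrapper around [stats::t.test()] with Satterthwaite degrees of
#' freedom, adding the degenerate-variance conventions needed for planted
#' noise-free data: when both groups have zero variance the p-value is 1 for
#' equal means and 0 (flagged degenerate) for unequal means.
#'
#' @param a,b Numeric replicate vectors (each of length >= 2 after removing
#'   missing values).
#' @return List with `t_stat`, `df`, `p_value` and `degenerate`.
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("welch_t needs at least two replicates per group")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t_stat = 0, df = NA_real_, p_value = 1, degenerate = TRUE))
    return(list(t_stat = sign(mean(a) - mean(b)) * Inf, df = NA_real_,
                p_value = 0, degenerate = TRUE))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, degenerate = FALSE)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted q-values, in input order.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

## Per-feature two-sample testing over a matrix contrast.
.de_table <- function(mat, treatment, control, var_equal = FALSE) {
  cond <- condition_of(colnames(mat))
  if (!treatment %in% cond) stop(sprintf("condition '%s' not present", treatment))
  if (!control %in% cond) stop(sprintf("condition '%s' not present", control))
  ta <- mat[, cond == treatment, drop = FALSE]
  co <- mat[, cond == control, drop = FALSE]
  n <- nrow(mat)
  res <- data.frame(feature_id = rownames(mat),
                    log2fc = NA_real_, t_stat = NA_real_, df = NA_real_,
                    p_value = NA_real_, q_value = NA_real_,
                    tested = FALSE, significant = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    a <- ta[i, ][!is.na(ta[i, ])]
    b <- co[i, ][!is.na(co[i, ])]
    if (length(a) < 2L || length(b) < 2L) next
    res$log2fc[i] <- mean(a) - mean(b)
    if (var(a) == 0 && var(b) == 0) {
      res$t_stat[i] <- if (mean(a) == mean(b)) 0 else
        sign(mean(a) - mean(b)) * Inf
      res$p_value[i] <- if (mean(a) == mean(b)) 1 else 0
    } else if (identical(treatment, control)) {
      res$t_stat[i] <- 0; res$df[i] <- NA_real_; res$p_value[i] <- 1
    } else {
      tt <- t.test(a, b, var.equal = var_equal)
      res$t_stat[i] <- unname(tt$statistic)
      res$df[i] <- unname(tt$parameter)
      res$p_value[i] <- tt$p.value
    }
    res$tested[i] <- TRUE
  }
  res$q_value[res$tested] <- bh_fdr(res$p_value[res$tested])
  res
}

#' Transcript differential expression (per-gene Welch test)
#'
#' Intensities are log2-transformed (unless `log2_input = TRUE`); per gene,
#' the log2 fold change is the mean log2 treatment minus mean log2 control
#' and significance follows the raw-p rule `p < alpha`.  Genes with fewer
#' than two non-missing replicates in either group are flagged untested.
#' BH q-values are reported alongside for reference.
#'
#' @param mat Expression matrix (features x samples, positive intensities).
#' @param treatment,control Condition labels.
#' @param alpha Raw p-value cutoff (default 0.05).
#' @param log2_input Set `TRUE` when `mat` is already on the log2 scale.
#' @return Data frame of per-gene results.
#' @export
transcript_de <- function(mat, treatment, control, alpha = 0.05,
                          log2_input = FALSE) {
  if (!log2_input) {
    if (any(mat[!is.na(mat)] <= 0))
      stop("intensities must be positive for log2 transformation")
    mat <- log2(mat)
  }
  res <- .de_table(mat, treatment, control, var_equal = FALSE)
  res$significant <- res$tested & !is.na(res$p_value) & res$p_value < alpha
  attr(res, "rule") <- list(test = "welch", threshold = "p",
                            alpha = alpha,
                            treatment = treatment, control = control)
  res
}

#' Preprocess a proteome intensity matrix
#'
#' Log2-transforms the raw label-free intensities and replaces every missing
#' cell with the single lowest observed log2 intensity in the whole matrix
#' (the default), or with each sample's own minimum when
#' `per_sample = TRUE`.  Features missing in all samples become constant
#' minimum rows and are flagged low-confidence.
#'
#' @param mat Raw intensity matrix; missing values as `NA`, observed values
#'   positive.
#' @param per_sample Impute with per-column minima instead of the global
#'   minimum.
#' @return Log2 matrix with no missing values; attributes `imputed` (logical
#'   matrix) and `all_missing` (feature ids imputed in every sample).
#' @export
proteome_preprocess <- function(mat, per_sample = FALSE) {
  if (any(mat[!is.na(mat)] <= 0))
    stop("observed intensities must be positive")
  lm <- log2(mat)
  missing <- is.na(lm)
  if (all(missing)) stop("matrix has no observed values")
  if (per_sample) {
    mins <- apply(lm, 2L, min, na.rm = TRUE)
    for (j in seq_len(ncol(lm))) lm[missing[, j], j] <- mins[j]
  } else {
    lm[missing] <- min(lm, na.rm = TRUE)
  }
  attr(lm, "imputed") <- missing
  attr(lm, "all_missing") <- rownames(mat)[rowSums(!missing) == 0L]
  attr(lm, "log2") <- TRUE
  lm
}

#' Proteome differential expression (BH-controlled two-sample test)
#'
#' Runs a per-protein two-sample t-test across a preprocessed (log2,
#' imputed) matrix and adjusts p-values with Benjamini-Hochberg within the
#' contrast; a protein is significant iff its q-value is below `q_alpha`.
#' Welch's unequal-variance form is the default; `test = "student"` gives
#' the literal equal-variance Student test.
#'
#' @param mat Preprocessed log2 matrix (see [proteome_preprocess()]).
#' @param treatment,control Condition labels.
#' @param q_alpha BH q-value cutoff (default 0.05).
#' @param test `"welch"` (default) or `"student"`.
#' @return Data frame of per-protein results.
#' @export
proteome_de <- function(mat, treatment, control, q_alpha = 0.05,
                        test = c("welch", "student")) {
  test <- match.arg(test)
  res <- .de_table(mat, treatment, control, var_equal = test == "student")
  res$significant <- res$tested & !is.na(res$q_value) & res$q_value < q_alpha
  attr(res, "rule") <- list(test = test, threshold = "q", alpha = q_alpha,
                            treatment = treatment, control = control)
  res
}

#' Principal-component scores of the samples
#'
#' Unvalidated QC convenience (descriptive only): PCA of the samples over
#' features with complete data.
#'
#' @param mat Expression matrix (log2 scale recommended).
#' @param n_components Number of component columns to return.
#' @return Matrix of sample scores (samples x components).
#' @export
pca_scores <- function(mat, n_components = 2L) {
  keep <- rowSums(is.na(mat)) == 0L & apply(mat, 1L, var) > 0
  pc <- prcomp(t(mat[keep, , drop = FALSE]), center = TRUE, scale. = FALSE)
  pc$x[, seq_len(min(n_components, ncol(pc$x))), drop = FALSE]
}

#' Write a differential-expression table as TSV
#'
#' @param de Result of [transcript_de()] or [proteome_de()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_tsv <- function(de, path) {
  write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
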