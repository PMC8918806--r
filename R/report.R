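# Group-level reporting: coefficient of variation, percent-difference
# tables between conditions, and agglomerative clustering of condition
# profiles with correlation distance and average linkage.

#' Coefficient of variation (percent)
#'
#' `100 * sd / mean` using the sample standard deviation (n - 1
#' denominator).
#'
#' @param values numeric vector, length >= 2, non-zero mean.
#' @return CoV in percent.
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("CoV needs at least 2 values")
  m <- mean(values)
  if (m == 0) stop("CoV undefined for zero mean")
  100 * sd(values) / m
}

#' Per-group summary of vascular parameters
#'
#' Mean, sample standard deviation and CoV (percent) of each numeric
#' parameter per group.
#'
#' @param records data.frame of [quantify_region()] rows (or any numeric
#'   parameter table).
#' @param groups group label per row.
#' @return a `group_summary` data.frame with columns `group`, `parameter`,
#'   `mean`, `sd`, `cov_pct`, `n`.
#' @export
group_summary <- function(records, groups) {
  records <- as.data.frame(records)
  num <- vapply(records, is.numeric, logical(1))
  params <- names(records)[num]
  out <- NULL
  for (g in unique(groups)) {
    sub <- records[groups == g, params, drop = FALSE]
    for (p in params) {
      v <- sub[[p]]
      v <- v[is.finite(v)]
      m <- if (length(v)) mean(v) else NA_real_
      s <- if (length(v) >= 2) sd(v) else NA_real_
      cv <- if (length(v) >= 2 && !is.na(m) && m != 0) 100 * s / m
            else NA_real_
      out <- rbind(out, data.frame(group = g, parameter = p, mean = m,
                                   sd = s, cov_pct = cv, n = length(v),
                                   stringsAsFactors = FALSE))
    }
  }
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Percent differences of group means
#'
#' For each shared numeric parameter,
#' `100 * (mean(treated) - mean(control)) / mean(control)` (e.g. control
#' morpholino versus morpholino, or untreated versus treated).
#'
#' @param control,treated data.frames of parameter values (one row per
#'   sample).
#' @return named numeric vector of percent differences; parameters with a
#'   zero control mean are `NA` and listed in attribute `"flagged"`.
#' @export
percent_difference_table <- function(control, treated) {
  control <- as.data.frame(control); treated <- as.data.frame(treated)
  if (nrow(control) == 0L || nrow(treated) == 0L)
    stop("both groups must be non-empty")
  params <- intersect(names(control)[vapply(control, is.numeric, logical(1))],
                      names(treated)[vapply(treated, is.numeric, logical(1))])
  if (length(params) == 0L) stop("no shared numeric parameters")
  out <- numeric(length(params)); names(out) <- params
  flagged <- character(0)
  for (p in params) {
    mc <- mean(control[[p]], na.rm = TRUE)
    mt <- mean(treated[[p]], na.rm = TRUE)
    if (is.na(mc) || mc == 0) {
      out[p] <- NA_real_
      flagged <- c(flagged, p)
    } else {
      out[p] <- 100 * (mt - mc) / mc
    }
  }
  attr(out, "flagged") <- flagged
  out
}

#' Cluster experimental conditions by their parameter profiles
#'
#' Agglomerative clustering of the rows of a conditions x parameters
#' matrix (typically percent-difference profiles), using distance
#' `1 - Pearson correlation` between condition profiles and average
#' linkage. With `scale_parameters = TRUE` the parameters (columns) are
#' standardised to zero mean and unit variance first, as web clustering
#' tools commonly do by default; this makes the tree invariant to
#' per-parameter affine rescaling with positive slope, at the cost of
#' being undefined for some small degenerate matrices, so the raw
#' correlation distance is the default. Identical profiles merge at
#' distance 0; perfectly anti-correlated profiles sit at distance 2.
#'
#' @param mat numeric matrix, conditions in rows (rownames used as
#'   labels), >= 2 conditions and >= 2 parameters.
#' @param scale_parameters standardise columns before clustering.
#' @return an [stats::hclust] tree (average linkage).
#' @export
cluster_conditions <- function(mat, scale_parameters = FALSE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    stop("need at least 2 conditions and 2 parameters")
  if (any(apply(mat, 1, sd) == 0))
    stop("constant condition profile: correlation distance undefined for ",
         paste(rownames(mat)[apply(mat, 1, sd) == 0], collapse = ", "))
  if (scale_parameters) {
    keep <- apply(mat, 2, sd) > 0
    mat <- scale(mat[, keep, drop = FALSE])
    if (ncol(mat) < 2L) stop("fewer than 2 varying parameters")
    if (any(apply(mat, 1, sd) == 0))
      stop("constant condition profile after standardisation")
  }
  d <- as.dist(1 - cor(t(mat)))
  hclust(d, method = "average")
}
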