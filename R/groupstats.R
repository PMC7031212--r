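#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For small untied samples the exact U null
#' distribution is used (via [stats::wilcox.test()]); with ties or larger
#' samples the normal approximation with tie correction applies. Identical
#' samples give `p = 1` with a warning.
#'
#' @param a,b numeric samples.
#' @return list with `U` (statistic for sample `a`) and `p`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))   # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  if (length(unique(c(a, b))) == 1L) {
    warning("all values identical across both samples")
    return(list(U = length(a) * length(b) / 2, p = 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' @param a,b numeric samples.
#' @return list with `D` and `p` (two-sided, asymptotic under ties).
#' @export
ks_two_sample <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  ks <- suppressWarnings(stats::ks.test(a, b))
  list(D = unname(ks$statistic), p = ks$p.value)
}

#' Standard error of the mean
#' @param x numeric sample.
#' @return `sd(x) / sqrt(n)` (sample standard deviation, divide-by-(n-1)).
#' @export
sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Assemble a long-format cohort table
#'
#' One row per (animal, metric); animal-level metric values are channel
#' averages of a per-channel metrics data.frame (e.g. [so_metrics()]
#' output).
#'
#' @param metric_tables named list (animal id -> per-channel metrics
#'   data.frame or named numeric vector).
#' @param groups named character vector, animal id -> group label.
#' @return data.frame with columns `animal`, `group`, `metric`, `value`.
#' @export
cohort_table <- function(metric_tables, groups) {
  rows <- lapply(names(metric_tables), function(an) {
    mt <- metric_tables[[an]]
    if (is.data.frame(mt)) {
      num <- vapply(mt, is.numeric, logical(1))
      vals <- colMeans(mt[, num, drop = FALSE], na.rm = TRUE)
    } else vals <- mt
    data.frame(animal = an, group = unname(groups[an]),
               metric = names(vals), value = unname(vals))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group comparison report
#'
#' Mean +/- SEM per group per metric with a two-sided Mann-Whitney U test
#' and significance stars (`*` p < 0.05, `**` p < 0.01), mirroring the
#' standard cohort summary table. No multiple-testing correction by default
#' (per-test reporting); Holm adjustment available behind `adjust`.
#'
#' @param table long-format table from [cohort_table()].
#' @param group_a,group_b group labels to contrast (defaults: first two
#'   levels encountered).
#' @param adjust `"none"` (default) or `"holm"`.
#' @return data.frame with one row per metric: group means, SEMs, `U`, `p`,
#'   `stars`.
#' @export
cohort_report <- function(table, group_a = NULL, group_b = NULL,
                          adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  gl <- unique(table$group)
  if (is.null(group_a)) group_a <- gl[1L]
  if (is.null(group_b)) group_b <- gl[2L]
  metrics <- unique(table$metric)
  rows <- lapply(metrics, function(m) {
    a <- table$value[table$metric == m & table$group == group_a]
    b <- table$value[table$metric == m & table$group == group_b]
    a <- a[is.finite(a)]
    b <- b[is.finite(b)]
    if (length(a) < 2L || length(b) < 2L) {
      warning("metric ", m, " dropped: fewer than 2 animals in a group")
      return(NULL)
    }
    mw <- suppressWarnings(mann_whitney_u(a, b))
    data.frame(metric = m,
               mean_a = mean(a), sem_a = sem(a),
               mean_b = mean(b), sem_b = sem(b),
               U = mw$U, p = mw$p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no metric had at least 2 animals per group")
  if (adjust == "holm") out$p <- stats::p.adjust(out$p, "holm")
  out$stars <- ifelse(out$p < 0.01, "**", ifelse(out$p < 0.05, "*", ""))
  attr(out, "groups") <- c(group_a, group_b)
  rownames(out) <- NULL
  out
}

#' Anterior/posterior regional split of per-channel metrics
#'
#' Averages a per-channel metric within the anterior (x >= boundary) and
#' posterior (x < boundary) regions of a surface array; the boundary
#' defaults to the array midline in x.
#'
#' @param values per-channel metric values.
#' @param geometry an [electrode_geometry()].
#' @param boundary x-coordinate separating the regions, mm (`NULL` =
#'   midline).
#' @return named numeric `c(anterior =, posterior =)`.
#' @export
regional_split <- function(values, geometry, boundary = NULL) {
  x <- geometry$positions[, 1]
  if (is.null(boundary)) boundary <- mean(range(x))
  c(anterior = mean(values[x >= boundary], na.rm = TRUE),
    posterior = mean(values[x < boundary], na.rm = TRUE))
}
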