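#' Welch's two-sample t-test
#'
#' Unequal-variance two-sided t-test (Welch-Satterthwaite degrees of
#' freedom), the comparison used for per-cell cytosolic intensities
#' between strains. Thin wrapper around [stats::t.test()] with explicit
#' conventions for degenerate inputs: if both samples have zero variance,
#' the test returns `t = 0, p = 1` for equal means and `t = +/-Inf,
#' p = 0` otherwise (documented convention; `t.test` would error).
#'
#' @param a,b numeric vectors with at least 2 values each
#' @return object of class `test_result`: `statistic`, `df`, `p.value`,
#'   `n` (the two sample sizes), `method`
#' @examples
#' welch_t_test(c(1, 2, 3), c(2, 3, 4))   # t = -1.2247, df = 4, p = 0.2887
#' @export
welch_t_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs at least 2 values")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(test_result(0, NA_real_, 1, c(length(a), length(b)),
                         "Welch two-sample t-test (degenerate)"))
    }
    return(test_result(sign(mean(a) - mean(b)) * Inf, NA_real_, 0,
                       c(length(a), length(b)),
                       "Welch two-sample t-test (degenerate)"))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  test_result(unname(tt$statistic), unname(tt$parameter), tt$p.value,
              c(length(a), length(b)), "Welch two-sample t-test")
}

#' Paired two-sided t-test
#'
#' One-sample t-test on pairwise differences. Degenerate conventions:
#' all differences zero gives `t = 0, p = 1`; constant non-zero
#' differences (zero variance) give `t = +/-Inf, p = 0` with
#' `degenerate = TRUE`.
#'
#' @param a,b numeric vectors of equal length (>= 2)
#' @return object of class `test_result`
#' @examples
#' paired_t_test(c(2, 3, 4), c(1, 1, 1))  # differences 1, 2, 3: t = 3.464
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  if (length(a) < 2L) stop("at least 2 pairs are required")
  d <- a - b
  if (stats::var(d) == 0) {
    if (mean(d) == 0) {
      return(test_result(0, length(d) - 1, 1, length(d),
                         "paired t-test (degenerate)"))
    }
    res <- test_result(sign(mean(d)) * Inf, length(d) - 1, 0, length(d),
                       "paired t-test (degenerate)")
    res$degenerate <- TRUE
    return(res)
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  test_result(unname(tt$statistic), unname(tt$parameter), tt$p.value,
              length(d), "paired t-test")
}

test_result <- function(statistic, df, p.value, n, method) {
  structure(list(statistic = statistic, df = df, p.value = p.value,
                 n = n, method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, "\n  t =", format(x$statistic, digits = 5),
      " df =", format(x$df, digits = 5),
      " p =", format(x$p.value, digits = 4),
      " n =", paste(x$n, collapse = "/"), "\n")
  invisible(x)
}

#' Summarize growth curves and extract an endpoint
#'
#' Per strain and time point: mean OD600, sample standard deviation
#' (n - 1 denominator, as used for error bars) and replicate count.
#'
#' @param od_table data frame with columns `strain`, `replicate`, `time`,
#'   `od600`
#' @param endpoint optional time at which to extract the endpoint
#'   summary; an error is raised if absent from the table
#' @return data frame `strain`, `time`, `mean`, `sd`, `n` (whole table,
#'   or the endpoint rows when `endpoint` is given); single-replicate
#'   groups report `sd = 0` and are identifiable by `n = 1`
#' @export
summarize_growth <- function(od_table, endpoint = NULL) {
  need <- c("strain", "replicate", "time", "od600")
  if (!all(need %in% names(od_table))) {
    stop("od_table needs columns: ", paste(need, collapse = ", "))
  }
  agg <- aggregate(od600 ~ strain + time, data = od_table, function(v) {
    c(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0,
      n = length(v))
  })
  out <- data.frame(strain = agg$strain, time = agg$time,
                    mean = agg$od600[, "mean"], sd = agg$od600[, "sd"],
                    n = as.integer(agg$od600[, "n"]))
  out <- out[order(out$strain, out$time), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(endpoint)) {
    out <- out[out$time == endpoint, , drop = FALSE]
    if (nrow(out) == 0L) stop("no observations at time ", endpoint)
    rownames(out) <- NULL
  }
  out
}

#' Welch comparison of growth endpoints between two strains
#'
#' Convenience composition: extracts replicate OD600 values of both
#' strains at `endpoint` and runs [welch_t_test()].
#'
#' @param od_table growth table (see [summarize_growth()])
#' @param strain_a,strain_b strain labels
#' @param endpoint time of the endpoint comparison
#' @return a `test_result`
#' @export
compare_growth_endpoint <- function(od_table, strain_a, strain_b, endpoint) {
  at <- od_table[od_table$time == endpoint, , drop = FALSE]
  if (nrow(at) == 0L) stop("no observations at time ", endpoint)
  welch_t_test(at$od600[at$strain == strain_a],
               at$od600[at$strain == strain_b])
}
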