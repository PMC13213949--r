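#' Normality-gated descriptive statistics per group
#'
#' Applies a Shapiro-Wilk test per group at the given alpha; when every
#' group passes, values are summarised as mean with standard deviation,
#' otherwise as median with the 25th--75th percentile (linear-interpolation
#' quantiles). Groups with fewer than 3 values, or degenerate (constant)
#' groups, make the gate indeterminate, which routes to the non-parametric
#' summary and test path.
#'
#' @param values Numeric vector.
#' @param groups Factor or character vector parallel to `values`.
#' @param alpha Normality-test significance level.
#' @return List with `perGroup` (data.frame: group, n, mean, sd, median, q1,
#'   q3, shapiroP, normal), `gate` ("parametric", "nonparametric",
#'   "indeterminate") and `form` ("mean_sd" or "median_iqr").
#' @examples
#' describeGroups(c(1, 2, 3, 4, 100), rep("A", 5))
#' @export
describeGroups <- function(values, groups, alpha = 0.05) {
    keep <- !is.na(values)
    values <- values[keep]
    groups <- as.character(groups)[keep]
    per <- lapply(split(values, groups), function(v) {
        sw <- if (length(v) >= 3L && stats::sd(v) > 0)
            tryCatch(stats::shapiro.test(v)$p.value, error = function(e) NA_real_)
        else NA_real_
        data.frame(n = length(v), mean = mean(v), sd = stats::sd(v),
                   median = stats::median(v),
                   q1 = unname(stats::quantile(v, 0.25, type = 7)),
                   q3 = unname(stats::quantile(v, 0.75, type = 7)),
                   shapiroP = sw, normal = !is.na(sw) && sw > alpha)
    })
    perGroup <- cbind(data.frame(group = names(per), stringsAsFactors = FALSE),
                      do.call(rbind, per))
    rownames(perGroup) <- NULL
    gate <- if (anyNA(perGroup$shapiroP)) "indeterminate"
            else if (all(perGroup$normal)) "parametric" else "nonparametric"
    list(perGroup = perGroup, gate = gate,
         form = if (gate == "parametric") "mean_sd" else "median_iqr")
}
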