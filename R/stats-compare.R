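#' Dunn's post-hoc test after Kruskal-Wallis
#'
#' Pairwise z statistics on pooled mid-ranks with the tie-corrected variance
#' term, two-sided p-values, and Bonferroni-type multiplicity adjustment
#' across all pairs.
#'
#' @param values Numeric vector.
#' @param groups Factor or character vector parallel to `values`.
#' @return data.frame: group1, group2, z, p.value, p.adj.
#' @export
dunnTest <- function(values, groups) {
    groups <- as.character(groups)
    keep <- !is.na(values)
    values <- values[keep]; groups <- groups[keep]
    N <- length(values)
    r <- rank(values)
    rbar <- tapply(r, groups, mean)
    n <- tapply(r, groups, length)
    ties <- table(values)
    tieTerm <- sum(ties^3 - ties) / (12 * (N - 1))
    gs <- names(rbar)
    pairs <- utils::combn(gs, 2L)
    k <- ncol(pairs)
    out <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                      z = NA_real_, p.value = NA_real_, p.adj = NA_real_,
                      stringsAsFactors = FALSE)
    for (i in seq_len(k)) {
        g1 <- pairs[1L, i]; g2 <- pairs[2L, i]
        se <- sqrt((N * (N + 1) / 12 - tieTerm) * (1 / n[[g1]] + 1 / n[[g2]]))
        z <- if (se > 0) (rbar[[g1]] - rbar[[g2]]) / se else 0
        out$z[i] <- z
        out$p.value[i] <- if (se > 0) 2 * stats::pnorm(-abs(z)) else 1
    }
    out$p.adj <- pmin(1, out$p.value * k)
    out
}

# Unadjusted pairwise p-values matching Tukey's error term: two-sided t on
# the ANOVA pooled variance.
.pairwiseTRaw <- function(values, groups) {
    groups <- factor(groups)
    fit <- stats::aov(values ~ groups)
    mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
    n <- tapply(values, groups, length)
    m <- tapply(values, groups, mean)
    pairs <- utils::combn(levels(groups), 2L)
    vapply(seq_len(ncol(pairs)), function(i) {
        g1 <- pairs[1L, i]; g2 <- pairs[2L, i]
        se <- sqrt(mse * (1 / n[[g1]] + 1 / n[[g2]]))
        if (se == 0) return(1)
        2 * stats::pt(-abs((m[[g1]] - m[[g2]]) / se), stats::df.residual(fit))
    }, numeric(1))
}

#' Normality-gated group comparison for one variable in one region
#'
#' Reproduces the reporting pipeline: Shapiro-Wilk per group at `alpha`; if
#' all groups look normal, Welch's t-test (2 groups) or one-way ANOVA with
#' Tukey HSD (3+); otherwise Wilcoxon rank-sum (2 groups) or Kruskal-Wallis
#' with Dunn's Bonferroni-adjusted post-hoc (3+). Censored rows are excluded
#' (complete-case). The gate is a deterministic function of the data.
#'
#' @param table Long-format data.frame with columns group, value and
#'   (optionally) region, variable, censored.
#' @param variable Variable to select (ignored when the column is absent).
#' @param region Region to select (ignored when the column is absent or NA).
#' @param alpha Significance level (0.050 in the modelled reporting).
#' @return List of class `synoStatResult`: variable, region, gate,
#'   descriptives, omnibus (method, statistic, p.value), pairwise data.frame
#'   (group1, group2, estimate, p.value, p.adj, significant), alpha, n,
#'   skipped, reason.
#' @export
compareGroups <- function(table, variable = NA, region = NA, alpha = 0.05) {
    df <- as.data.frame(table)
    if (!is.na(variable) && "variable" %in% names(df))
        df <- df[df$variable == variable, , drop = FALSE]
    if (!is.na(region) && "region" %in% names(df))
        df <- df[df$region == region, , drop = FALSE]
    if ("censored" %in% names(df)) df <- df[!df$censored, , drop = FALSE]
    df <- df[!is.na(df$value), , drop = FALSE]
    res <- list(variable = variable, region = region, alpha = alpha,
                n = table(df$group), skipped = FALSE, reason = NA_character_)
    class(res) <- "synoStatResult"
    counts <- table(df$group)
    if (length(counts) < 2L || any(counts < 3L)) {
        res$skipped <- TRUE
        res$reason <- "need >= 2 groups with >= 3 non-censored values each"
        return(res)
    }
    v <- df$value; g <- factor(df$group)
    res$descriptives <- describeGroups(v, g, alpha)
    res$gate <- res$descriptives$gate
    parametric <- res$gate == "parametric"
    degenerate <- stats::sd(v) == 0
    ng <- nlevels(g)
    pairs <- utils::combn(levels(g), 2L)
    means <- tapply(v, g, mean); medians <- tapply(v, g, median)
    est <- vapply(seq_len(ncol(pairs)), function(i) {
        if (parametric) means[[pairs[1L, i]]] - means[[pairs[2L, i]]]
        else medians[[pairs[1L, i]]] - medians[[pairs[2L, i]]]
    }, numeric(1))
    if (degenerate) {
        res$omnibus <- list(method = "degenerate", statistic = NA_real_,
                            p.value = 1)
        res$pairwise <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                                   estimate = est, p.value = 1, p.adj = 1,
                                   significant = FALSE,
                                   stringsAsFactors = FALSE)
        return(res)
    }
    if (parametric) {
        if (ng == 2L) {
            tt <- stats::t.test(v ~ g)   # Welch
            res$omnibus <- list(method = "Welch t-test",
                                statistic = unname(tt$statistic),
                                p.value = tt$p.value)
            praw <- padj <- tt$p.value
        } else {
            fit <- stats::aov(v ~ g)
            an <- summary(fit)[[1L]]
            res$omnibus <- list(method = "one-way ANOVA",
                                statistic = an[["F value"]][1L],
                                p.value = an[["Pr(>F)"]][1L])
            tk <- stats::TukeyHSD(fit)$g
            # TukeyHSD rows are "B-A"; align to our pair order
            key <- paste(pairs[2L, ], pairs[1L, ], sep = "-")
            padj <- tk[key, "p adj"]
            praw <- .pairwiseTRaw(v, g)
        }
    } else {
        if (ng == 2L) {
            wt <- suppressWarnings(stats::wilcox.test(v ~ g, exact = FALSE))
            res$omnibus <- list(method = "Wilcoxon rank-sum",
                                statistic = unname(wt$statistic),
                                p.value = wt$p.value)
            praw <- padj <- wt$p.value
        } else {
            kw <- stats::kruskal.test(v, g)
            res$omnibus <- list(method = "Kruskal-Wallis",
                                statistic = unname(kw$statistic),
                                p.value = kw$p.value)
            dn <- dunnTest(v, g)
            key <- paste(dn$group1, dn$group2, sep = ":")
            ord <- match(paste(pairs[1L, ], pairs[2L, ], sep = ":"), key)
            praw <- dn$p.value[ord]
            padj <- dn$p.adj[ord]
        }
    }
    res$pairwise <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                               estimate = est, p.value = unname(praw),
                               p.adj = unname(padj),
                               significant = unname(padj) < alpha,
                               stringsAsFactors = FALSE)
    res
}

#' @export
print.synoStatResult <- function(x, ...) {
    cat(sprintf("Group comparison: %s%s\n", x$variable,
                if (!is.na(x$region)) sprintf(" [%s]", x$region) else ""))
    if (x$skipped) {
        cat("  skipped:", x$reason, "\n")
        return(invisible(x))
    }
    cat(sprintf("  gate: %s; omnibus %s p = %.4g (alpha %.3f)\n", x$gate,
                x$omnibus$method, x$omnibus$p.value, x$alpha))
    print(x$pairwise, row.names = FALSE)
    invisible(x)
}

#' Did a comparison flag `group1 > group2`?
#'
#' TRUE when the pair's adjusted p-value is below alpha and the observed
#' group summary (mean under the parametric gate, median otherwise) orders
#' the two groups as asked.
#'
#' @param result A `synoStatResult` from [compareGroups()].
#' @param greater,lesser Group labels.
#' @return Logical scalar.
#' @export
flaggedGreater <- function(result, greater, lesser) {
    if (result$skipped) return(FALSE)
    pw <- result$pairwise
    i <- which((pw$group1 == greater & pw$group2 == lesser) |
               (pw$group1 == lesser & pw$group2 == greater))
    if (!length(i)) return(FALSE)
    est <- pw$estimate[i[1L]]
    if (pw$group1[i[1L]] == lesser) est <- -est
    isTRUE(pw$significant[i[1L]] && est > 0)
}
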