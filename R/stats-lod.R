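#' Flag analyte values below the limit of detection
#'
#' Values strictly below their analyte's LOD are flagged censored (a value
#' exactly at the LOD is kept). Analytes censored in 100 % of samples are
#' excluded from testing and listed in a below-LOD report block; partially
#' censored analytes are retained with their censored rows excluded
#' complete-case by [compareGroups()].
#'
#' @param analytes data.frame with columns sample_id, group, analyte, value
#'   and either a `lod` column or a `lod` argument.
#' @param lod Optional named numeric vector analyte -> LOD, overriding /
#'   replacing the table's column. Every analyte must have an LOD.
#' @return List of class `lodReport`: `table` (input plus logical `censored`),
#'   `belowLOD` (analytes fully censored), `censoredFraction` (named numeric).
#' @export
censorBelowLOD <- function(analytes, lod = NULL) {
    df <- as.data.frame(analytes)
    stopifnot(all(c("sample_id", "group", "analyte", "value") %in% names(df)))
    if (!is.null(lod)) {
        df$lod <- unname(lod[df$analyte])
    }
    if (!"lod" %in% names(df)) stop("no LOD column or lod argument supplied")
    bad <- unique(df$analyte[is.na(df$lod)])
    if (length(bad))
        stop(sprintf("missing LOD for analyte(s): %s", paste(bad, collapse = ", ")))
    df$censored <- df$value < df$lod
    frac <- tapply(df$censored, df$analyte, mean)
    out <- list(table = df,
                belowLOD = names(frac)[frac == 1],
                censoredFraction = frac)
    class(out) <- "lodReport"
    out
}

#' @export
print.lodReport <- function(x, ...) {
    cat(sprintf("Analyte LOD report: %d analytes, %d fully below LOD\n",
                length(x$censoredFraction), length(x$belowLOD)))
    if (length(x$belowLOD))
        cat("  below LOD in all samples:", paste(x$belowLOD, collapse = ", "), "\n")
    part <- x$censoredFraction[x$censoredFraction > 0 & x$censoredFraction < 1]
    for (a in names(part))
        cat(sprintf("  %s: %.0f%% censored\n", a, 100 * part[[a]]))
    invisible(x)
}

#' Group comparisons for every testable analyte
#'
#' Runs [compareGroups()] per analyte on the complete-case values, skipping
#' analytes below LOD in all samples (these appear only in the report's
#' `belowLOD` element). Analytes with any group entirely censored are
#' skipped with a reason.
#'
#' @param report A `lodReport` from [censorBelowLOD()] (or a raw analyte
#'   data.frame, which is censored first).
#' @param alpha Significance level.
#' @return List: `results` (named list of `synoStatResult`), `belowLOD`,
#'   `censoredFraction`.
#' @export
analyteCompare <- function(report, alpha = 0.05) {
    if (!inherits(report, "lodReport")) report <- censorBelowLOD(report)
    df <- report$table
    testable <- setdiff(unique(df$analyte), report$belowLOD)
    results <- list()
    for (a in testable) {
        sub <- df[df$analyte == a, , drop = FALSE]
        groupsCensored <- tapply(sub$censored, sub$group, all)
        if (any(groupsCensored)) {
            res <- list(variable = a, region = NA, alpha = alpha,
                        skipped = TRUE,
                        reason = sprintf("group(s) entirely censored: %s",
                            paste(names(groupsCensored)[groupsCensored],
                                  collapse = ", ")))
            class(res) <- "synoStatResult"
            results[[a]] <- res
            next
        }
        sub$variable <- a
        results[[a]] <- compareGroups(sub, variable = a, alpha = alpha)
    }
    list(results = results, belowLOD = report$belowLOD,
         censoredFraction = report$censoredFraction)
}
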