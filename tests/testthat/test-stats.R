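test_that("descriptive summaries follow the normality gate", {
    d <- describeGroups(c(5, 5, 5, 5), rep("A", 4))
    expect_equal(d$gate, "indeterminate")
    expect_equal(d$form, "median_iqr")
    expect_equal(d$perGroup$median, 5)
    expect_equal(d$perGroup$q1, 5)
    expect_equal(d$perGroup$q3, 5)

    d2 <- describeGroups(c(1, 2, 3, 4, 100), rep("A", 5))
    expect_equal(d2$perGroup$median, 3)
    expect_equal(d2$perGroup$q1, 2)
    expect_equal(d2$perGroup$q3, 4)
    expect_equal(d2$gate, "nonparametric")   # Shapiro rejects the outlier

    set.seed(51)
    v <- rnorm(200, mean = 10, sd = 2)
    d3 <- describeGroups(v, rep("A", 200))
    expect_equal(d3$gate, "parametric")
    expect_lt(abs(d3$perGroup$mean - 10), 3 * 2 / sqrt(200))

    d4 <- describeGroups(c(1, 2), rep("A", 2))
    expect_equal(d4$gate, "indeterminate")
})

test_that("identical constant groups yield degenerate unit p-values", {
    tab <- data.frame(group = rep(c("F", "CTRL", "OA"), each = 4),
                      value = 7, variable = "v", region = "ICL")
    res <- compareGroups(tab, "v", "ICL")
    expect_equal(res$omnibus$p.value, 1)
    expect_false(any(res$pairwise$significant))
})

test_that("a 3-SD shifted group is flagged and the omnibus agrees with a permutation oracle", {
    set.seed(52)
    v <- c(rnorm(10), rnorm(10), rnorm(10, mean = 3))
    g <- rep(c("A", "B", "C"), each = 10)
    res <- compareGroups(data.frame(group = g, value = v, variable = "v",
                                    region = "r"), "v", "r")
    pw <- res$pairwise
    expect_true(pw$significant[pw$group1 == "A" & pw$group2 == "C"])
    expect_true(pw$significant[pw$group1 == "B" & pw$group2 == "C"])
    expect_true(flaggedGreater(res, "C", "A"))
    expect_false(flaggedGreater(res, "A", "C"))
    # permutation reference for the omnibus decision (F statistic)
    obs <- rawFstat(v, factor(g))
    perm <- replicate(10000, rawFstat(v, factor(sample(g))))
    pPerm <- mean(perm >= obs)
    expect_lt(abs(res$omnibus$p.value - pPerm), 0.02)
})

test_that("two-group comparisons use Welch or rank-sum by the gate", {
    set.seed(53)
    tab <- data.frame(group = rep(c("A", "B"), each = 12),
                      value = c(rnorm(12), rnorm(12, 2)),
                      variable = "v", region = "r")
    res <- compareGroups(tab, "v", "r")
    expect_match(res$omnibus$method, "Welch|rank-sum")
    expect_true(res$pairwise$significant[1L])
    skew <- data.frame(group = rep(c("A", "B"), each = 12),
                       value = exp(c(rnorm(12, sd = 2), rnorm(12, sd = 2))),
                       variable = "v", region = "r")
    res2 <- compareGroups(skew, "v", "r")
    expect_true(res2$gate %in% c("nonparametric", "parametric"))
    expect_true(res2$skipped == FALSE)
})

test_that("Dunn's test reproduces independently computed z and p values", {
    vals <- c(1.2, 3.4, 2.2, 4.1, 2.0, 5.6, 7.1, 6.3, 5.9, 2.2, 2.9, 3.4, 1.1, 0.7)
    grps <- c(rep("A", 5), rep("B", 4), rep("C", 5))
    dn <- dunnTest(vals, grps)
    ref <- data.frame(group1 = c("A", "A", "B"), group2 = c("B", "C", "C"),
                      z = c(-2.2499448117, 0.5303170779, 2.7499325476),
                      p.value = c(0.0244524488, 0.5958921079, 0.0059607533),
                      p.adj = c(0.0733573465, 1, 0.01788226))
    expect_equal(dn$z, ref$z, tolerance = 1e-8)
    expect_equal(dn$p.value, ref$p.value, tolerance = 1e-8)
    expect_equal(dn$p.adj, ref$p.adj, tolerance = 1e-8)
    kw <- kruskal.test(vals, factor(grps))
    expect_equal(unname(kw$statistic), 8.316556291390729, tolerance = 1e-10)
})

test_that("adjusted p-values never fall below their raw counterparts", {
    set.seed(54)
    for (rep in 1:30) {
        heavy <- rep %% 2 == 0
        v <- if (heavy) exp(rnorm(30, sd = 1.5)) else rnorm(30)
        g <- sample(rep(c("A", "B", "C"), each = 10))
        res <- compareGroups(data.frame(group = g, value = v,
                                        variable = "v", region = "r"), "v", "r")
        expect_true(all(res$pairwise$p.adj >= res$pairwise$p.value - 1e-12))
    }
})

test_that("LOD censoring is strict and routes analytes correctly", {
    tab <- data.frame(
        sample_id = rep(sprintf("s%d", 1:10), times = 3),
        group = rep(rep(c("F", "CTRL"), each = 5), times = 3),
        analyte = rep(c("low", "edge", "mixed"), each = 10),
        value = c(runif(10, 0, 4), rep(5, 10),
                  c(runif(4, 0, 4), runif(6, 6, 20))),
        lod = rep(5, 30))
    rep_ <- censorBelowLOD(tab)
    expect_equal(rep_$belowLOD, "low")
    expect_false(any(rep_$table$censored[rep_$table$analyte == "edge"]))
    expect_equal(unname(rep_$censoredFraction[["mixed"]]), 0.4)
    expect_error(censorBelowLOD(tab[, setdiff(names(tab), "lod")]),
                 "no LOD")
    expect_error(censorBelowLOD(tab[, setdiff(names(tab), "lod")],
                                lod = c(low = 5, edge = 5)),
                 "missing LOD.*mixed")
    ac <- analyteCompare(rep_)
    expect_false("low" %in% names(ac$results))
    # a group entirely censored skips the analyte with a reason
    tab2 <- data.frame(sample_id = sprintf("s%d", 1:8),
                       group = rep(c("F", "CTRL"), each = 4),
                       analyte = "a",
                       value = c(runif(4, 0, 1), runif(4, 10, 20)), lod = 5)
    ac2 <- analyteCompare(censorBelowLOD(tab2))
    expect_true(ac2$results[["a"]]$skipped)
    expect_match(ac2$results[["a"]]$reason, "entirely censored")
})

test_that("the comparison gate is deterministic and seed-free", {
    set.seed(55)
    tab <- data.frame(group = rep(c("A", "B", "C"), each = 8),
                      value = exp(rnorm(24)), variable = "v", region = "r")
    r1 <- compareGroups(tab, "v", "r")
    set.seed(99999)
    r2 <- compareGroups(tab, "v", "r")
    expect_identical(r1$gate, r2$gate)
    expect_identical(r1$pairwise, r2$pairwise)
})
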