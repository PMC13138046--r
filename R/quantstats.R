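# Particle-concentration arithmetic and the statistical comparison suite.

#' Count particles in a pseudo-2D field image
#'
#' Thresholds a single epifluorescence field, labels 8-connected components
#' of at least `min_area_px` pixels and reports the count and areal density.
#' Touching particles merge into one component; this undercount is inherent
#' to threshold-based counting.
#'
#' @param image 2D numeric matrix.
#' @param pixel_size Pixel size, um/px (defines the field area).
#' @param method Threshold method (see [binarize()]).
#' @param min_area_px Minimum component area in px.
#' @return List with `count` and `areal_density` (particles/um^2).
#' @export
count_field <- function(image, pixel_size, method = "otsu", min_area_px = 2) {
  check_that(is.matrix(image), "quantstats", "image must be a 2D matrix")
  field_area <- length(image) * pixel_size^2
  check_that(field_area > 0, "quantstats", "zero field area")
  count <- 0L
  if (diff(range(image)) > 0) {
    fun <- if (is.function(method)) method else
      switch(method, otsu = otsu_threshold,
             stop_fk("quantstats", "unknown threshold method: ", method))
    cmp <- mask_components(image > fun(image))
    count <- sum(cmp$sizes >= min_area_px)
  }
  list(count = count, areal_density = count / field_area)
}

#' Convert an areal particle density to a volumetric concentration
#'
#' A pseudo-2D field image integrates fluorescence over the depth of field
#' of the optics; dividing the areal density by that depth (here ~700 nm,
#' determined for a 63x/1.2 NA setup) estimates the particle concentration
#' per volume.
#'
#' @param areal_density Particles per um^2.
#' @param depth_of_field Depth of field, um.
#' @param count,field_area Optional provenance fields carried through.
#' @return Object of class `concentration_estimate` with `areal_density`,
#'   `depth_of_field`, `volumetric_density` (particles/um^3) and
#'   `per_microliter` (= volumetric density x 1e9).
#' @export
to_volumetric <- function(areal_density, depth_of_field = 0.7, count = NA,
                          field_area = NA) {
  check_that(depth_of_field > 0, "quantstats", "depth_of_field must be > 0")
  check_that(areal_density >= 0, "quantstats", "areal_density must be >= 0")
  vol <- areal_density / depth_of_field
  structure(list(count = count, field_area = field_area,
                 areal_density = areal_density,
                 depth_of_field = depth_of_field,
                 volumetric_density = vol,
                 per_microliter = vol * 1e9),
            class = "concentration_estimate")
}

#' Dilution factor to reach a target areal density
#'
#' Reported, never auto-applied; a factor below 1 means the suspension is
#' already below target.
#'
#' @param current A `concentration_estimate`.
#' @param target_per_area Target areal density, particles/um^2.
#' @return List with `factor` and `below_target` flag.
#' @export
dilution_factor <- function(current, target_per_area) {
  check_that(target_per_area > 0, "quantstats", "target must be > 0")
  check_that(current$areal_density > 0, "quantstats",
             "current areal density must be > 0")
  f <- current$areal_density / target_per_area
  list(factor = f, below_target = f < 1)
}

#' Final concentration after a volumetric mix
#'
#' @param stock_conc Stock concentration, mg/mL.
#' @param stock_vol Stock volume, uL.
#' @param total_vol Final total volume, uL.
#' @return Final concentration, mg/mL.
#' @export
mix_concentration <- function(stock_conc, stock_vol, total_vol) {
  check_that(stock_vol > 0 && total_vol > 0, "quantstats",
             "volumes must be positive")
  check_that(stock_vol <= total_vol, "quantstats",
             "stock volume exceeds total volume")
  stock_conc * stock_vol / total_vol
}

comparison_result <- function(test, statistic, df, p, groups,
                              posthoc = NULL, outlier_flags = NULL) {
  structure(list(test = test, statistic = statistic, df = df, p = p,
                 groups = groups, posthoc = posthoc,
                 outlier_flags = outlier_flags),
            class = "comparison_result")
}

#' Two-tailed Welch's t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom. When both samples have zero variance the statistic is undefined
#' and a structured error is raised (degenerate-variance case).
#'
#' @param a,b Numeric samples, each n >= 2.
#' @return A `comparison_result` with `statistic`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  check_that(length(a) >= 2 && length(b) >= 2, "quantstats",
             "each sample needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop_fk("quantstats",
            "both samples have zero variance; Welch statistic undefined")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  comparison_result("welch_t", unname(ht$statistic), unname(ht$parameter),
                    ht$p.value, c("a", "b"))
}

#' One- or two-way ANOVA with Tukey-Kramer post hoc comparisons
#'
#' One-way: classical F test plus Tukey-Kramer pairwise comparisons
#' (studentized-range correction with the unequal-n adjustment). Two-way:
#' full factorial model with interaction; F tests use type-II sums of
#' squares, appropriate for unbalanced designs where replicate counts
#' differ between conditions; Tukey-Kramer tables are produced for each
#' main factor.
#'
#' @param values Numeric response vector.
#' @param groups Factor (one-way) of group labels.
#' @param factor_a,factor_b Factors for the two-way design (used when
#'   `design = "two_way"`; `groups` is then ignored).
#' @param design `"one_way"` or `"two_way"`.
#' @return A `comparison_result`; `statistic`, `df`, `p` are named vectors
#'   for the two-way design, and `posthoc` holds the Tukey-Kramer tables
#'   (`diff`, `lwr`, `upr`, `p_adj` per unordered pair).
#' @export
anova_tukey <- function(values, groups = NULL, factor_a = NULL,
                        factor_b = NULL, design = c("one_way", "two_way")) {
  design <- match.arg(design)
  if (design == "one_way") {
    g <- factor(groups)
    check_that(nlevels(g) >= 2, "quantstats", "need >= 2 groups")
    check_that(all(table(g) >= 2), "quantstats", "every group needs n >= 2")
    fit <- stats::aov(values ~ g)
    s <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$g
    ph <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                     lwr = tk[, "lwr"], upr = tk[, "upr"],
                     p_adj = tk[, "p adj"], row.names = NULL)
    comparison_result("anova_one_way", s[["F value"]][1],
                      c(df1 = s[["Df"]][1], df2 = s[["Df"]][2]),
                      s[["Pr(>F)"]][1], levels(g), posthoc = ph)
  } else {
    fa <- factor(factor_a)
    fb <- factor(factor_b)
    check_that(length(fa) == length(values) && length(fb) == length(values),
               "quantstats", "factor lengths must match values")
    cells <- table(fa, fb)
    if (any(cells == 0)) {
      empty <- which(cells == 0, arr.ind = TRUE)[1, ]
      stop_fk("quantstats", "empty cell in two-way design: ",
              rownames(cells)[empty[1]], " x ", colnames(cells)[empty[2]])
    }
    check_that(all(cells >= 2), "quantstats", "every cell needs n >= 2")
    fit <- stats::aov(values ~ fa * fb)
    a2 <- car::Anova(fit, type = 2)
    terms <- c("fa", "fb", "fa:fb")
    labels <- c("A", "B", "A:B")
    stat <- stats::setNames(a2[terms, "F value"], labels)
    p <- stats::setNames(a2[terms, "Pr(>F)"], labels)
    df <- stats::setNames(c(a2[terms, "Df"], a2["Residuals", "Df"]),
                          c(labels, "residual"))
    tk <- stats::TukeyHSD(fit, which = c("fa", "fb"))
    ph <- lapply(tk, function(m) {
      data.frame(pair = rownames(m), diff = m[, "diff"], lwr = m[, "lwr"],
                 upr = m[, "upr"], p_adj = m[, "p adj"], row.names = NULL)
    })
    names(ph) <- c("A", "B")
    comparison_result("anova_two_way", stat, df, p,
                      list(A = levels(fa), B = levels(fb)), posthoc = ph)
  }
}

#' Pearson dose-response correlation
#'
#' Sample Pearson correlation with the two-tailed p-value from the
#' t transform on n - 2 degrees of freedom, as used for testing
#' dose-dependence of gelation parameters on particle concentration.
#'
#' @param x Concentrations (or doses).
#' @param y Responses.
#' @return A `comparison_result` with `statistic` = r and `p`.
#' @export
pearson_dose <- function(x, y) {
  check_that(length(x) == length(y), "quantstats", "x and y lengths differ")
  check_that(length(x) >= 3, "quantstats", "need n >= 3")
  check_that(stats::var(x) > 0 && stats::var(y) > 0, "quantstats",
             "zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  comparison_result("pearson", unname(ct$estimate), unname(ct$parameter),
                    ct$p.value, NULL)
}

#' Flag outliers by the 1.5 IQR boxplot rule
#'
#' Points outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are flagged. Flags are
#' advisory: exclusion is always an explicit caller choice. With n < 4 the
#' quartiles are too unstable; an all-FALSE mask is returned with a
#' warning.
#'
#' @param x Numeric sample.
#' @return Logical mask, TRUE = outlier.
#' @export
flag_outliers <- function(x) {
  if (length(x) < 4) {
    warning("n < 4: outlier flags not assigned")
    return(rep(FALSE, length(x)))
  }
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  x < q[1] - 1.5 * iqr | x > q[2] + 1.5 * iqr
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, p = %s\n", x$test,
              paste(format(x$statistic, digits = 4), collapse = ", "),
              paste(format(x$p, digits = 4), collapse = ", ")))
  if (!is.null(x$posthoc)) {
    cat("Tukey-Kramer post hoc:\n")
    print(x$posthoc)
  }
  invisible(x)
}
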