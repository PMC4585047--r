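#' Two-way factorial ANOVA for one region
#'
#' Fits activation counts of one region against treatment, phase and their
#' interaction. The model is a cell-means fit tested with Type-III-style
#' (sum-to-zero) contrasts, which on the balanced design of the emulated
#' study equals the classical balanced two-way decomposition; unbalanced
#' tables (dropped animals) are handled without silently changing the
#' hypotheses being tested.
#'
#' @param table A `cfos_table` (see [read_cfos_table()], [simulate_cfos()]).
#' @param region Region column name.
#' @return Object of class `cfos_aov`: list with components `region`,
#'   `F` / `p` (named vectors: treatment, time, interaction), `df`
#'   (numerator per term and residual), `cell_means` and `cell_ns`
#'   (2x2 treatment x phase), `mse`, and the underlying `lm` fit.
#' @examples
#' tab <- simulate_cfos(cfos_sim_config(seed = 7))
#' two_way_anova(tab, "PVN")
#' @export
two_way_anova <- function(table, region) {
  d <- check_region_data(table, region)
  fit <- lm(y ~ treatment * phase, data = d,
            contrasts = list(treatment = contr.sum, phase = contr.sum))
  a <- car::Anova(fit, type = 3)
  terms <- c(treatment = "treatment", time = "phase",
             interaction = "treatment:phase")
  rows <- match(terms, rownames(a))
  Fv <- setNames(a[rows, "F value"], names(terms))
  pv <- setNames(a[rows, "Pr(>F)"], names(terms))
  df_num <- setNames(a[rows, "Df"], names(terms))
  df_res <- a[rownames(a) == "Residuals", "Df"]

  means <- tapply(d$y, list(d$treatment, d$phase), mean)
  ns <- tapply(d$y, list(d$treatment, d$phase), length)
  structure(
    list(region = region, F = Fv, p = pv,
         df = list(numerator = df_num, residual = df_res),
         cell_means = means, cell_ns = ns,
         mse = a[rownames(a) == "Residuals", "Sum Sq"] / df_res,
         fit = fit),
    class = "cfos_aov"
  )
}

# Validate factors/counts for one region; returns data.frame(y, treatment,
# phase). Errors name the offending cell or region.
check_region_data <- function(table, region) {
  if (!region %in% region_names(table))
    stop("unknown region: ", region)
  y <- table[[region]]
  if (!is.numeric(y)) stop("region column '", region, "' is not numeric")
  d <- data.frame(y = y, treatment = table$treatment, phase = table$phase)
  d <- d[complete.cases(d), , drop = FALSE]
  ns <- base::table(d$treatment, d$phase)
  if (any(ns < 2)) {
    bad <- which(ns < 2, arr.ind = TRUE)[1, ]
    stop(sprintf("design cell %s x %s has %d observation(s); need >= 2",
                 rownames(ns)[bad[1]], colnames(ns)[bad[2]],
                 ns[bad[1], bad[2]]))
  }
  within_var <- tapply(d$y, list(d$treatment, d$phase), var)
  if (sum(within_var * (ns - 1)) <= 0)
    stop("zero residual variance for region '", region,
         "': degenerate data")
  d
}

#' @export
print.cfos_aov <- function(x, ...) {
  cat(sprintf("Two-way ANOVA, region %s (df = %d, %d)\n", x$region,
              x$df$numerator[[1]], x$df$residual))
  out <- data.frame(F = round(x$F, 3),
                    p = signif(x$p, 4))
  print(out)
  invisible(x)
}

#' Classify a region into an activation pattern
#'
#' Maps the significance of the treatment effect, time (phase) effect and
#' treatment-by-time interaction to one of five activation patterns:
#' \describe{
#'   \item{1}{treatment only (time no, interaction no)}
#'   \item{2}{time only}
#'   \item{3}{treatment and interaction (time may or may not be
#'     significant)}
#'   \item{4}{treatment and time, no interaction}
#'   \item{5}{no significant effects}
#'   \item{other}{any remaining combination (an interaction without a
#'     treatment main effect); the five-pattern taxonomy is not exhaustive
#'     and such regions are not forced into a wrong label}
#' }
#'
#' @param x A `cfos_aov` result, a logical vector of length 3 (treatment,
#'   time, interaction significance), or a data.frame with logical columns
#'   `treatment`, `time`, `interaction` (one row per region).
#' @param alpha Significance level applied to the p-values of a `cfos_aov`
#'   (ignored when flags are passed directly). Default 0.05.
#' @param ... Unused.
#' @return For a single result/flag vector, a list with `pattern` (character
#'   among "1".."5", "other") and the three `flags`; for a data.frame,
#'   a character vector of labels.
#' @examples
#' classify_pattern(c(TRUE, FALSE, FALSE))   # pattern 1
#' classify_pattern(c(FALSE, TRUE, FALSE))   # pattern 2
#' @export
classify_pattern <- function(x, alpha = 0.05, ...) UseMethod("classify_pattern")

pattern_from_flags <- function(trt, tim, inter) {
  if (trt && inter) "3"
  else if (trt && tim) "4"
  else if (trt) "1"
  else if (!trt && tim && !inter) "2"
  else if (!trt && !tim && !inter) "5"
  else "other"
}

#' @rdname classify_pattern
#' @export
classify_pattern.cfos_aov <- function(x, alpha = 0.05, ...) {
  flags <- x$p < alpha
  names(flags) <- names(x$p)
  list(region = x$region,
       pattern = pattern_from_flags(flags[["treatment"]], flags[["time"]],
                                    flags[["interaction"]]),
       flags = flags)
}

#' @rdname classify_pattern
#' @export
classify_pattern.logical <- function(x, alpha = 0.05, ...) {
  stopifnot(length(x) == 3, !anyNA(x))
  list(pattern = pattern_from_flags(x[[1]], x[[2]], x[[3]]),
       flags = setNames(x, c("treatment", "time", "interaction")))
}

#' @rdname classify_pattern
#' @export
classify_pattern.data.frame <- function(x, alpha = 0.05, ...) {
  stopifnot(all(c("treatment", "time", "interaction") %in% names(x)))
  mapply(pattern_from_flags, as.logical(x$treatment), as.logical(x$time),
         as.logical(x$interaction))
}

#' Bonferroni-corrected simple-effect contrasts for one region
#'
#' The four pairwise contrasts of the 2x2 design (MA vs SAL within each
#' phase; light vs dark within each treatment), tested with t statistics
#' built on the pooled ANOVA error term, Bonferroni-adjusted for the family
#' of 4 contrasts.
#'
#' @inheritParams two_way_anova
#' @param alpha Significance level used only for the `significant` flag.
#' @return Object of class `cfos_posthoc`: data.frame with one row per
#'   contrast: `contrast`, `estimate` (mean difference), `t`, `df`,
#'   `p` (raw), `p_adj` (Bonferroni, capped at 1), `significant`.
#' @export
simple_effects <- function(table, region, alpha = 0.05) {
  aov <- two_way_anova(table, region)
  m <- aov$cell_means
  n <- aov$cell_ns
  mse <- aov$mse
  df <- aov$df$residual

  contrasts <- list(
    "MA - SAL | light" = list(a = c("MA", "light"), b = c("SAL", "light")),
    "MA - SAL | dark"  = list(a = c("MA", "dark"),  b = c("SAL", "dark")),
    "light - dark | MA"  = list(a = c("MA", "light"), b = c("MA", "dark")),
    "light - dark | SAL" = list(a = c("SAL", "light"), b = c("SAL", "dark"))
  )
  rows <- lapply(names(contrasts), function(nm) {
    cc <- contrasts[[nm]]
    est <- m[cc$a[1], cc$a[2]] - m[cc$b[1], cc$b[2]]
    se <- sqrt(mse * (1 / n[cc$a[1], cc$a[2]] + 1 / n[cc$b[1], cc$b[2]]))
    t <- est / se
    p <- 2 * pt(-abs(t), df)
    data.frame(contrast = nm, estimate = est, t = t, df = df,
               p = p, p_adj = min(1, 4 * p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  attr(out, "region") <- region
  class(out) <- c("cfos_posthoc", "data.frame")
  out
}

#' Per-region activation statistics and pattern labels
#'
#' Runs [two_way_anova()], [classify_pattern()] and [simple_effects()] on
#' every region of a sample table. Trends (0.05 < p < 0.1) are annotated
#' but never influence the pattern label, which uses significance at
#' `alpha` only.
#'
#' @inheritParams two_way_anova
#' @param alpha Significance level for classification (default 0.05).
#' @return Object of class `cfos_patterns`: data.frame with one row per
#'   region holding F, df and p for the three effects, the pattern label,
#'   a `trend` annotation, and the four Bonferroni-adjusted simple-effect
#'   p-values.
#' @examples
#' tab <- simulate_cfos(cfos_sim_config(seed = 3))
#' ap <- activation_patterns(tab)
#' table(ap$pattern)
#' @export
activation_patterns <- function(table, alpha = 0.05) {
  regions <- region_names(table)
  rows <- lapply(regions, function(r) {
    a <- two_way_anova(table, r)
    cl <- classify_pattern(a, alpha = alpha)
    trend <- names(a$p)[a$p >= alpha & a$p < 0.1]
    ph <- simple_effects(table, r, alpha = alpha)
    data.frame(
      region = r,
      F_treatment = a$F[["treatment"]], p_treatment = a$p[["treatment"]],
      F_time = a$F[["time"]], p_time = a$p[["time"]],
      F_interaction = a$F[["interaction"]],
      p_interaction = a$p[["interaction"]],
      df1 = a$df$numerator[[1]], df2 = a$df$residual,
      pattern = cl$pattern,
      trend = if (length(trend)) paste(trend, collapse = ";") else "",
      p_adj_MA_vs_SAL_light = ph$p_adj[1],
      p_adj_MA_vs_SAL_dark = ph$p_adj[2],
      p_adj_light_vs_dark_MA = ph$p_adj[3],
      p_adj_light_vs_dark_SAL = ph$p_adj[4],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("cfos_patterns", "data.frame")
  out
}

#' @export
print.cfos_patterns <- function(x, ...) {
  cat(sprintf("Activation patterns (%d regions, alpha = %g)\n",
              nrow(x), attr(x, "alpha")))
  tab <- x[, c("region", "F_treatment", "F_time", "F_interaction",
               "pattern")]
  tab[2:4] <- lapply(tab[2:4], round, 2)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.cfos_patterns <- function(object, ...) {
  split(object$region, factor(object$pattern,
                              levels = c("1", "2", "3", "4", "5", "other")))
}
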