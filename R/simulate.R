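#' Default brain-region panel
#'
#' The 17-region panel quantified in the motivating study design:
#' hypothalamic (SCN, PVN, ARC, VMH, DMH), thalamic (PVT), amygdalar
#' (CEA, BLA, MEA), hippocampal (DG, CA1, CA3), cortical (ILC, CIN),
#' extended amygdala (BNST) and accumbens (NACc, NACs) regions.
#'
#' @return Character vector of region identifiers.
#' @export
cfos_regions <- function() {
  c("SCN", "PVN", "PVT", "CEA", "BLA", "MEA", "DG", "CA1", "CA3",
    "ILC", "ARC", "VMH", "DMH", "BNST", "CIN", "NACc", "NACs")
}

#' Build a latent inter-regional correlation matrix
#'
#' Constructs the target correlation matrix for the synthetic-data copula:
#' a constant baseline correlation `base_r` between all region pairs,
#' optionally with a "hub" region coupled at `r` to a set of partner
#' regions. Hub-partner entries equal `r` exactly. Partner-partner entries
#' stay at `base_r` when that is feasible; a star of near-orthogonal
#' partners with `sum(r^2) > 1` is not a valid correlation matrix, and in
#' that case the partner-partner entries are raised to the smallest value
#' that restores positive semidefiniteness (at most `r^2`, the correlation
#' implied by partners sharing the hub's latent component). If the result
#' is still not PSD it is repaired by clipping negative eigenvalues to
#' zero and renormalising the diagonal; repairs that move any entry by
#' more than `max_repair` abort, since a large repair would silently
#' change the simulation's truth.
#'
#' @param n_regions Number of regions (>= 2).
#' @param base_r Baseline pairwise correlation, in (-1, 1).
#' @param hub Optional `list(region =, partners =, r =)`: 1-based index (or
#'   name resolved by the caller) of the hub region, indices of its
#'   partners, and the hub-partner correlation in (-1, 1).
#' @param max_repair Maximum tolerated absolute entry change during PSD
#'   repair (default 0.05).
#' @return Correlation matrix with unit diagonal; attribute `"psd_repair"`
#'   holds the maximum absolute entry change incurred by the repair (0 when
#'   none was needed).
#' @examples
#' latent_correlation(3, base_r = 0)                      # identity
#' latent_correlation(5, base_r = 0.2,
#'                    hub = list(region = 1, partners = 2:4, r = 0.8))
#' @export
latent_correlation <- function(n_regions, base_r = 0, hub = NULL,
                               max_repair = 0.05) {
  if (n_regions < 2) stop("need at least 2 regions")
  if (abs(base_r) >= 1) stop("'base_r' must lie in (-1, 1)")
  C <- matrix(base_r, n_regions, n_regions)
  diag(C) <- 1
  if (!is.null(hub)) {
    h <- hub$region
    p <- hub$partners
    r <- hub$r
    if (is.null(h) || is.null(p) || is.null(r))
      stop("'hub' must be a list with elements region, partners, r")
    if (abs(r) >= 1) stop("hub correlation must lie in (-1, 1)")
    idx <- c(h, p)
    if (any(idx < 1 | idx > n_regions))
      stop("hub or partner index out of range [1, ", n_regions, "]")
    if (h %in% p) stop("hub region cannot be its own partner")
    C[h, p] <- r
    C[p, h] <- r
    if (length(p) > 1) C <- raise_partner_corr(C, p, base_r, r)
  }
  psd_repair(C, max_repair = max_repair)
}

# Raise the partner-partner correlations to the smallest value (between
# base_r and r^2, found by bisection) that makes the hub star positive
# semidefinite with a small spectral margin. r^2 -- partners loading fully
# on the hub's latent component -- is always sufficient when the baseline
# matrix is PSD.
raise_partner_corr <- function(C, p, base_r, r, margin = 1e-3) {
  set_pp <- function(pp) {
    for (i in p) for (j in p) if (i != j) C[i, j] <- pp
    C
  }
  min_eig <- function(pp) min(eigen(set_pp(pp), symmetric = TRUE,
                                    only.values = TRUE)$values)
  if (min_eig(base_r) >= margin) return(C)
  lo <- base_r
  hi <- max(r^2, base_r)
  if (min_eig(hi) < 0) return(C)   # leave to psd_repair to decide
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    if (min_eig(mid) >= margin) hi <- mid else lo <- mid
  }
  set_pp(hi)
}

# Clip negative eigenvalues to zero and renormalise to unit diagonal.
# Attaches the max absolute entry change as attribute "psd_repair".
psd_repair <- function(C, max_repair = 0.05, tol = 1e-10) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) >= -tol) {
    attr(C, "psd_repair") <- 0
    return(C)
  }
  lam <- pmax(e$values, 0)
  R <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(diag(R))
  R <- R / tcrossprod(d)
  diag(R) <- 1
  R <- (R + t(R)) / 2
  delta <- max(abs(R - C))
  if (delta > max_repair)
    stop(sprintf(
      "PSD repair changed an entry by %.3f (> %.3f); latent correlation %s",
      delta, max_repair, "specification is too far from feasible"))
  dimnames(R) <- dimnames(C)
  attr(R, "psd_repair") <- delta
  R
}

#' Preset 2x2 cell means for the five activation patterns
#'
#' Named presets of expected c-Fos-positive cell counts per
#' treatment-by-phase cell, one per activation pattern:
#' \describe{
#'   \item{1 (treatment only)}{MA elevated over SAL, no phase difference.}
#'   \item{2 (time only)}{light elevated over dark, no treatment difference.}
#'   \item{3 (treatment + interaction)}{MA effect concentrated in the light
#'     phase.}
#'   \item{4 (treatment + time, additive)}{both main effects, no
#'     interaction.}
#'   \item{5 (null)}{flat across all four cells.}
#' }
#' Magnitudes (tens of labelled cells per counting frame) are typical of
#' immediate-early-gene immunohistochemistry.
#'
#' @param pattern Pattern id: 1-5 (integer or character).
#' @return Named numeric vector with elements `MA.light`, `MA.dark`,
#'   `SAL.light`, `SAL.dark`.
#' @export
pattern_cell_means <- function(pattern) {
  presets <- list(
    `1` = c(MA.light = 75, MA.dark = 75, SAL.light = 30, SAL.dark = 30),
    `2` = c(MA.light = 80, MA.dark = 25, SAL.light = 80, SAL.dark = 25),
    `3` = c(MA.light = 90, MA.dark = 40, SAL.light = 32, SAL.dark = 38),
    `4` = c(MA.light = 80, MA.dark = 55, SAL.light = 45, SAL.dark = 25),
    `5` = c(MA.light = 35, MA.dark = 35, SAL.light = 35, SAL.dark = 35)
  )
  key <- as.character(pattern)
  if (!key %in% names(presets)) stop("unknown pattern preset: ", pattern)
  presets[[key]]
}

#' Region-to-pattern assignment of the default study design
#'
#' Maps each of the 17 default regions to the activation pattern it
#' exhibits in the emulated study (e.g. SCN shows a time effect only,
#' PVN a treatment effect with interaction, MEA no effects).
#'
#' @return Named integer vector (names are regions, values pattern ids).
#' @export
default_pattern_map <- function() {
  c(ILC = 1, CEA = 1, BNST = 1, CA1 = 1, CIN = 1, NACc = 1,
    SCN = 2, VMH = 2, DMH = 2,
    PVN = 3, PVT = 3, ARC = 3,
    CA3 = 4, NACs = 4,
    MEA = 5, BLA = 5, DG = 5)
}

#' Configure the synthetic c-Fos count generator
#'
#' Assembles and validates a generator configuration. Counts are produced
#' by a latent Gaussian copula: each animal draws a latent multivariate
#' normal vector under its treatment group's latent correlation matrix,
#' each coordinate is transformed to a lognormal count scale with mean
#' equal to that animal's treatment-by-phase cell mean and coefficient of
#' variation `dispersion`, then rounded to a whole cell count.
#'
#' @param regions Character vector of region names.
#' @param n_per_cell Animals per treatment-by-phase cell (>= 2); the
#'   default 10 matches the emulated study design (40 animals total).
#' @param cell_means Numeric matrix, regions x 4, columns `MA.light`,
#'   `MA.dark`, `SAL.light`, `SAL.dark`; all entries >= 0. Default: the
#'   pattern presets under [default_pattern_map()] when the regions are the
#'   default panel, otherwise required.
#' @param dispersion Coefficient of variation of counts on the latent
#'   scale (>= 0). Default 0.3, a typical spread for per-animal
#'   immediate-early-gene cell counts.
#' @param base_r Baseline latent inter-regional correlation used when
#'   `latent_corr` is not supplied. Default 0.3 in both groups.
#' @param hub Optional hub enhancement applied to the treated (MA) group's
#'   latent matrix: `list(region =, partners =, r =)` with region names or
#'   indices. Mimics a treatment-specific increase in one region's
#'   coupling.
#' @param latent_corr Optional explicit latent correlation: a single matrix
#'   (both groups) or `list(MA =, SAL =)`.
#' @param seed Master RNG seed (integer). Substreams for each group and
#'   each animal are derived from it deterministically.
#' @return Object of class `cfos_sim_config`.
#' @seealso [simulate_cfos()]
#' @export
cfos_sim_config <- function(regions = cfos_regions(),
                            n_per_cell = 10,
                            cell_means = NULL,
                            dispersion = 0.3,
                            base_r = 0.3,
                            hub = NULL,
                            latent_corr = NULL,
                            seed = 1L) {
  regions <- as.character(regions)
  R <- length(regions)
  if (R < 2) stop("need at least 2 regions")
  if (anyDuplicated(regions)) stop("region names must be unique")
  if (n_per_cell < 2) stop("'n_per_cell' must be >= 2")
  if (dispersion < 0) stop("'dispersion' must be >= 0")

  cells <- c("MA.light", "MA.dark", "SAL.light", "SAL.dark")
  if (is.null(cell_means)) {
    pm <- default_pattern_map()
    if (!all(regions %in% names(pm)))
      stop("'cell_means' is required for non-default region panels")
    cell_means <- t(vapply(regions, function(r) pattern_cell_means(pm[[r]]),
                           numeric(4)))
  }
  cell_means <- as.matrix(cell_means)
  if (!all(cells %in% colnames(cell_means)))
    stop("'cell_means' needs columns ", paste(cells, collapse = ", "))
  cell_means <- cell_means[, cells, drop = FALSE]
  if (nrow(cell_means) != R)
    stop("'cell_means' must have one row per region")
  rownames(cell_means) <- regions
  if (any(cell_means < 0) || any(!is.finite(cell_means)))
    stop("all cell means must be finite and >= 0")

  hub_idx <- NULL
  if (!is.null(hub)) {
    hub_idx <- list(
      region = resolve_region(hub$region, regions),
      partners = vapply(hub$partners, resolve_region, integer(1),
                        regions = regions),
      r = hub$r
    )
  }

  if (is.null(latent_corr)) {
    latent_corr <- list(
      MA = latent_correlation(R, base_r = base_r, hub = hub_idx),
      SAL = latent_correlation(R, base_r = base_r)
    )
  } else {
    if (is.matrix(latent_corr))
      latent_corr <- list(MA = latent_corr, SAL = latent_corr)
    if (!all(c("MA", "SAL") %in% names(latent_corr)))
      stop("'latent_corr' must be a matrix or list(MA =, SAL =)")
    latent_corr <- lapply(latent_corr[c("MA", "SAL")], function(C) {
      C <- as.matrix(C)
      if (nrow(C) != R || ncol(C) != R)
        stop("latent correlation must be ", R, " x ", R)
      if (max(abs(C - t(C))) > 1e-8) stop("latent correlation not symmetric")
      if (max(abs(diag(C) - 1)) > 1e-8) stop("latent diagonal must be 1")
      if (any(abs(C) > 1 + 1e-8)) stop("correlations must lie in [-1, 1]")
      psd_repair((C + t(C)) / 2)
    })
  }
  latent_corr <- lapply(latent_corr, function(C) {
    dimnames(C) <- list(regions, regions)
    C
  })

  structure(
    list(regions = regions, n_per_cell = as.integer(n_per_cell),
         cell_means = cell_means, dispersion = dispersion,
         latent_corr = latent_corr, hub = hub_idx,
         seed = as.integer(seed)),
    class = "cfos_sim_config"
  )
}

resolve_region <- function(x, regions) {
  if (is.character(x)) {
    i <- match(x, regions)
    if (is.na(i)) stop("unknown region: ", x)
    return(i)
  }
  i <- as.integer(x)
  if (is.na(i) || i < 1 || i > length(regions))
    stop("region index out of range: ", x)
  i
}

#' @export
print.cfos_sim_config <- function(x, ...) {
  cat("Synthetic c-Fos generator configuration\n")
  cat(sprintf("  %d regions, %d animals/cell (%d total)\n",
              length(x$regions), x$n_per_cell, 4L * x$n_per_cell))
  cat(sprintf("  dispersion (CV): %.3g; seed: %d\n", x$dispersion, x$seed))
  if (!is.null(x$hub))
    cat(sprintf("  hub: %s -> {%s} at r = %.2f (MA group)\n",
                x$regions[x$hub$region],
                paste(x$regions[x$hub$partners], collapse = ", "),
                x$hub$r))
  invisible(x)
}

#' Pearson correlation implied by a latent Gaussian correlation after the
#' lognormal transform
#'
#' The copula attenuates correlations: with lognormal margins of
#' coefficients of variation `cv1`, `cv2` and latent (Gaussian-scale)
#' correlation `rho`, the count-scale Pearson correlation is
#' `(exp(rho * s1 * s2) - 1) / sqrt((exp(s1^2) - 1) * (exp(s2^2) - 1))`
#' with `s_i^2 = log(1 + cv_i^2)`. Rounding to whole counts perturbs this
#' only slightly at realistic means.
#'
#' @param rho Latent correlation.
#' @param cv1,cv2 Coefficients of variation of the two margins.
#' @return Attenuated Pearson correlation (equal to `rho` when either CV
#'   is 0, by continuity).
#' @export
attenuated_correlation <- function(rho, cv1, cv2 = cv1) {
  s1 <- sqrt(log(1 + cv1^2))
  s2 <- sqrt(log(1 + cv2^2))
  if (s1 == 0 || s2 == 0) return(rho)
  (exp(rho * s1 * s2) - 1) / sqrt(expm1(s1^2) * expm1(s2^2))
}

#' Simulate a factorial c-Fos count table
#'
#' Draws a per-animal activation table under a [cfos_sim_config()]:
#' `4 * n_per_cell` animals (2 treatments x 2 phases), one nonnegative
#' count per region, generated by the latent Gaussian copula described in
#' the config's documentation. Identical configs (including seed) yield
#' identical tables; each animal has its own derived RNG substream, so
#' individual rows are reproducible independently of table size.
#'
#' @param config A `cfos_sim_config` object.
#' @return A `cfos_table`: data.frame with columns `animal_id`,
#'   `treatment` (MA/SAL), `phase` (light/dark) and one numeric column per
#'   region.
#' @examples
#' tab <- simulate_cfos(cfos_sim_config(n_per_cell = 5, seed = 42))
#' dim(tab)  # 20 animals x (3 + 17) columns
#' @export
simulate_cfos <- function(config) {
  stopifnot(inherits(config, "cfos_sim_config"))
  regions <- config$regions
  R <- length(regions)
  n <- config$n_per_cell
  cv <- config$dispersion
  s2 <- log(1 + cv^2)

  # per-group transform: z = V sqrt(lambda) e maps iid N(0,1) to N(0, C)
  transforms <- lapply(config$latent_corr, function(C) {
    e <- eigen(C, symmetric = TRUE)
    e$vectors %*% diag(sqrt(pmax(e$values, 0)), R)
  })

  groups <- expand.grid(phase = c("light", "dark"),
                        treatment = c("MA", "SAL"),
                        stringsAsFactors = FALSE)[, c("treatment", "phase")]
  N <- nrow(groups) * n
  counts <- matrix(0, N, R, dimnames = list(NULL, regions))
  ids <- character(N)
  trt_col <- character(N)
  ph_col <- character(N)
  k <- 0L
  for (g in seq_len(nrow(groups))) {
    trt <- groups$treatment[g]
    ph <- groups$phase[g]
    gi <- match(trt, c("MA", "SAL"))        # substream index by group
    L <- transforms[[trt]]
    m <- config$cell_means[, paste(trt, ph, sep = ".")]
    mu <- ifelse(m > 0, log(m) - s2 / 2, -Inf)
    for (a in seq_len(n)) {
      k <- k + 1L
      # animal index within treatment group spans both phases
      ai <- (match(ph, c("light", "dark")) - 1L) * n + a
      set.seed(derive_seed(config$seed, gi, ai))
      z <- as.vector(L %*% rnorm(R))
      x <- if (cv > 0) exp(mu + sqrt(s2) * z) else m
      x[m == 0] <- 0
      counts[k, ] <- round(x)
      ids[k] <- sprintf("%s_%s_%02d", trt, ph, a)
      trt_col[k] <- trt
      ph_col[k] <- ph
    }
  }
  out <- data.frame(animal_id = ids, treatment = trt_col, phase = ph_col,
                    counts, stringsAsFactors = FALSE, check.names = FALSE)
  as_cfos_table(out, seed = config$seed)
}

as_cfos_table <- function(df, seed = NULL) {
  df$treatment <- factor(df$treatment, levels = c("MA", "SAL"))
  df$phase <- factor(df$phase, levels = c("light", "dark"))
  class(df) <- c("cfos_table", "data.frame")
  attr(df, "seed") <- seed
  df
}

#' Region columns of a sample table
#' @param table A `cfos_table` or compatible data.frame.
#' @return Character vector of region column names.
#' @export
region_names <- function(table) {
  setdiff(names(table), c("animal_id", "treatment", "phase"))
}

#' @export
print.cfos_table <- function(x, ...) {
  cat(sprintf("c-Fos sample table: %d animals x %d regions\n",
              nrow(x), length(region_names(x))))
  tb <- table(x$treatment, x$phase)
  print(tb)
  invisible(x)
}
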