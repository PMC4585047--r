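#' Run the full activation-pattern and connectivity pipeline
#'
#' Chains the three analysis stages on one sample table: (1) per-region
#' two-way ANOVA with pattern classification and simple-effect post hocs;
#' (2) per-group correlation networks, connectivity and permutation
#' Z-scores; (3) bootstrap comparison of per-region connectivity between
#' treatments. With `collapse_phases = TRUE` (the default, matching the
#' motivating analysis, which pools light and dark animals within
#' treatment for power) the networks are built per treatment group;
#' otherwise per treatment-by-phase cell (4 networks) with the bootstrap
#' comparison run within each phase. `center_phases` subtracts within-phase
#' region means before correlating, removing correlation inflation driven
#' by shared phase effects (off by default, matching the motivating
#' analysis).
#'
#' @param table A `cfos_table`, or a path to a CSV readable by
#'   [read_cfos_table()].
#' @param alpha Significance level for pattern classification.
#' @param method Correlation coefficient (pearson/spearman).
#' @param n_perm Permutation replicates for connectivity Z-scores.
#' @param n_boot Bootstrap re-splits for the group comparison.
#' @param seed Master seed; stage substreams are derived from it.
#' @param collapse_phases Pool light/dark within treatment before building
#'   networks (default TRUE).
#' @param center_phases Mean-center each region within phase before
#'   correlating (default FALSE).
#' @param edge_threshold Minimum |r| for edge-list/GraphML display output
#'   (does not affect connectivity).
#' @param out_dir Optional output directory; when given, all results are
#'   written as TSV/JSON plus a machine-readable `manifest.json` recording
#'   inputs, parameters and seeds.
#' @param unsafe Allow `n_perm`/`n_boot` below 100 (testing only).
#' @return Invisibly, a list with `patterns` (a `cfos_patterns`),
#'   `networks` (per group: correlation matrix, connectivity, permutation
#'   result, edges), `comparison` (a `cfos_netdiff`, or one per phase when
#'   phases are not collapsed) and `manifest`.
#' @examples
#' tab <- simulate_cfos(cfos_sim_config(seed = 2))
#' res <- run_pipeline(tab, n_perm = 200, n_boot = 200, seed = 2)
#' res$patterns
#' @export
run_pipeline <- function(table, alpha = 0.05,
                         method = c("pearson", "spearman"),
                         n_perm = 10000, n_boot = 10000, seed = 1L,
                         collapse_phases = TRUE, center_phases = FALSE,
                         edge_threshold = 0, out_dir = NULL,
                         unsafe = FALSE) {
  method <- match.arg(method)
  if (!unsafe && (n_perm < 100 || n_boot < 100))
    stop("'n_perm' and 'n_boot' must be >= 100 for analysis runs")
  input <- if (is.character(table)) table else "<in-memory table>"
  if (is.character(table)) table <- read_cfos_table(table)
  stopifnot(inherits(table, "cfos_table"))

  patterns <- activation_patterns(table, alpha = alpha)

  groups <- if (collapse_phases) {
    split(seq_len(nrow(table)), table$treatment)
  } else {
    split(seq_len(nrow(table)),
          list(table$treatment, table$phase), sep = ".")
  }
  networks <- list()
  gi <- 0L
  for (gname in names(groups)) {
    gi <- gi + 1L
    sub <- table[groups[[gname]], , drop = FALSE]
    m <- region_matrix(sub)
    if (center_phases) m <- center_within_phase(m, sub$phase)
    corr <- correlation_matrix(m, method = method)
    perm <- permutation_null(m, n_perm = n_perm, method = method,
                             seed = derive_seed(seed, 10L + gi),
                             unsafe = unsafe)
    networks[[gname]] <- list(
      correlation = corr,
      connectivity = connectivity_profile(corr),
      permutation = perm,
      edges = edge_list(corr, min_abs_r = edge_threshold)
    )
  }

  if (collapse_phases) {
    mt <- region_matrix(table)
    if (center_phases) {
      mt <- do.call(rbind, lapply(levels(table$treatment), function(tr) {
        i <- table$treatment == tr
        center_within_phase(mt[i, , drop = FALSE], table$phase[i])
      }))
      comparison_table <- table[order(table$treatment), , drop = FALSE]
      comparison_table[, region_names(table)] <- mt
    } else comparison_table <- table
    comparison <- bootstrap_compare(comparison_table, n_boot = n_boot,
                                    seed = derive_seed(seed, 20L),
                                    method = method, unsafe = unsafe)
  } else {
    comparison <- lapply(levels(table$phase), function(ph) {
      sub <- table[table$phase == ph, , drop = FALSE]
      bootstrap_compare(sub, n_boot = n_boot,
                        seed = derive_seed(seed, 20L,
                                           match(ph, levels(table$phase))),
                        method = method, unsafe = unsafe)
    })
    names(comparison) <- levels(table$phase)
  }

  manifest <- list(
    package = "cofosnet",
    version = as.character(packageVersion("cofosnet")),
    input = input,
    n_animals = nrow(table),
    regions = region_names(table),
    parameters = list(alpha = alpha, method = method, n_perm = n_perm,
                      n_boot = n_boot, seed = seed,
                      collapse_phases = collapse_phases,
                      center_phases = center_phases,
                      edge_threshold = edge_threshold)
  )

  res <- list(patterns = patterns, networks = networks,
              comparison = comparison, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  invisible(res)
}

center_within_phase <- function(m, phase) {
  for (ph in unique(phase)) {
    i <- phase == ph
    m[i, ] <- scale(m[i, , drop = FALSE], center = TRUE, scale = FALSE)
  }
  m
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_tsv(as.data.frame(res$patterns), p("activation_patterns.tsv"))
  jsonlite::write_json(res$patterns, p("activation_patterns.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  for (g in names(res$networks)) {
    nw <- res$networks[[g]]
    cm <- as.data.frame(unclass(nw$correlation))
    cm <- cbind(region = rownames(unclass(nw$correlation)), cm)
    write_tsv(cm, p(sprintf("correlation_%s.tsv", g)))
    conn <- data.frame(region = names(nw$connectivity),
                       connectivity = as.numeric(nw$connectivity))
    conn <- merge(conn, as.data.frame(nw$permutation), by = "region",
                  sort = FALSE)
    write_tsv(conn, p(sprintf("connectivity_%s.tsv", g)))
    jsonlite::write_json(conn, p(sprintf("connectivity_%s.json", g)),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    write_tsv(nw$edges, p(sprintf("edges_%s.tsv", g)))
    write_network_graphml(nw$correlation, p(sprintf("network_%s.graphml", g)),
                          min_abs_r = res$manifest$parameters$edge_threshold)
  }
  comps <- if (inherits(res$comparison, "cfos_netdiff"))
    list(all = res$comparison) else res$comparison
  for (nm in names(comps)) {
    suffix <- if (nm == "all") "" else paste0("_", nm)
    write_tsv(as.data.frame(comps[[nm]]),
              p(sprintf("network_difference%s.tsv", suffix)))
    jsonlite::write_json(
      c(list(n_boot = attr(comps[[nm]], "n_boot"),
             seed = attr(comps[[nm]], "seed"),
             groups = attr(comps[[nm]], "groups")),
        list(results = as.data.frame(comps[[nm]]))),
      p(sprintf("network_difference%s.json", suffix)),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}
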