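#' Inter-regional correlation matrix for one group
#'
#' Correlates per-animal activation across regions within one experimental
#' group, using pairwise-complete observations. Across-animal correlation
#' of regional activation is the coupling measure from which functional
#' connectivity is derived.
#'
#' @param x A one-group `cfos_table` (region columns are used) or a numeric
#'   animals-by-regions matrix.
#' @param method Correlation coefficient: `"pearson"` (default) or
#'   `"spearman"` (rank-based, robust to outlying counts).
#' @return Object of class `cfos_corr`: the region-by-region correlation
#'   matrix with attributes `method` and `npairs` (per-entry complete-pair
#'   counts).
#' @examples
#' tab <- simulate_cfos(cfos_sim_config(seed = 1))
#' cm <- correlation_matrix(tab[tab$treatment == "MA", ])
#' @export
correlation_matrix <- function(x, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- region_matrix(x)
  npairs <- crossprod(!is.na(m))
  off <- npairs[upper.tri(npairs)]
  if (any(off < 3)) {
    bad <- which(npairs < 3 & upper.tri(npairs), arr.ind = TRUE)[1, ]
    stop(sprintf("only %d complete pairs for regions %s and %s; need >= 3",
                 npairs[bad[1], bad[2]],
                 colnames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  C <- cor(m, use = "pairwise.complete.obs", method = method)
  structure(C, method = method, npairs = npairs,
            n = nrow(m), class = c("cfos_corr", class(C)))
}

# numeric animals x regions matrix from a table or matrix input
region_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(colnames(x)))
      colnames(x) <- paste0("R", seq_len(ncol(x)))
    return(x)
  }
  regions <- region_names(x)
  if (length(regions) < 2) stop("need at least 2 region columns")
  as.matrix(x[, regions, drop = FALSE])
}

#' @export
print.cfos_corr <- function(x, ...) {
  cat(sprintf("%s correlation matrix, %d regions, %d samples\n",
              attr(x, "method"), ncol(x), attr(x, "n")))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Per-region connectivity
#'
#' Connectivity of region r is the sum of absolute correlations with all
#' other regions, `k_r = sum_{s != r} |corr(r, s)|` — a weighted node
#' strength on the full (unthresholded) correlation network. It is bounded
#' by 0 and the number of other regions.
#'
#' @param corr A `cfos_corr` or any symmetric correlation matrix.
#' @return Named numeric vector of connectivity values, one per region.
#' @examples
#' connectivity_profile(diag(3))  # independent regions: all zero
#' @export
connectivity_profile <- function(corr) {
  C <- unclass(corr)
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  k <- rowSums(abs(C)) - abs(diag(C))
  names(k) <- rownames(C) %||% paste0("R", seq_len(nrow(C)))
  k
}

#' Permutation null for connectivity
#'
#' Calibrates observed connectivity against chance: each permutation
#' replicate shuffles every region column's sample order independently,
#' destroying cross-region alignment while preserving each region's
#' marginal distribution, and recomputes connectivity. (A joint shuffle of
#' whole animals would leave all correlations unchanged, hence the
#' column-wise scheme.) The per-region Z-score is
#' `(observed - null mean) / null sd` with the sample (n-1) standard
#' deviation; Z > 2 is the conventional criterion for connectivity
#' unlikely to arise by chance.
#'
#' @inheritParams correlation_matrix
#' @param n_perm Number of permutation replicates (>= 100; the motivating
#'   analysis used 10,000).
#' @param seed RNG seed; each replicate uses a substream derived from it.
#' @param unsafe Allow `n_perm` below 100 (testing only).
#' @return Object of class `cfos_permnull`: data.frame with columns
#'   `region`, `observed`, `null_mean`, `null_sd`, `z`; attributes
#'   `n_perm`, `seed`, `method`.
#' @examples
#' tab <- simulate_cfos(cfos_sim_config(seed = 1))
#' permutation_null(tab[tab$treatment == "MA", ], n_perm = 200, seed = 9)
#' @export
permutation_null <- function(x, n_perm = 10000,
                             method = c("pearson", "spearman"), seed = 1L,
                             unsafe = FALSE) {
  method <- match.arg(method)
  if (n_perm < 100 && !unsafe) stop("'n_perm' must be >= 100")
  if (n_perm < 2) stop("'n_perm' must be >= 2")
  m <- region_matrix(x)
  sds <- apply(m, 2, sd, na.rm = TRUE)
  if (any(sds == 0 | is.na(sds)))
    stop("zero variance in region '",
         colnames(m)[which(sds == 0 | is.na(sds))[1]], "'")
  observed <- connectivity_profile(correlation_matrix(m, method = method))
  n <- nrow(m)
  R <- ncol(m)
  ks <- matrix(0, n_perm, R)
  sm <- m
  for (b in seq_len(n_perm)) {
    set.seed(derive_seed(seed, 3L, b))
    for (j in seq_len(R)) sm[, j] <- m[sample.int(n), j]
    ks[b, ] <- rowSums(abs(cor(sm, use = "pairwise.complete.obs",
                               method = method))) - 1
  }
  mu <- colMeans(ks)
  s <- apply(ks, 2, sd)
  out <- data.frame(region = colnames(m), observed = observed,
                    null_mean = mu, null_sd = s,
                    z = (observed - mu) / s, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "method") <- method
  class(out) <- c("cfos_permnull", "data.frame")
  out
}

#' @export
print.cfos_permnull <- function(x, ...) {
  cat(sprintf("Connectivity permutation null (%d replicates, %s, seed %d)\n",
              attr(x, "n_perm"), attr(x, "method"), attr(x, "seed")))
  tab <- x
  tab[2:5] <- lapply(tab[2:5], round, 3)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' Extract the edge list of a correlation network
#'
#' Lists region pairs whose absolute correlation reaches a display
#' threshold, each carrying the signed coefficient. The threshold affects
#' display only: [connectivity_profile()] always sums all off-diagonal
#' correlations.
#'
#' @param corr A `cfos_corr` or correlation matrix.
#' @param min_abs_r Threshold on |r| in \[0, 1\] (default 0: complete
#'   graph).
#' @return data.frame with columns `region_a`, `region_b`, `r`.
#' @export
edge_list <- function(corr, min_abs_r = 0) {
  if (min_abs_r < 0 || min_abs_r > 1)
    stop("'min_abs_r' must lie in [0, 1]")
  C <- unclass(corr)
  nm <- rownames(C) %||% paste0("R", seq_len(nrow(C)))
  idx <- which(upper.tri(C) & abs(C) >= min_abs_r, arr.ind = TRUE)
  out <- data.frame(region_a = nm[idx[, 1]], region_b = nm[idx[, 2]],
                    r = C[idx], stringsAsFactors = FALSE)
  out[order(out$region_a, out$region_b), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Export a thresholded correlation network as GraphML
#'
#' Writes the [edge_list()] of a correlation matrix as an undirected
#' weighted graph; edge attributes `weight` (|r|) and `sign` encode
#' strength and direction.
#'
#' @inheritParams edge_list
#' @param path Output file path.
#' @return Invisibly, the igraph object written.
#' @export
write_network_graphml <- function(corr, path, min_abs_r = 0) {
  el <- edge_list(corr, min_abs_r = min_abs_r)
  nm <- rownames(unclass(corr)) %||% paste0("R", seq_len(nrow(corr)))
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = data.frame(name = nm))
  igraph::E(g)$weight <- abs(el$r)
  igraph::E(g)$sign <- sign(el$r)
  igraph::E(g)$r <- el$r
  igraph::write_graph(g, path, format = "graphml")
  invisible(g)
}
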