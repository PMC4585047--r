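# Independent oracles used across tests. These deliberately avoid the code
# paths they validate: the ANOVA oracle is the classical balanced two-way
# decomposition computed from cell means; the correlation oracle is the
# textbook product-moment formula evaluated with explicit loops.

# Classical balanced 2x2 decomposition. d: data.frame(y, treatment, phase),
# equal n per cell.
oracle_balanced_anova <- function(d) {
  cells <- split(d$y, list(d$treatment, d$phase))
  n <- unique(vapply(cells, length, integer(1)))
  stopifnot(length(n) == 1)
  m <- tapply(d$y, list(d$treatment, d$phase), mean)
  grand <- mean(d$y)
  ma <- rowMeans(m)   # treatment margins
  mb <- colMeans(m)   # phase margins
  ss_a <- 2 * n * sum((ma - grand)^2)
  ss_b <- 2 * n * sum((mb - grand)^2)
  inter <- sweep(sweep(m, 1, ma), 2, mb) + grand
  ss_ab <- n * sum(inter^2)
  fitted <- m[cbind(as.integer(d$treatment), as.integer(d$phase))]
  ss_e <- sum((d$y - fitted)^2)
  df_e <- length(d$y) - 4
  list(F_treatment = ss_a / (ss_e / df_e),
       F_time = ss_b / (ss_e / df_e),
       F_interaction = ss_ab / (ss_e / df_e),
       df_residual = df_e)
}

# Product-moment correlation by direct summation.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

oracle_corr_matrix <- function(m) {
  R <- ncol(m)
  C <- diag(R)
  for (i in seq_len(R - 1)) for (j in (i + 1):R) {
    C[i, j] <- C[j, i] <- oracle_pearson(m[, i], m[, j])
  }
  dimnames(C) <- list(colnames(m), colnames(m))
  C
}

# Balanced factorial table with iid noise and per-region cell means.
# means: list per region of c(MA.light, MA.dark, SAL.light, SAL.dark).
make_balanced_table <- function(n_per_cell, means, sd = 1, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(phase = c("light", "dark"),
                      treatment = c("MA", "SAL"),
                      stringsAsFactors = FALSE)
  rows <- grid[rep(seq_len(4), each = n_per_cell), ]
  cellkey <- paste(rows$treatment, rows$phase, sep = ".")
  out <- data.frame(
    animal_id = sprintf("a%02d", seq_len(nrow(rows))),
    treatment = rows$treatment, phase = rows$phase,
    stringsAsFactors = FALSE)
  for (r in names(means)) {
    mu <- means[[r]][c("MA.light", "MA.dark", "SAL.light", "SAL.dark")]
    out[[r]] <- mu[match(cellkey,
                         c("MA.light", "MA.dark", "SAL.light",
                           "SAL.dark"))] + rnorm(nrow(rows), sd = sd)
    out[[r]] <- pmax(out[[r]], 0)
  }
  cofosnet:::as_cfos_table(out)
}

flat_means <- function(regions, value = 35) {
  m <- matrix(value, length(regions), 4,
              dimnames = list(regions,
                              c("MA.light", "MA.dark", "SAL.light",
                                "SAL.dark")))
  m
}

# All permutations of 1..n (n small), as a list.
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}
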