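#' Read a per-animal activation table from CSV
#'
#' Expects a comma-separated, UTF-8, header-first file with columns
#' `animal_id`, `treatment`, `phase`, then one numeric column per region.
#' Factor levels are normalised case-insensitively to MA/SAL and
#' light/dark; anything else is rejected with the offending row named.
#'
#' @param path CSV file path.
#' @return A validated `cfos_table`.
#' @seealso [write_cfos_table()]
#' @export
read_cfos_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_cfos_table(df, context = path)
}

validate_cfos_table <- function(df, context = "table") {
  required <- c("animal_id", "treatment", "phase")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(context, ": missing required column(s): ",
         paste(missing, collapse = ", "))
  if (ncol(df) < 5)
    stop(context, ": need at least 2 region columns")
  dup <- df$animal_id[duplicated(df$animal_id)]
  if (length(dup))
    stop(context, ": duplicate animal_id: ", paste(unique(dup),
                                                   collapse = ", "))

  df$treatment <- normalize_level(df$treatment, c(ma = "MA", sal = "SAL"),
                                  "treatment", context)
  df$phase <- normalize_level(df$phase, c(light = "light", dark = "dark"),
                              "phase", context)

  for (r in setdiff(names(df), required)) {
    v <- df[[r]]
    if (is.character(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad))
        stop(context, ": non-numeric value '", v[bad[1]], "' in column '",
             r, "', row ", bad[1])
      v <- vn
    }
    if (!is.numeric(v))
      stop(context, ": column '", r, "' is not numeric")
    neg <- which(v < 0)
    if (length(neg))
      stop(context, ": negative count ", v[neg[1]], " in column '", r,
           "', row ", neg[1])
    if (all(is.na(v)))
      stop(context, ": region '", r, "' has no observed values")
    df[[r]] <- v
  }
  as_cfos_table(df)
}

normalize_level <- function(x, map, what, context) {
  key <- tolower(trimws(as.character(x)))
  out <- unname(map[key])
  bad <- which(is.na(out))
  if (length(bad))
    stop(context, ": unknown ", what, " level '", x[bad[1]], "' in row ",
         bad[1], " (expected ", paste(map, collapse = "/"), ")")
  out
}

#' Write a sample table to CSV
#'
#' Writes the dialect read back by [read_cfos_table()]; a write/read
#' roundtrip reproduces the table.
#'
#' @param table A `cfos_table`.
#' @param path Destination file path.
#' @return Invisibly, `path`.
#' @export
write_cfos_table <- function(table, path) {
  if (nrow(table) == 0) stop("refusing to write an empty table")
  df <- as.data.frame(table)
  df$treatment <- as.character(df$treatment)
  df$phase <- as.character(df$phase)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
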