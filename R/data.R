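#' Build a longitudinal dataset from a long-format data frame
#'
#' Validates and groups a long table (one row per subject-visit) into the
#' per-subject form the QIF sums over. Required columns: `subject`,
#' `visit`, `y` (binary 0/1), covariates `x1..xp`, and `G` (genotype coded
#' 0/1/2, constant within subject). Rows are ordered by `visit` within
#' subject; file order is immaterial.
#'
#' @param df long-format data frame.
#' @return Object of class `gfvicm_data`: list with `y` (list of binary
#'   vectors), `X` (list of `n_i x p` matrices), `G` (integer vector),
#'   `ni`, `p`, `N`, plus the flattened `long` table.
#' @export
as_gfvicm_data <- function(df) {
  need <- c("subject", "visit", "y", "G")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  xcols <- grep("^x[0-9]+$", names(df), value = TRUE)
  xcols <- xcols[order(as.integer(sub("^x", "", xcols)))]
  if (!length(xcols)) stop("no covariate columns x1..xp found")
  bad <- which(!(df$y %in% c(0, 1)))
  if (length(bad)) stop("non-binary response y at row(s): ",
                        paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!(df$G %in% c(0, 1, 2)))
  if (length(bad)) stop("genotype G must be coded 0/1/2; offending row(s): ",
                        paste(utils::head(bad, 5), collapse = ", "))
  df <- df[order(df$subject, df$visit), , drop = FALSE]
  idx <- split(seq_len(nrow(df)), df$subject)
  G <- vapply(idx, function(i) {
    g <- unique(df$G[i])
    if (length(g) != 1) stop("genotype varies within subject ", df$subject[i[1]])
    as.integer(g)
  }, integer(1))
  Xall <- as.matrix(df[, xcols, drop = FALSE])
  storage.mode(Xall) <- "double"
  structure(list(
    y = lapply(idx, function(i) as.integer(df$y[i])),
    X = lapply(idx, function(i) Xall[i, , drop = FALSE]),
    G = G,
    ni = vapply(idx, length, integer(1)),
    p = length(xcols), N = length(idx), long = df), class = "gfvicm_data")
}

#' Read a long-format gFVICM CSV
#'
#' @param path CSV path with header `subject,visit,y,x1..xp,G`.
#' @return A `gfvicm_data` object (see [as_gfvicm_data()]).
#' @export
read_gfvicm_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_gfvicm_data(df)
}

#' Write a gFVICM dataset to CSV
#'
#' @param data a `gfvicm_data` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gfvicm_csv <- function(data, path) {
  utils::write.csv(data$long, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.gfvicm_data <- function(x, ...) {
  cat(sprintf(
    "gFVICM longitudinal data: %d subjects, %d observations, %d covariate(s)\n",
    x$N, sum(x$ni), x$p))
  cat("  visits per subject:", paste(range(x$ni), collapse = "-"),
      "| genotype counts:",
      paste(sprintf("G=%d:%d", 0:2, tabulate(x$G + 1L, 3L)), collapse = " "),
      "\n")
  invisible(x)
}

# flatten to the arrays the C++ engine consumes
flatten_data <- function(data) {
  list(y = as.numeric(unlist(data$y)),
       X = do.call(rbind, data$X),
       G = as.numeric(data$G),
       ni = as.integer(data$ni))
}
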