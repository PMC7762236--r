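# Correlation-matrix PCA of environment-level means of covariates and yield
# traits, with a collinearity screen, emitting biplot coordinates.

#' Environment-level mean table
#'
#' Averages the per-plot covariates and the main yield traits (grain number,
#' grain weight, grain yield) over genotypes and replications within each
#' site-year environment: one row per environment.
#'
#' @param plots plot record data frame (after [derive_traits()] for
#'   `gn_m2`).
#' @param covariates per-plot covariate data frame from
#'   [window_aggregates()].
#' @return data frame: `environment` plus mean columns; covariate columns
#'   with missing values in any environment are dropped with a warning.
#' @export
environment_table <- function(plots, covariates) {
  keys <- c("site", "year", "block", "genotype")
  merged <- merge(plots, covariates, by = keys)
  env <- .env_id(merged$site, merged$year)
  vars <- c(.covariate_cols,
            intersect(c("gn_m2", "gw_mg", "gy_g_m2"), names(merged)))
  vars <- intersect(vars, names(merged))
  out <- data.frame(environment = sort(unique(env)), stringsAsFactors = FALSE)
  dropped <- character(0)
  for (v in vars) {
    mns <- tapply(merged[[v]], env, mean, na.rm = TRUE)
    if (anyNA(mns) || any(!is.finite(mns)) ||
        any(tapply(is.na(merged[[v]]), env, all))) {
      dropped <- c(dropped, v)
      next
    }
    out[[v]] <- as.vector(mns[out$environment])
  }
  if (length(dropped))
    warning("dropped covariate column(s) missing for some environment: ",
            paste(dropped, collapse = ", "))
  out
}

#' Correlation-matrix principal component analysis
#'
#' Screens collinear variables (pairwise |r| above `collinearity_r_cut`;
#' the first column in order is kept), standardises the remainder, and
#' eigendecomposes their correlation matrix.  Axes are ordered by decreasing
#' eigenvalue; the sign convention makes each loading vector's
#' largest-magnitude element positive so output is deterministic.
#'
#' @param table data frame whose numeric columns are the variables (a
#'   non-numeric `environment`/id column is used for score row names);
#'   at least 3 rows.
#' @param collinearity_r_cut pairwise correlation threshold (default 0.95).
#' @return object of class `pca_corr`: list with `loadings` (variables x
#'   axes), `scores` (observations x axes), `explained` (% variance per
#'   axis), `correlation` (the matrix decomposed), `variables` (retained),
#'   `dropped_constant`, `dropped_collinear`.
#' @export
pca_corr <- function(table, collinearity_r_cut = 0.95) {
  ids <- NULL
  num <- vapply(table, is.numeric, logical(1))
  if (!all(num)) {
    ids <- as.character(table[[which(!num)[1]]])
    table <- table[num]
  }
  X <- as.matrix(table)
  if (!is.null(ids)) rownames(X) <- ids
  if (nrow(X) < 3) stop("PCA needs at least 3 observations")
  const <- apply(X, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  R_full <- stats::cor(X)
  keep <- logical(ncol(X))
  for (j in seq_len(ncol(X))) {
    keep[j] <- !any(keep & abs(R_full[j, ]) > collinearity_r_cut &
                      seq_len(ncol(X)) != j)
  }
  dropped_coll <- colnames(X)[!keep]
  X <- X[, keep, drop = FALSE]
  if (ncol(X) < 2) stop("fewer than 2 variables left after screening")
  R <- stats::cor(X)
  eig <- eigen(R, symmetric = TRUE)
  V <- eig$vectors
  for (j in seq_len(ncol(V))) {
    i_max <- which.max(abs(V[, j]))
    if (V[i_max, j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(colnames(X), paste0("PC", seq_len(ncol(V))))
  scores <- scale(X) %*% V
  explained <- 100 * eig$values / sum(eig$values)
  structure(list(loadings = V, scores = scores, explained = explained,
                 correlation = R, variables = colnames(X),
                 dropped_constant = if (exists("const"))
                   names(const)[const] else character(0),
                 dropped_collinear = dropped_coll),
            class = "pca_corr")
}

#' @export
print.pca_corr <- function(x, ...) {
  cat("Correlation-matrix PCA of", length(x$variables), "variables;",
      "axis 1-2 explain", round(sum(x$explained[1:2]), 1), "%\n")
  print(round(x$loadings[, 1:min(3, ncol(x$loadings))], 3))
  invisible(x)
}
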