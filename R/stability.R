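# Five genotype-by-environment yield-stability indices on a complete
# entity x environment cell-mean matrix: Finlay-Wilkinson joint regression,
# Lin-Binns superiority measure, Wricke ecovalence, Shukla stability
# variance, and Kang's rank-sum (yield-stability, YS) selection rule.

.as_matrix <- function(matrix) {
  if (inherits(matrix, "two_way_means")) matrix <- matrix$values
  m <- as.matrix(matrix)
  if (anyNA(m)) stop("cell-mean matrix must be complete (no NA cells)")
  m
}

#' Finlay-Wilkinson joint regression
#'
#' Regresses each entity's environment means on the environment index (the
#' column mean over entities).  The slope b measures responsiveness: b = 1 is
#' average, b > 1 above-average response to good environments.  A two-sided
#' t test of b = 1 uses q - 2 df (q environments).
#'
#' @param matrix `two_way_means` object or plain entity x environment matrix
#'   (at least 3 environments).
#' @return data frame: entity, b, se, t (vs 1), p.
#' @export
finlay_wilkinson <- function(matrix) {
  m <- .as_matrix(matrix)
  q <- ncol(m)
  if (q < 3) stop("need at least 3 environments")
  I <- colMeans(m)
  sxx <- sum((I - mean(I))^2)
  if (sxx == 0) stop("degenerate environments: zero variance in index")
  xc <- I - mean(I)
  b <- as.vector((m %*% xc) / sxx)
  fitted <- outer(rowMeans(m) - b * mean(I), rep(1, q)) + outer(b, I)
  rss <- rowSums((m - fitted)^2)
  se <- sqrt(rss / (q - 2) / sxx)
  tstat <- (b - 1) / se
  p <- 2 * stats::pt(abs(tstat), q - 2, lower.tail = FALSE)
  p[se == 0] <- ifelse(b[se == 0] == 1, 1, 0)
  data.frame(entity = rownames(m), b = b, se = se, t = tstat, p = p,
             stringsAsFactors = FALSE)
}

#' Lin-Binns superiority measure
#'
#' \eqn{P_i = \sum_j (x_{ij} - M_j)^2 / (2q)} where \eqn{M_j} is the best
#' (maximum) entity value in environment j.  Zero iff the entity is maximal
#' everywhere; small values indicate performance close to the best across
#' environments.
#'
#' @inheritParams finlay_wilkinson
#' @return named numeric vector of Pi values.
#' @export
lin_binns_pi <- function(matrix) {
  m <- .as_matrix(matrix)
  M <- apply(m, 2, max)
  rowSums((m - matrix(M, nrow(m), ncol(m), byrow = TRUE))^2) / (2 * ncol(m))
}

#' Wricke ecovalence
#'
#' \eqn{W_i^2 = \sum_j (x_{ij} - \bar x_{i.} - \bar x_{.j} + \bar x_{..})^2},
#' an entity's squared contribution to the two-way interaction sum of
#' squares; the W2 values sum exactly to the interaction SS.
#'
#' @inheritParams finlay_wilkinson
#' @return named numeric vector of W2 values.
#' @export
wricke_ecovalence <- function(matrix) {
  m <- .as_matrix(matrix)
  dev <- sweep(sweep(m, 1, rowMeans(m)), 2, colMeans(m)) + mean(m)
  rowSums(dev^2)
}

#' Shukla stability variance
#'
#' The unbiased per-entity estimate of genotype-by-environment variance,
#' a linear transform of ecovalence:
#' \deqn{\sigma^2_i = \frac{p}{(p-2)(q-1)} W_i^2 -
#'   \frac{\sum_k W_k^2}{(p-1)(p-2)(q-1)}}
#' for p entities and q environments.  Negative estimates are reported as-is
#' (not truncated).  When replicate-level error information is supplied,
#' significance of \eqn{\sigma^2_i > 0} is assessed by an approximate F test
#' against the pooled plot-level error variance of an entity cell mean
#' (`error_ms / n_per_mean`) on (q - 1, error_df) df; otherwise stars are
#' omitted, never fabricated.
#'
#' @inheritParams finlay_wilkinson
#' @param error_ms pooled plot-level error mean square (optional).
#' @param error_df its degrees of freedom.
#' @param n_per_mean plots contributing to each cell mean.
#' @return data frame: entity, w2, sigma2, f, p, stars.
#' @export
shukla_sigma2 <- function(matrix, error_ms = NULL, error_df = NULL,
                          n_per_mean = NULL) {
  m <- .as_matrix(matrix)
  p <- nrow(m); q <- ncol(m)
  if (p < 3) stop("Shukla stability variance needs at least 3 entities")
  w2 <- wricke_ecovalence(m)
  sigma2 <- p / ((p - 2) * (q - 1)) * w2 -
    sum(w2) / ((p - 1) * (p - 2) * (q - 1))
  out <- data.frame(entity = rownames(m), w2 = unname(w2),
                    sigma2 = unname(sigma2),
                    f = NA_real_, p = NA_real_, stars = NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(error_ms)) {
    stopifnot(!is.null(error_df), !is.null(n_per_mean))
    s2_mean <- error_ms / n_per_mean
    out$f <- out$sigma2 / s2_mean
    out$p <- stats::pf(out$f, q - 1, error_df, lower.tail = FALSE)
    out$p[out$f <= 0] <- 1
    out$stars <- significance_stars(out$p)
  }
  out
}

#' Kang rank-sum yield-stability (YS) selection
#'
#' The rank-sum rule combining yield and Shukla-stability evidence:
#' \enumerate{
#'   \item yield rank 1..p, highest mean = p (ties get average ranks);
#'   \item rank adjustment: +k when the entity mean exceeds the grand mean by
#'     more than k LSDs, -k symmetrically below, 0 within one LSD;
#'   \item stability rating 0 / -2 / -4 / -8 for Shukla sigma2 not
#'     significant / significant at 0.05 / 0.01 / 0.001;
#'   \item YS = rank + adjustment + rating;
#'   \item selected iff YS strictly exceeds the mean YS.
#' }
#' Without replicate error information the LSD adjustment is skipped (0) and
#' the result flagged unadjusted.
#'
#' @inheritParams finlay_wilkinson
#' @param replicate_error optional list with `error_ms`, `error_df`,
#'   `n_per_mean` (plots per entity overall mean) for the LSD step; Shukla
#'   significance uses the same error on cell means (see `n_cell`).
#' @param n_cell plots per entity x environment cell mean, used for the
#'   Shukla significance test (defaults to `n_per_mean / q`).
#' @param alpha LSD significance level (default 0.05).
#' @return data frame of class `kang_ys`: entity, mean, yield_rank,
#'   rank_adjustment, stability_rating, ys, selected; attribute `adjusted`.
#' @export
kang_ys <- function(matrix, replicate_error = NULL, n_cell = NULL,
                    alpha = 0.05) {
  m <- .as_matrix(matrix)
  p <- nrow(m); q <- ncol(m)
  means <- rowMeans(m)
  grand <- mean(means)
  yield_rank <- rank(means, ties.method = "average")
  adjusted <- !is.null(replicate_error)
  if (adjusted) {
    if (is.null(n_cell)) n_cell <- replicate_error$n_per_mean / q
    lsd <- stats::qt(1 - alpha / 2, replicate_error$error_df) *
      sqrt(2 * replicate_error$error_ms / replicate_error$n_per_mean)
    adj <- trunc((means - grand) / lsd)
    sh <- shukla_sigma2(m, replicate_error$error_ms,
                        replicate_error$error_df, n_cell)
    rating <- ifelse(is.na(sh$p) | sh$p >= 0.05, 0,
                     ifelse(sh$p < 0.001, -8, ifelse(sh$p < 0.01, -4, -2)))
  } else {
    adj <- rep(0, p)
    sh <- shukla_sigma2(m)
    rating <- rep(0, p)
  }
  ys <- yield_rank + adj + rating
  out <- data.frame(entity = rownames(m), mean = unname(means),
                    yield_rank = unname(yield_rank),
                    rank_adjustment = as.integer(adj),
                    stability_rating = as.integer(rating),
                    ys = unname(ys),
                    selected = unname(ys > mean(ys)),
                    stringsAsFactors = FALSE)
  structure(out, class = c("kang_ys", "data.frame"), adjusted = adjusted)
}

#' Kang selection flags for precomputed YS values
#'
#' The final selection step alone: entities whose YS exceeds the mean YS are
#' selected (`+`), the rest are not (`-`).
#'
#' @param ys numeric vector of YS values.
#' @return logical vector of selection flags.
#' @export
kang_select <- function(ys) ys > mean(ys)

#' Full yield-stability report at genotype and allele-combination level
#'
#' Computes all five indices per genotype on the genotype x environment
#' cell-mean matrix, using the combined-ANOVA residual as the replicate
#' error.  Allele-combination summaries are the unweighted means of the
#' member genotypes' indices, with LSD letter groups over member values per
#' index; a second, direct variant computes the indices on the
#' combination x environment mean matrix (both are returned, labelled).
#'
#' @param plots plot record data frame (balanced).
#' @param genotypes genotype metadata.
#' @param trait trait column (default grain yield `"gy_g_m2"`).
#' @param alpha significance level for LSD letters (default 0.05).
#' @return object of class `stability_report`: list with `genotype` (one row
#'   per genotype: mean, b, se_b, p_b, pi, sigma2, sigma2_stars, w2,
#'   yield_rank, rank_adjustment, stability_rating, ys, selected,
#'   allele_combination), `ac_summary` (per-combination index means with
#'   letter groups), `ac_matrix` (indices computed directly on the
#'   combination-level matrix) and `error` (the replicate error used).
#' @export
stability_report <- function(plots, genotypes, trait = "gy_g_m2",
                             alpha = 0.05) {
  keep <- genotypes[!genotypes$excluded, ]
  av <- combined_anova(plots, trait, genotypes)
  res <- av[av$source == "residual", ]
  n_blocks <- attr(av, "n_blocks")
  n_env <- attr(av, "n_environments")
  err <- list(error_ms = res$ms, error_df = res$df,
              n_per_mean = n_blocks * n_env)

  mg <- cell_means(plots, "genotype", trait, genotypes)
  fw <- finlay_wilkinson(mg)
  pi <- lin_binns_pi(mg)
  sh <- shukla_sigma2(mg, err$error_ms, err$error_df, n_blocks)
  ks <- kang_ys(mg, err, n_cell = n_blocks, alpha = alpha)

  g <- data.frame(genotype = fw$entity,
                  allele_combination =
                    keep$allele_combination[match(fw$entity, keep$genotype)],
                  mean = ks$mean, b = fw$b, se_b = fw$se, p_b = fw$p,
                  pi = unname(pi), sigma2 = sh$sigma2,
                  sigma2_stars = sh$stars, w2 = sh$w2,
                  yield_rank = ks$yield_rank,
                  rank_adjustment = ks$rank_adjustment,
                  stability_rating = ks$stability_rating,
                  ys = ks$ys, selected = ks$selected,
                  stringsAsFactors = FALSE)

  # combination summaries: unweighted means of member-genotype indices,
  # letters from a one-way ANOVA of the member values per index
  idx_cols <- c("mean", "b", "pi", "sigma2", "w2", "ys")
  acs <- sort(unique(g$allele_combination))
  summ <- data.frame(allele_combination = acs, stringsAsFactors = FALSE)
  n_members <- as.vector(table(g$allele_combination)[acs])
  summ$n_genotypes <- n_members
  for (cc in idx_cols)
    summ[[cc]] <- as.vector(tapply(g[[cc]], g$allele_combination, mean)[acs])
  summ$selected <- summ$ys > mean(g$ys)
  letter_groups <- list()
  multi <- acs[n_members >= 2]
  for (cc in idx_cols) {
    gm <- g[g$allele_combination %in% multi, ]
    f <- factor(gm$allele_combination)
    fit <- stats::aov(gm[[cc]] ~ f)
    an <- stats::anova(fit)
    mse <- an$`Mean Sq`[2]; dfe <- an$Df[2]
    n_h <- length(multi) / sum(1 / table(f))  # harmonic mean group size
    mc <- lsd_compare(stats::setNames(summ[[cc]][match(multi, acs)], multi),
                      n_per_mean = n_h, error_ms = mse, error_df = dfe,
                      alpha = alpha, protect_p = an$`Pr(>F)`[1])
    letter_groups[[cc]] <- mc
    summ[[paste0(cc, "_group")]] <-
      mc$table$group[match(acs, mc$table$entity)]
  }

  mac <- cell_means(plots, "allele_combination", trait, genotypes)
  n_cell_ac <- round(mean(mac$counts))
  err_ac <- list(error_ms = err$error_ms, error_df = err$error_df,
                 n_per_mean = n_cell_ac * n_env)
  fw_ac <- finlay_wilkinson(mac)
  sh_ac <- shukla_sigma2(mac, err$error_ms, err$error_df, n_cell_ac)
  ks_ac <- kang_ys(mac, err_ac, n_cell = n_cell_ac, alpha = alpha)
  ac_matrix <- data.frame(allele_combination = fw_ac$entity,
                          mean = ks_ac$mean, b = fw_ac$b, se_b = fw_ac$se,
                          p_b = fw_ac$p, pi = unname(lin_binns_pi(mac)),
                          sigma2 = sh_ac$sigma2, sigma2_stars = sh_ac$stars,
                          w2 = sh_ac$w2, ys = ks_ac$ys,
                          selected = ks_ac$selected,
                          stringsAsFactors = FALSE)

  structure(list(genotype = g, ac_summary = summ, ac_matrix = ac_matrix,
                 letter_groups = letter_groups, error = err, trait = trait),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Yield-stability report for trait", x$trait, "\n\n",
      "Allele-combination summary (means of member-genotype indices):\n")
  df <- x$ac_summary
  for (cc in c("mean", "b", "pi", "sigma2", "w2", "ys"))
    df[[cc]] <- signif(df[[cc]], 4)
  print(df, row.names = FALSE)
  invisible(x)
}
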