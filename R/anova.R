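# Combined ANOVA across sites and years for a balanced complete RCBD series,
# with the genotype sum of squares split into between- and within-
# allele-combination components, and Fisher's protected LSD comparison.
#
# All sums of squares are computed in closed form from marginal means, which
# on balanced data equal the sequential (and Type-III) SS of the linear model
#   y ~ site + year + site:year + block(site:year) + genotype
#       + genotype:site + genotype:year + genotype:site:year.

.ss_main <- function(y, f, grand) {
  m <- tapply(y, f, mean)
  n <- tapply(y, f, length)
  sum(n * (m - grand)^2)
}

#' Combined analysis of variance with genotype sum-of-squares split
#'
#' Sequential ANOVA of a trait over the complete sites x years x genotypes x
#' blocks design, with blocks nested in site-year.  The genotype main effect
#' is split into between-allele-combination (4 df for 5 combinations) and
#' within-combination (earliness per se) components, and the genotype x site
#' and genotype x site x year interactions are split analogously.  The F test
#' for the between-combination source uses the within-combination mean square
#' as its error term (the one non-default denominator of the analysis); every
#' other source is tested against the residual mean square.  Denominators are
#' labelled in the output so alternative quasi-F ratios can be formed.
#'
#' @param plots plot record data frame.
#' @param trait trait column name.
#' @param genotypes genotype metadata (see [genotype_meta()]); excluded
#'   combinations' genotypes are dropped before analysis.
#' @param strict error on unbalanced/incomplete data (default TRUE).
#' @return object of class `anova_table`: data frame with columns `source`,
#'   `df`, `ss`, `pct_ss`, `ms`, `f`, `p`, `stars`, `error_term`, `nested`
#'   (TRUE for the split sub-rows, which re-partition their parent row), plus
#'   attributes `total_ss`, `trait`, `n_blocks`.
#' @export
combined_anova <- function(plots, trait, genotypes, strict = TRUE) {
  if (!trait %in% names(plots)) stop("trait column not found: ", trait)
  keep <- genotypes[!genotypes$excluded, ]
  plots <- plots[plots$genotype %in% keep$genotype, ]
  y <- plots[[trait]]
  if (anyNA(y)) {
    if (strict) stop("missing values in trait ", trait, " (strict mode)")
    plots <- plots[!is.na(y), ]
    y <- plots[[trait]]
  }
  s <- factor(plots$site)
  t <- factor(plots$year)
  g <- factor(plots$genotype)
  b <- factor(plots$block)
  ac <- factor(keep$allele_combination[match(plots$genotype, keep$genotype)])
  cell <- table(s, t, g, b)
  if (any(cell != 1L)) {
    if (strict)
      stop("design is not a complete balanced RCBD series (strict mode): ",
           sum(cell != 1L), " cells do not have exactly one plot")
  }
  S <- nlevels(s); T <- nlevels(t); G <- nlevels(g); B <- nlevels(b)
  A <- nlevels(ac)
  N <- length(y)
  grand <- mean(y)
  ss_tot <- sum((y - grand)^2)

  f_sy <- interaction(s, t, drop = TRUE)
  f_gs <- interaction(g, s, drop = TRUE)
  f_gt <- interaction(g, t, drop = TRUE)
  f_gst <- interaction(g, s, t, drop = TRUE)
  f_blk <- interaction(s, t, b, drop = TRUE)
  f_acs <- interaction(ac, s, drop = TRUE)
  f_acst <- interaction(ac, s, t, drop = TRUE)

  ss_s <- .ss_main(y, s, grand)
  ss_t <- .ss_main(y, t, grand)
  ss_sy <- .ss_main(y, f_sy, grand) - ss_s - ss_t
  ss_g <- .ss_main(y, g, grand)
  ss_gs <- .ss_main(y, f_gs, grand) - ss_g - ss_s
  ss_gt <- .ss_main(y, f_gt, grand) - ss_g - ss_t
  ss_gst <- .ss_main(y, f_gst, grand) -
    ss_g - ss_s - ss_t - ss_gs - ss_gt - ss_sy
  ss_blk <- .ss_main(y, f_blk, grand) - ss_s - ss_t - ss_sy
  ss_ac <- .ss_main(y, ac, grand)
  ss_acs <- .ss_main(y, f_acs, grand) - ss_ac - ss_s
  ss_acst <- .ss_main(y, f_acst, grand) -
    ss_ac - ss_s - ss_t - ss_acs - ss_sy -
    (.ss_main(y, interaction(ac, t, drop = TRUE), grand) - ss_ac - ss_t)
  ss_res <- ss_tot -
    (ss_s + ss_t + ss_sy + ss_g + ss_gs + ss_gt + ss_gst + ss_blk)

  split_ok <- A >= 2
  if (!split_ok)
    warning("fewer than 2 allele combinations; genotype split skipped")

  src <- list(
    list("site", S - 1, ss_s, FALSE),
    list("year", T - 1, ss_t, FALSE),
    list("site_x_year", (S - 1) * (T - 1), ss_sy, FALSE),
    list("genotype", G - 1, ss_g, FALSE),
    list("between_ac", A - 1, ss_ac, TRUE),
    list("within_ac", G - A, ss_g - ss_ac, TRUE),
    list("genotype_x_site", (G - 1) * (S - 1), ss_gs, FALSE),
    list("between_ac_x_site", (A - 1) * (S - 1), ss_acs, TRUE),
    list("within_ac_x_site", (G - A) * (S - 1), ss_gs - ss_acs, TRUE),
    list("genotype_x_year", (G - 1) * (T - 1), ss_gt, FALSE),
    list("genotype_x_site_x_year", (G - 1) * (S - 1) * (T - 1), ss_gst, FALSE),
    list("between_ac_x_site_x_year", (A - 1) * (S - 1) * (T - 1), ss_acst,
         TRUE),
    list("within_ac_x_site_x_year", (G - A) * (S - 1) * (T - 1),
         ss_gst - ss_acst, TRUE),
    list("block", S * T * (B - 1), ss_blk, FALSE),
    list("residual", NA_integer_, ss_res, FALSE))
  df_model <- (S - 1) + (T - 1) + (S - 1) * (T - 1) + (G - 1) +
    (G - 1) * (S - 1) + (G - 1) * (T - 1) + (G - 1) * (S - 1) * (T - 1) +
    S * T * (B - 1)
  src[[length(src)]][[2]] <- N - 1 - df_model
  if (!split_ok) src <- src[!vapply(src, `[[`, logical(1), 4)]

  tab <- data.frame(
    source = vapply(src, `[[`, character(1), 1),
    df = vapply(src, function(z) as.integer(z[[2]]), integer(1)),
    ss = vapply(src, `[[`, numeric(1), 3),
    nested = vapply(src, `[[`, logical(1), 4),
    stringsAsFactors = FALSE)
  tab$pct_ss <- 100 * tab$ss / ss_tot
  tab$ms <- ifelse(tab$df > 0, tab$ss / tab$df, NA_real_)
  ms_res <- tab$ms[tab$source == "residual"]
  df_res <- tab$df[tab$source == "residual"]
  ms_within <- if (split_ok) tab$ms[tab$source == "within_ac"] else NA_real_
  df_within <- if (split_ok) tab$df[tab$source == "within_ac"] else NA_integer_

  tab$error_term <- ifelse(tab$source == "between_ac", "within_ac", "residual")
  tab$error_term[tab$source == "residual"] <- NA_character_
  tab$f <- NA_real_
  tab$p <- NA_real_
  for (i in seq_len(nrow(tab))) {
    if (tab$source[i] == "residual" || is.na(tab$ms[i])) next
    den_ms <- if (tab$error_term[i] == "within_ac") ms_within else ms_res
    den_df <- if (tab$error_term[i] == "within_ac") df_within else df_res
    if (is.na(den_ms) || den_ms <= 0 || den_df <= 0) next
    tab$f[i] <- tab$ms[i] / den_ms
    tab$p[i] <- stats::pf(tab$f[i], tab$df[i], den_df, lower.tail = FALSE)
  }
  tab$stars <- significance_stars(tab$p)

  # internal consistency: SS additivity over primary sources
  prim <- tab[!tab$nested & tab$source != "residual", "ss"]
  stopifnot(abs(sum(prim) + ss_res - ss_tot) <= 1e-8 * max(ss_tot, 1))

  structure(tab, class = c("anova_table", "data.frame"),
            total_ss = ss_tot, trait = trait, n_blocks = B,
            n_environments = S * T)
}

#' Significance stars
#'
#' Standard convention: `***` below 0.001, `**` below 0.01, `*` below 0.05,
#' `ns` otherwise.
#'
#' @param p numeric vector of p values (NA allowed).
#' @return character vector of star codes.
#' @export
significance_stars <- function(p) {
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  out[ok] <- ifelse(p[ok] < 0.001, "***",
                    ifelse(p[ok] < 0.01, "**",
                           ifelse(p[ok] < 0.05, "*", "ns")))
  out
}

#' @export
print.anova_table <- function(x, ...) {
  cat("Combined ANOVA for trait", attr(x, "trait"), "\n")
  df <- as.data.frame(x)
  df$ss <- signif(df$ss, 6)
  df$pct_ss <- round(df$pct_ss, 2)
  df$ms <- signif(df$ms, 6)
  df$f <- round(df$f, 2)
  df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

# compact letter display by insert-and-absorb over descending means; valid
# because the LSD threshold is common to all pairs (interval graph)
.cld_letters <- function(means_sorted, lsd) {
  k <- length(means_sorted)
  ends <- integer(k)
  for (i in seq_len(k)) {
    j <- i
    while (j < k && means_sorted[i] - means_sorted[j + 1] <= lsd) j <- j + 1
    ends[i] <- j
  }
  # ends is non-decreasing, so interval i is absorbed by interval i-1 exactly
  # when both end at the same mean; keep the maximal ones
  starts <- which(c(TRUE, diff(ends) > 0))
  letters_out <- character(k)
  for (gi in seq_along(starts)) {
    rng <- starts[gi]:ends[starts[gi]]
    letters_out[rng] <- paste0(letters_out[rng], letters[gi])
  }
  letters_out
}

#' Fisher's protected LSD means comparison
#'
#' Least significant difference
#' \eqn{LSD = t_{1-\alpha/2, df} \sqrt{2\,MS_e / n}} with a compact letter
#' display over the sorted means (letter `a` = highest mean).  Protection:
#' when the protecting omnibus F test is not significant (`protect_p >
#' alpha`), all entities share letter `a` and the result is flagged
#' unprotected.
#'
#' @param means named numeric vector of entity means.
#' @param n_per_mean observations contributing to each mean.
#' @param error_ms error mean square.
#' @param error_df error degrees of freedom.
#' @param alpha significance level (default 0.05).
#' @param protect_p p value of the protecting F test (optional).
#' @return object of class `means_comparison`: list with `table` (entity,
#'   mean, group), `lsd`, `alpha`, `protected`.
#' @export
lsd_compare <- function(means, n_per_mean, error_ms, error_df, alpha = 0.05,
                        protect_p = NULL) {
  if (is.null(names(means))) names(means) <- seq_along(means)
  lsd <- stats::qt(1 - alpha / 2, error_df) * sqrt(2 * error_ms / n_per_mean)
  ord <- order(means, decreasing = TRUE)
  protected <- is.null(protect_p) || protect_p <= alpha
  grp <- if (protected) .cld_letters(means[ord], lsd)
         else rep("a", length(means))
  tab <- data.frame(entity = names(means)[ord], mean = unname(means[ord]),
                    group = grp, stringsAsFactors = FALSE)
  structure(list(table = tab, lsd = lsd, alpha = alpha, protected = protected),
            class = "means_comparison")
}

#' @export
print.means_comparison <- function(x, ...) {
  cat("LSD =", signif(x$lsd, 4), "at alpha =", x$alpha,
      if (!x$protected) "(protecting F not significant)" else "", "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
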