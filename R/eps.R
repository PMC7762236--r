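# Per-experiment mixed model isolating within-allele-combination (earliness
# per se) genotype effects:
#
#   Y_ij = AC_i + G(AC)_ij + R_j + E_ij
#
# with fixed allele-combination effects, random genotype-within-combination,
# random replicate (block), and residual.  REML fits are delegated to
# lme4::lmer; BLUPs of the genotype effect are the shrinkage estimates of the
# earliness-per-se signal, centred on their combination by construction of
# the fixed term.

.one_experiment <- function(plots) {
  env <- unique(.env_id(plots$site, plots$year))
  if (length(env) != 1)
    stop("expected plots from a single experiment, got: ",
         paste(env, collapse = ", "))
  env
}

#' Fit the per-experiment earliness-per-se mixed model
#'
#' REML fit of the model with fixed allele combination, random
#' genotype-within-combination and random replicate, for one experiment's
#' plots.  Returns variance components, per-genotype BLUPs and the balanced
#' shrinkage factor \eqn{k_g = \sigma^2_g / (\sigma^2_g + \sigma^2_e /
#' n_{rep})}.  Negative variance components are truncated at zero (the REML
#' boundary); a boundary fit is flagged `singular`.
#'
#' @param plots plot records of a single experiment.
#' @param trait trait column name.
#' @param genotypes genotype metadata; genotypes of excluded (singleton)
#'   combinations are dropped with a warning since they carry no
#'   within-combination information.
#' @return object of class `eps_fit`: list with `site`, `year`, `trait`,
#'   `fixed_ac`, `sigma2_g`, `sigma2_r`, `sigma2_e`, `blup` (named numeric),
#'   `shrinkage`, `n_rep`, `singular`.
#' @export
fit_eps_model <- function(plots, trait, genotypes) {
  .one_experiment(plots)
  keep <- genotypes[!genotypes$excluded, ]
  dropped <- setdiff(unique(plots$genotype), keep$genotype)
  if (length(dropped))
    warning("dropping genotype(s) of singleton allele combinations: ",
            paste(dropped, collapse = ", "))
  plots <- plots[plots$genotype %in% keep$genotype, ]
  y <- plots[[trait]]
  ok <- !is.na(y)
  d <- data.frame(
    y = as.numeric(y[ok]),
    ac = factor(keep$allele_combination[match(plots$genotype[ok],
                                              keep$genotype)]),
    genotype = factor(plots$genotype[ok]),
    block = factor(plots$block[ok]))
  if (nlevels(d$genotype) < 2) stop("need at least 2 genotypes")
  n_rep <- nlevels(d$block)
  form <- if (nlevels(d$ac) > 1) y ~ ac + (1 | genotype) + (1 | block)
          else y ~ 1 + (1 | genotype) + (1 | block)
  ctrl <- lme4::lmerControl(
    check.conv.singular = "ignore",
    optimizer = "bobyqa",
    optCtrl = list(rhobeg = 0.2, rhoend = 1e-10))
  fit <- suppressMessages(lme4::lmer(form, data = d, REML = TRUE,
                                     control = ctrl))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sig2 <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v[1] else 0
  }
  sigma2_g <- sig2("genotype")
  sigma2_r <- sig2("block")
  sigma2_e <- sig2("Residual")
  blup <- lme4::ranef(fit)$genotype
  blup_v <- stats::setNames(blup[[1]], rownames(blup))
  blup_v <- blup_v[levels(d$genotype)]
  shrink <- sigma2_g / (sigma2_g + sigma2_e / n_rep)
  if (!is.finite(shrink)) shrink <- 0
  structure(list(site = plots$site[1], year = plots$year[1], trait = trait,
                 fixed_ac = lme4::fixef(fit),
                 sigma2_g = sigma2_g, sigma2_r = sigma2_r,
                 sigma2_e = sigma2_e,
                 blup = blup_v, shrinkage = shrink, n_rep = n_rep,
                 singular = lme4::isSingular(fit)),
            class = "eps_fit")
}

#' @export
print.eps_fit <- function(x, ...) {
  cat("Earliness-per-se model fit:", x$site, x$year, "trait", x$trait, "\n",
      sprintf("sigma2_g = %.4g, sigma2_r = %.4g, sigma2_e = %.4g (k = %.3f)%s\n",
              x$sigma2_g, x$sigma2_r, x$sigma2_e, x$shrinkage,
              if (x$singular) " [boundary]" else ""))
  invisible(x)
}

#' BLUPs of earliness-per-se effects for every experiment and trait
#'
#' Runs [fit_eps_model()] for each (experiment, trait) pair and collects the
#' genotype BLUPs in long format.
#'
#' @param plots plot record data frame (all experiments); run
#'   [derive_traits()] first if duration or grain-number traits are needed.
#' @param traits character vector of trait column names.
#' @param genotypes genotype metadata.
#' @return list with `blups` (data frame site, year, trait, genotype, blup)
#'   and `fits` (named list of `eps_fit` objects, `"SITE-YEAR|trait"`).
#' @export
eps_blups <- function(plots, traits, genotypes) {
  envs <- unique(.env_id(plots$site, plots$year))
  fits <- list()
  rows <- list()
  for (e in sort(envs)) {
    pe <- plots[.env_id(plots$site, plots$year) == e, ]
    for (tr in traits) {
      if (!tr %in% names(pe) || all(is.na(pe[[tr]]))) next
      f <- fit_eps_model(pe, tr, genotypes)
      fits[[paste(e, tr, sep = "|")]] <- f
      rows[[length(rows) + 1L]] <- data.frame(
        site = f$site, year = f$year, trait = tr,
        genotype = names(f$blup), blup = unname(f$blup),
        stringsAsFactors = FALSE)
    }
  }
  list(blups = do.call(rbind, rows), fits = fits)
}

#' Pearson correlations between earliness-per-se BLUPs of trait pairs
#'
#' For every experiment, correlates the genotype BLUPs of each x trait
#' (typically the phase durations) with those of each y trait (yield
#' formation traits).  Two-sided p values come from the t transform with
#' n - 2 df.  Pairs where either BLUP vector is (numerically) constant are
#' excluded and recorded in the `excluded` attribute; experiments with fewer
#' than 4 genotypes keep their r but the p value is flagged unreliable.
#'
#' @param blups long BLUP data frame from [eps_blups()].
#' @param x_traits,y_traits trait name vectors to pair.
#' @return data frame of class `correlation_table`: site, year, x_trait,
#'   y_trait, n, r, p, stars, flag.
#' @export
eps_correlations <- function(blups,
                             x_traits = c("days_ef", "days_fm"),
                             y_traits = c("gn_m2", "gw_mg", "gy_g_m2",
                                          "spikes_m2", "grains_per_spike",
                                          "spikelets_per_spike",
                                          "grains_per_spikelet")) {
  key <- .env_id(blups$site, blups$year)
  rows <- list()
  excluded <- character(0)
  for (e in sort(unique(key))) {
    be <- blups[key == e, ]
    for (xt in intersect(x_traits, be$trait)) {
      for (yt in intersect(y_traits, be$trait)) {
        bx <- be[be$trait == xt, ]
        by <- be[be$trait == yt, ]
        m <- merge(bx[c("genotype", "blup")], by[c("genotype", "blup")],
                   by = "genotype", suffixes = c("_x", "_y"))
        n <- nrow(m)
        if (n < 3) next
        if (stats::sd(m$blup_x) < 1e-10 || stats::sd(m$blup_y) < 1e-10) {
          excluded <- c(excluded, paste(e, xt, yt, sep = "|"))
          next
        }
        r <- stats::cor(m$blup_x, m$blup_y)
        tstat <- r * sqrt((n - 2) / (1 - r^2))
        p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          site = bx$site[1], year = bx$year[1], x_trait = xt, y_trait = yt,
          n = n, r = r, p = p, stars = significance_stars(p),
          flag = if (n < 4) "low_n" else "",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(site = character(0), year = integer(0),
                      x_trait = character(0), y_trait = character(0),
                      n = integer(0), r = numeric(0), p = numeric(0),
                      stars = character(0), flag = character(0))
  structure(out, class = c("correlation_table", "data.frame"),
            excluded = excluded)
}
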