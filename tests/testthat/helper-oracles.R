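# Independent oracles, deliberately written with brute force (explicit loops,
# numerical scans, closed forms) and kept decoupled from the package code
# paths they are used to check.

# day length by minute-scan of the solar altitude over the hour angle,
# sharing only the declination with the closed-form model under test
ora_day_length_scan <- function(lat_deg, doy, p_deg, n = 200001) {
  theta <- 0.2163108 + 2 * atan(0.9671396 * tan(0.00860 * (doy - 186)))
  delta <- asin(0.39795 * cos(theta))
  H <- seq(0, pi, length.out = n)
  alt <- asin(sin(lat_deg * pi / 180) * sin(delta) +
                cos(lat_deg * pi / 180) * cos(delta) * cos(H))
  24 * mean(alt > -p_deg * pi / 180)
}

# sequential SS of the combined model by explicit mean-decomposition loops
ora_anova_loops <- function(df, trait) {
  y <- df[[trait]]
  m <- mean(y)
  mn <- function(cond) mean(y[cond])
  ss <- list(site = 0, year = 0, site_x_year = 0, genotype = 0,
             genotype_x_site = 0, genotype_x_year = 0,
             genotype_x_site_x_year = 0, block = 0)
  for (s in unique(df$site)) ss$site <- ss$site +
    sum(df$site == s) * (mn(df$site == s) - m)^2
  for (t in unique(df$year)) ss$year <- ss$year +
    sum(df$year == t) * (mn(df$year == t) - m)^2
  for (s in unique(df$site)) for (t in unique(df$year)) {
    c1 <- df$site == s & df$year == t
    ss$site_x_year <- ss$site_x_year +
      sum(c1) * (mn(c1) - mn(df$site == s) - mn(df$year == t) + m)^2
  }
  for (g in unique(df$genotype)) ss$genotype <- ss$genotype +
    sum(df$genotype == g) * (mn(df$genotype == g) - m)^2
  for (g in unique(df$genotype)) for (s in unique(df$site)) {
    c1 <- df$genotype == g & df$site == s
    ss$genotype_x_site <- ss$genotype_x_site +
      sum(c1) * (mn(c1) - mn(df$genotype == g) - mn(df$site == s) + m)^2
  }
  for (g in unique(df$genotype)) for (t in unique(df$year)) {
    c1 <- df$genotype == g & df$year == t
    ss$genotype_x_year <- ss$genotype_x_year +
      sum(c1) * (mn(c1) - mn(df$genotype == g) - mn(df$year == t) + m)^2
  }
  for (g in unique(df$genotype)) for (s in unique(df$site))
    for (t in unique(df$year)) {
      c1 <- df$genotype == g & df$site == s & df$year == t
      ss$genotype_x_site_x_year <- ss$genotype_x_site_x_year + sum(c1) *
        (mn(c1) -
           mn(df$genotype == g & df$site == s) -
           mn(df$genotype == g & df$year == t) -
           mn(df$site == s & df$year == t) +
           mn(df$genotype == g) + mn(df$site == s) + mn(df$year == t) - m)^2
    }
  for (s in unique(df$site)) for (t in unique(df$year))
    for (b in unique(df$block)) {
      c1 <- df$site == s & df$year == t & df$block == b
      ss$block <- ss$block +
        sum(c1) * (mn(c1) - mn(df$site == s & df$year == t))^2
    }
  ss$total <- sum((y - m)^2)
  ss$residual <- ss$total - sum(unlist(ss[names(ss) != "total"]))
  ss
}

# between-allele-combination SS by loops (genotype split oracle)
ora_between_ac_ss <- function(df, trait, ac_of) {
  y <- df[[trait]]
  m <- mean(y)
  ac <- ac_of[df$genotype]
  out <- 0
  for (a in unique(ac)) out <- out + sum(ac == a) * (mean(y[ac == a]) - m)^2
  out
}

# closed-form balanced REML for y = mu + genotype + block + error: ANOVA
# estimators with REML boundary truncation (pool the truncated stratum)
ora_reml_oneway <- function(y, genotype, block) {
  g <- factor(genotype); b <- factor(block)
  G <- nlevels(g); B <- nlevels(b); m <- mean(y)
  ss_g <- B * sum((tapply(y, g, mean) - m)^2)
  ss_b <- G * sum((tapply(y, b, mean) - m)^2)
  ss_e <- sum((y - tapply(y, g, mean)[g] - tapply(y, b, mean)[b] + m)^2)
  df_g <- G - 1; df_b <- B - 1; df_e <- (G - 1) * (B - 1)
  ms_g <- ss_g / df_g; ms_b <- ss_b / df_b; ms_e <- ss_e / df_e
  s2_e <- ms_e
  s2_g <- (ms_g - s2_e) / B
  s2_b <- (ms_b - s2_e) / G
  if (s2_b < 0) {        # block at boundary: refit without block stratum
    s2_b <- 0
    s2_e <- (ss_e + ss_b) / (df_e + df_b)
    s2_g <- (ms_g - s2_e) / B
  }
  if (s2_g < 0) {
    s2_g <- 0
    s2_e <- (ss_e + ss_g) / (df_e + df_g)
    s2_b <- max((ms_b - s2_e) / G, 0)
  }
  list(sigma2_g = s2_g, sigma2_r = s2_b, sigma2_e = s2_e)
}

# Kang rank-sum rule by rule, scripted independently
ora_kang <- function(means, sigma2_p, lsd) {
  p <- length(means)
  rk <- rank(means, ties.method = "average")
  adj <- integer(p)
  grand <- mean(means)
  for (i in seq_len(p)) {
    k <- 0
    while (abs(means[i] - grand) > (k + 1) * lsd) k <- k + 1
    adj[i] <- if (means[i] > grand) k else -k
  }
  rating <- vapply(sigma2_p, function(pp) {
    if (is.na(pp) || pp >= 0.05) 0L
    else if (pp < 0.001) -8L else if (pp < 0.01) -4L else -2L
  }, integer(1))
  ys <- rk + adj + rating
  list(rank = rk, adjustment = adj, rating = rating, ys = ys,
       selected = ys > mean(ys))
}

# explicit per-entity least squares for the joint regression
ora_fw_lm <- function(m) {
  I <- colMeans(m)
  t(apply(m, 1, function(row) {
    fit <- stats::lm(row ~ I)
    c(b = unname(stats::coef(fit)[2]),
      se = summary(fit)$coefficients[2, 2])
  }))
}

# ecovalence by double loop
ora_w2_loops <- function(m) {
  p <- nrow(m); q <- ncol(m)
  gm <- mean(m)
  out <- numeric(p)
  for (i in seq_len(p)) for (j in seq_len(q))
    out[i] <- out[i] + (m[i, j] - mean(m[i, ]) - mean(m[, j]) + gm)^2
  out
}

ora_pi_loops <- function(m) {
  q <- ncol(m)
  M <- apply(m, 2, max)
  apply(m, 1, function(row) sum((row - M)^2) / (2 * q))
}

ora_sigma2_formula <- function(w2) {
  # independently re-coded linear map, p entities, q environments implied by
  # caller supplying w2 of a full matrix
  function(p, q) p / ((p - 2) * (q - 1)) * w2 -
    sum(w2) / ((p - 1) * (p - 2) * (q - 1))
}

# all-pairs LSD letter oracle: entities share a letter iff no chain of
# significant differences separates them (common threshold -> interval rule)
ora_lsd_groups_allpairs <- function(means, lsd) {
  ord <- order(means, decreasing = TRUE)
  ms <- means[ord]
  k <- length(ms)
  sig <- abs(outer(ms, ms, "-")) > lsd
  # intervals of mutually non-different entities
  groups <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !sig[i, j + 1]) j <- j + 1
    groups[[i]] <- i:j
  }
  groups <- groups[!duplicated(vapply(groups, max, 1L))]
  lett <- character(k)
  for (gi in seq_along(groups))
    lett[groups[[gi]]] <- paste0(lett[groups[[gi]]], letters[gi])
  stats::setNames(lett, names(ms))
}

# small balanced plot table with controllable effects, for ANOVA/LSD tests
make_tiny_plots <- function(sites = c("A", "B"), years = c(2001L, 2002L),
                            genotypes, blocks = 2L,
                            effect_fun, noise_sd = 0, seed = 99) {
  set.seed(seed)
  df <- expand.grid(site = sites, year = years,
                    genotype = genotypes$genotype, block = seq_len(blocks),
                    stringsAsFactors = FALSE)
  df$gy_g_m2 <- effect_fun(df) + stats::rnorm(nrow(df), 0, noise_sd)
  df$gw_mg <- 40
  df
}

tiny_genotypes <- function(n = 3, two_ac = FALSE) {
  # n genotypes in one allele combination, or split evenly over two
  a1 <- if (two_ac)
    rep(c("Ppd-A1b", "GS105-Ppd-A1a"), each = ceiling(n / 2))[seq_len(n)]
  else rep("Ppd-A1b", n)
  genotype_meta(data.frame(genotype = sprintf("g%02d", seq_len(n)),
                           ppd_a1 = a1, ppd_b1 = "Ppd-B1b",
                           stringsAsFactors = FALSE))
}
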