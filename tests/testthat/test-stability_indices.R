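rand_matrix <- function(p, q, seed) {
  set.seed(seed)
  matrix(rnorm(p * q, 500, 60), p, q,
         dimnames = list(paste0("e", seq_len(p)), paste0("env", seq_len(q))))
}

test_that("joint regression slopes match the per-entity least-squares oracle", {
  m <- matrix(c(10, 12, 14, 16,
                8, 12, 16, 20,
                12, 12, 12, 12), 3, 4, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), paste0("E", 1:4)))
  fw <- finlay_wilkinson(m)
  expect_equal(fw$b, c(1, 2, 0), tolerance = 1e-12)

  # identity response: every row equals the index -> b = 1, p = 1
  mi <- rbind(a = c(5, 8, 11, 20), b = c(5, 8, 11, 20))
  fwi <- finlay_wilkinson(mi)
  expect_equal(fwi$b, c(1, 1), tolerance = 1e-12)
  expect_equal(fwi$p, c(1, 1))

  for (seed in 1:5) {
    m <- rand_matrix(6, 8, seed)
    fw <- finlay_wilkinson(m)
    ora <- ora_fw_lm(m)
    expect_equal(fw$b, unname(ora[, "b"]), tolerance = 1e-9)
    expect_equal(fw$se, unname(ora[, "se"]), tolerance = 1e-9)
  }
  expect_error(finlay_wilkinson(matrix(1, 3, 2)), "at least 3")
  expect_error(finlay_wilkinson(matrix(5, 3, 4)), "degenerate")
})

test_that("superiority, ecovalence and stability variance match their oracles", {
  # hand-evaluated 2x2 case
  m22 <- rbind(a = c(10, 20), b = c(8, 24))
  expect_equal(unname(lin_binns_pi(m22)), c((0 + 16) / 4, (4 + 0) / 4))

  # entity maximal everywhere has Pi = 0, and only then
  for (seed in 1:10) {
    m <- rand_matrix(5, 6, 100 + seed)
    m[2, ] <- apply(m, 2, max) + 1
    pi <- lin_binns_pi(m)
    expect_equal(unname(pi[2]), 0)
    expect_true(all(pi[-2] > 0))
    expect_equal(unname(pi), unname(ora_pi_loops(m)), tolerance = 1e-10)
  }

  # additive matrix: all W2 = 0, sigma2 = 0, b = 1
  add <- outer(c(1, 5, 9), c(100, 110, 150, 90), "+")
  rownames(add) <- paste0("e", 1:3)
  expect_true(all(abs(wricke_ecovalence(add)) < 1e-18))
  expect_true(all(abs(shukla_sigma2(add)$sigma2) < 1e-18))
  expect_equal(finlay_wilkinson(add)$b, rep(1, 3), tolerance = 1e-12)

  for (seed in 1:10) {
    p <- sample(3:8, 1); q <- sample(3:8, 1)
    m <- rand_matrix(p, q, 200 + seed)
    w2 <- wricke_ecovalence(m)
    expect_equal(unname(w2), ora_w2_loops(m), tolerance = 1e-10)
    # ecovalences sum to the interaction SS
    ss_ge <- sum((m - outer(rowMeans(m), rep(1, q)) -
                    outer(rep(1, p), colMeans(m)) + mean(m))^2)
    expect_equal(sum(w2), ss_ge, tolerance = 1e-8 * ss_ge)
    # sigma2 is the stated linear transform of W2
    sig <- shukla_sigma2(m)$sigma2
    expect_equal(sig, ora_sigma2_formula(w2)(p, q), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  expect_error(shukla_sigma2(rand_matrix(2, 4, 1)), "at least 3")
})

test_that("negative Shukla variances are retained, not truncated", {
  set.seed(77)
  found_neg <- FALSE
  for (seed in 1:20) {
    m <- rand_matrix(6, 5, 300 + seed)
    sig <- shukla_sigma2(m)$sigma2
    if (any(sig < 0)) found_neg <- TRUE
  }
  expect_true(found_neg)
})

test_that("index invariances hold under shifts and rescaling", {
  m <- rand_matrix(6, 7, 42)
  shift <- m + 250
  expect_equal(finlay_wilkinson(shift)$b, finlay_wilkinson(m)$b,
               tolerance = 1e-9)
  expect_equal(lin_binns_pi(shift), lin_binns_pi(m), tolerance = 1e-9)
  expect_equal(wricke_ecovalence(shift), wricke_ecovalence(m),
               tolerance = 1e-8)
  expect_equal(shukla_sigma2(shift)$sigma2, shukla_sigma2(m)$sigma2,
               tolerance = 1e-8)
  scaled <- m * 3
  expect_equal(finlay_wilkinson(scaled)$b, finlay_wilkinson(m)$b,
               tolerance = 1e-9)
  expect_equal(rank(rowMeans(scaled)), rank(rowMeans(m)))
  # mean of entity slopes is exactly 1 on any complete matrix
  expect_equal(mean(finlay_wilkinson(m)$b), 1, tolerance = 1e-12)
})

test_that("Kang rank-sum follows its five rules and the scripted oracle", {
  # published-style selection step: YS (8, 5, 2, -7, -5) -> (+, +, +, -, -)
  ys <- c(8, 5, 2, -7, -5)
  expect_equal(kang_select(ys), c(TRUE, TRUE, TRUE, FALSE, FALSE))

  # all-identical entities: no adjustment, no rating, nobody selected
  m_const <- matrix(500, 4, 5, dimnames = list(paste0("e", 1:4), NULL))
  ks0 <- kang_ys(m_const, replicate_error = list(error_ms = 100,
                                                 error_df = 60,
                                                 n_per_mean = 15))
  expect_true(all(ks0$yield_rank == 2.5))
  expect_true(all(ks0$rank_adjustment == 0L))
  expect_true(all(ks0$stability_rating == 0L))
  expect_false(any(ks0$selected))

  # seeded instances against the rule-by-rule oracle
  for (seed in 1:8) {
    m <- rand_matrix(5, 6, 400 + seed)
    err <- list(error_ms = 2500, error_df = 100, n_per_mean = 18)
    ks <- kang_ys(m, err, n_cell = 3)
    lsd <- qt(0.975, err$error_df) * sqrt(2 * err$error_ms / err$n_per_mean)
    sig <- shukla_sigma2(m, err$error_ms, err$error_df, 3)
    ora <- ora_kang(rowMeans(m), sig$p, lsd)
    expect_equal(ks$yield_rank, unname(ora$rank))
    expect_equal(ks$rank_adjustment, unname(as.integer(ora$adjustment)))
    expect_equal(ks$stability_rating, unname(as.integer(ora$rating)))
    expect_equal(ks$ys, unname(ora$ys))
    expect_equal(ks$selected, unname(ora$selected))
  }

  # without replicate error the adjustment is skipped and flagged
  ks_na <- kang_ys(rand_matrix(5, 6, 1))
  expect_false(attr(ks_na, "adjusted"))
  expect_true(all(ks_na$rank_adjustment == 0L))
})

test_that("the genotype-level report is internally consistent", {
  sim <- simulate_trial(sim_config(seed = 71))
  pl <- derive_traits(sim$plots)
  sr <- stability_report(pl, sim$genotypes)
  g <- sr$genotype
  expect_equal(nrow(g), 23L)
  expect_true(all(g$pi >= 0))
  expect_true(all(g$w2 >= 0))
  # genotype-count-weighted mean of combination slope summaries is exactly 1
  summ <- sr$ac_summary
  expect_equal(sum(summ$b * summ$n_genotypes) / sum(summ$n_genotypes), 1,
               tolerance = 1e-9)
  # combination summaries are the plain means of their members' indices
  for (a in summ$allele_combination) {
    members <- g[g$allele_combination == a, ]
    for (cc in c("mean", "b", "pi", "sigma2", "w2", "ys"))
      expect_equal(summ[[cc]][summ$allele_combination == a],
                   mean(members[[cc]]), tolerance = 1e-12)
  }
  # the direct combination-matrix variant is present and complete
  expect_equal(nrow(sr$ac_matrix), 5L)
  expect_equal(mean(sr$ac_matrix$b), 1, tolerance = 1e-9)
})

test_that("the noisiest entity wins the interaction indices", {
  # one genotype with double the interaction variance has the largest W2 and
  # sigma2 in nearly all replicates
  hits <- 0L
  n_rep <- 100L
  for (r in seq_len(n_rep)) {
    set.seed(500 + r)
    # detection of a single double-variance genotype needs many environments:
    # measured top-rank rates ~0.79 (q=25), ~0.95 (q=60), ~0.995 (q=100)
    p <- 8; q <- 100
    ge <- matrix(rnorm(p * q, 0, 10), p, q)
    ge[3, ] <- rnorm(q, 0, 10 * sqrt(2))   # double interaction variance
    m <- outer(rnorm(p, 500, 30), rep(1, q)) +
      outer(rep(1, p), rnorm(q, 0, 50)) + ge
    rownames(m) <- paste0("e", 1:p)
    w2 <- wricke_ecovalence(m)
    sig <- shukla_sigma2(m)$sigma2
    if (which.max(w2) == 3 && which.max(sig) == 3) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})
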