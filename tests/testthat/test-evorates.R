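test_that("NG86 site and difference counting matches hand computation", {
  # TTT (Phe): only the third-position T->C change is synonymous, so
  # S = 1/3 and N = 8/3; TTT vs TTC is one synonymous difference
  r <- ng86_dnds(c(a = "TTT", b = "TTC"))
  expect_equal(r$dn, 0)
  tb <- floranet:::ng86_tables()
  expect_equal(unname(tb$syn_sites["TTT"]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(tb$syn_sites["TTC"]), 1 / 3, tolerance = 1e-12)
  expect_equal(tb$nd["TTT", "TTC"], 0)
  expect_equal(tb$sd["TTT", "TTC"], 1)

  # the lone synonymous difference saturates the tiny alignment's JC
  # correction for dS, which is therefore undefined
  expect_true(is.na(r$ds))
  expect_equal(r$flag, "undefined")

  # identical sequences: no differences, omega undefined
  r2 <- ng86_dnds(c(a = "ATGGCT", b = "ATGGCT"))
  expect_equal(r2$dn, 0)
  expect_equal(r2$ds, 0)
  expect_true(is.na(r2$omega))
  expect_equal(r2$flag, "zero_ds")

  # errors: frame and stops
  expect_error(ng86_dnds(c(a = "ATGG", b = "ATGG")), "divisible")
  expect_error(ng86_dnds(c(ok = "ATGGCT", bad = "ATGTAA")), "bad")
  expect_error(ng86_dnds(c(a = "ATG")), "2 sequences")
})

test_that("NG86 sites partition into S + N = 3 per codon and order-invariance", {
  tb <- floranet:::ng86_tables()
  expect_true(all(tb$syn_sites >= 0 & tb$syn_sites <= 3))
  # S + N = 3 per codon is built in: check via a pair computation
  tr <- simulate_phylogeny(6, seed = 1)
  aln <- simulate_codon_alignments(tr, codon_sim_spec(0.5, n_codons = 40),
                                   1, seed = 2)[[1]]
  r <- ng86_dnds(aln)
  expect_equal(r$n_pairs, choose(6, 2))

  # permuting sequence order changes nothing
  r_perm <- ng86_dnds(aln[c(3, 1, 6, 2, 4, 5)])
  expect_equal(r$dn, r_perm$dn, tolerance = 1e-12)
  expect_equal(r$ds, r_perm$ds, tolerance = 1e-12)

  # gapped codons are skipped pairwise
  aln_gap <- aln
  substr(aln_gap[1], 1, 3) <- "NNN"
  expect_silent(rg <- ng86_dnds(aln_gap))
  expect_equal(rg$flag, "ok")
})

test_that("NG86 recovers simulated omega within the counting-bias band", {
  tr <- simulate_phylogeny(12, seed = 1)
  alns <- simulate_codon_alignments(tr, codon_sim_spec(0.2), 50, seed = 20)
  r <- ng86_rates(alns)
  m <- mean(r$omega[r$flag == "ok"])
  expect_gte(m, 0.14)
  expect_lte(m, 0.28)
  expect_lte(abs(m / 0.2 - 1), 0.25)
})

test_that("rate filtering removes sentinels, invalid and non-positive rows", {
  tab <- tibble::tibble(
    orthogroup = sprintf("og%02d", 1:10),
    omega = c(999, 999, NA, 0.5, 0.2, 1.1, 0.8, 0.3, 0.6, 0.4),
    flag = c("ok", "ok", "zero_ds", rep("ok", 7)),
    k_total = c(1, 1, 1, 2, 3, 4, 5, 6, 0, 2),
    mean_expr = rep(5, 10)
  )
  out <- filter_rates(tab)
  expect_equal(nrow(out), 6) # 2 sentinels, 1 invalid, 1 zero connectivity
  expect_false(any(out$omega == 999))
  rm <- attr(out, "removed")
  expect_equal(unname(rm["sentinel"]), 2)
  expect_equal(unname(rm["total"]), 4)

  # dS = 0 rows (flag zero_ds, omega NA) are always removed
  expect_false("og03" %in% out$orthogroup)
})

test_that("OLS core matches the normal-equations oracle", {
  set.seed(1)
  tab <- tibble::tibble(
    omega = exp(rnorm(10)), k_total = exp(rnorm(10)),
    mean_expr = exp(rnorm(10))
  )
  tab <- dplyr::bind_rows(tab, tab, tab) # 30 rows to pass the size gate
  fit <- rates_vs_connectivity_lm(tab, n_boot = 0, seed = 1)
  lk <- log(tab$k_total); le <- log(tab$mean_expr)
  X <- cbind(1, lk, le, lk * le)
  oracle <- ols_normal_equations(X, log(tab$omega))
  expect_equal(unname(fit$coefficients$estimate), unname(oracle),
               tolerance = 1e-8)

  # n_boot = 0 degrades gracefully to point estimates with empty CIs
  expect_true(all(is.na(fit$coefficients$ci_lo)))
  expect_equal(glance(fit)$n, 30)

  # collinear predictors are rejected
  tab2 <- tab; tab2$mean_expr <- tab2$k_total
  expect_error(rates_vs_connectivity_lm(tab2, n_boot = 0), "collinear")
})

test_that("a planted negative rate-connectivity slope is recovered", {
  set.seed(2)
  n <- 300
  log_k <- rnorm(n, 1, 0.8)
  log_om <- -0.5 * log_k + rnorm(n, 0, 0.4)
  tab <- tibble::tibble(omega = exp(log_om), k_total = exp(log_k),
                        mean_expr = exp(rnorm(n, 2, 0.5)))
  fit <- rates_vs_connectivity_lm(tab, n_boot = 400, seed = 3)
  co <- tidy(fit)
  sl <- co[co$term == "log_k", ]
  expect_lt(sl$estimate, 0)
  expect_lt(sl$ci_hi, 0)
  # bootstrap intervals contain the point estimates
  expect_true(all(co$ci_lo <= co$estimate & co$estimate <= co$ci_hi))
  # reproducible given seed
  fit2 <- rates_vs_connectivity_lm(tab, n_boot = 400, seed = 3)
  expect_identical(tidy(fit), tidy(fit2))
})

test_that("the interaction term is calibrated under independence", {
  false_pos <- 0
  n_sim <- 60
  for (i in seq_len(n_sim)) {
    set.seed(1000 + i)
    n <- 200
    tab <- tibble::tibble(omega = exp(rnorm(n)), k_total = exp(rnorm(n)),
                          mean_expr = exp(rnorm(n)))
    fit <- rates_vs_connectivity_lm(tab, n_boot = 200, seed = i)
    co <- tidy(fit)
    ia <- co[co$term == "log_k:log_expr", ]
    if (ia$ci_lo > 0 || ia$ci_hi < 0) false_pos <- false_pos + 1
  }
  expect_lte(false_pos / n_sim, 0.10 + 0.05)
})

test_that("permutation t-test: null band, power, and hand-checked Cohen's d", {
  # group and background holding the identical multiset of values (shuffled):
  # the observed t is exactly 0, so the directional p sits near 0.5
  ok <- 0
  for (i in 1:20) {
    set.seed(i)
    vals <- exp(rnorm(30))
    r <- group_rate_permutation_test(sample(vals), vals, "less",
                                     n_perm = 400, seed = i)
    if (r$p_value >= 0.4) ok <- ok + 1
  }
  expect_gte(ok / 20, 0.95)

  # strong planted shift: decisive p at the permutation floor
  set.seed(4)
  g <- exp(rnorm(100, -1, 0.3)); b <- exp(rnorm(100, 0, 0.3))
  r2 <- group_rate_permutation_test(g, b, "less", n_perm = 2000, seed = 5)
  expect_lte(r2$p_value, 0.001)
  expect_lt(r2$cohens_d, 0)

  # hand case: log-groups {1..5} vs {3..7}, mean diff -2, pooled SD
  # sqrt(2.5) -> d = -2 / 1.5811 = -1.2649; Welch df = 8
  r3 <- group_rate_permutation_test(exp(1:5), exp(3:7), "less",
                                    n_perm = 200, seed = 1)
  expect_equal(r3$mean_difference, -2, tolerance = 1e-12)
  expect_equal(r3$cohens_d, -2 / sqrt(2.5), tolerance = 1e-12)
  expect_equal(r3$df, 8, tolerance = 1e-9)

  expect_error(group_rate_permutation_test(exp(1:3), exp(1:6), "less"),
               ">= 5")
})

test_that("syndrome rate model uses 'none' as reference and finds effects", {
  set.seed(6)
  n <- 500
  assoc <- sample(c("none", "bee", "hummingbird"), n, TRUE,
                  prob = c(0.6, 0.2, 0.2))
  log_om <- rnorm(n, 0, 0.4) + ifelse(assoc == "bee", log(0.8), 0)
  tab <- tibble::tibble(omega = exp(log_om), syndrome_assoc = assoc)
  fit <- syndrome_rate_lm(tab, n_boot = 400, seed = 7)
  expect_equal(fit$reference_level, "none")
  co <- tidy(fit)
  bee <- co[co$term == "bee", ]
  expect_lt(bee$estimate, 0)
  expect_lt(bee$ci_hi, 0)

  # null calibration per level
  fp <- 0; n_sim <- 40
  for (i in seq_len(n_sim)) {
    set.seed(2000 + i)
    tab0 <- tibble::tibble(omega = exp(rnorm(200)),
                           syndrome_assoc = sample(c("none", "bee"), 200, TRUE))
    f0 <- syndrome_rate_lm(tab0, n_boot = 200, seed = i)
    c0 <- tidy(f0)
    b0 <- c0[c0$term == "bee", ]
    if (b0$ci_lo > 0 || b0$ci_hi < 0) fp <- fp + 1
  }
  expect_lte(fp / n_sim, 0.10 + 0.075)

  expect_error(syndrome_rate_lm(tibble::tibble(omega = exp(rnorm(10)),
                                               syndrome_assoc = "none"),
                                n_boot = 0), "2 syndrome")
})
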