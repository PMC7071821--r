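test_that("module eigengenes: rank-1 case, sign rule, variance explained", {
  set.seed(1)
  n_s <- 12
  x <- matrix(rnorm(5 * n_s), 5, n_s,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:n_s)))
  part <- tibble::tibble(gene = rownames(x), module = 1L)

  # single-gene module: eigengene is that gene's standardized profile
  part1 <- tibble::tibble(gene = "g1", module = 1L)
  eig1 <- module_eigengenes(x["g1", , drop = FALSE], part1)
  expect_equal(as.numeric(eig1$values["ME1", ]),
               as.numeric(scale(x["g1", ])), tolerance = 1e-10)
  expect_equal(unname(eig1$var_explained["ME1"]), 1)

  # flipping the sign of every gene leaves the eigengene magnitude unchanged
  # and the orientation rule resolves the sign deterministically
  eig <- module_eigengenes(x, part)
  eig_f <- module_eigengenes(-x, part)
  expect_equal(abs(eig$values["ME1", ]), abs(eig_f$values["ME1", ]),
               tolerance = 1e-10)
  z <- t(scale(t(x)))
  expect_gte(stats::cor(as.numeric(eig$values["ME1", ]), colMeans(z)), 0)

  # variance explained matches an independent full SVD
  set.seed(2)
  x2 <- matrix(rnorm(30 * n_s), 30, n_s,
               dimnames = list(paste0("h", 1:30), paste0("s", 1:n_s)))
  part2 <- tibble::tibble(gene = rownames(x2), module = 1L)
  eig2 <- module_eigengenes(x2, part2)
  d <- svd(t(scale(t(x2))))$d
  expect_equal(unname(eig2$var_explained["ME1"]), d[1]^2 / sum(d^2),
               tolerance = 1e-10)

  # eigengenes have unit variance across samples
  expect_equal(stats::sd(eig2$values["ME1", ]), 1, tolerance = 1e-10)

  # constant gene is an error naming the module
  x3 <- rbind(x2, const = rep(1, n_s))
  part3 <- tibble::tibble(gene = rownames(x3), module = 2L)
  expect_error(module_eigengenes(x3, part3), "ME2")
})

test_that("eigengene explains at least as much variance as any member gene", {
  sim <- quick_sim(seed = 21, n_modules = 1, module_size = 20, n_background = 0)
  x <- sim$log_values$Bud
  part <- tibble::tibble(gene = rownames(x), module = 1L)
  eig <- module_eigengenes(x, part)
  z <- t(scale(t(x)))
  total <- sum(svd(z)$d^2)
  # the first principal axis maximizes projected variance over unit vectors,
  # so no single standardized gene profile can explain more
  for (g in seq_len(nrow(z))) {
    p <- z[g, ] / sqrt(sum(z[g, ]^2))
    ve_gene <- sum((z %*% p)^2) / total
    expect_gte(eig$var_explained[["ME1"]] + 1e-10, ve_gene)
  }
})

test_that("kME is the gene-eigengene Pearson correlation for all modules", {
  set.seed(3)
  x <- matrix(rnorm(20 * 12), 20, 12,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:12)))
  part <- tibble::tibble(gene = rownames(x),
                         module = rep(c(1L, 2L), each = 10))
  eig <- module_eigengenes(x, part)
  kme <- compute_kme(x, eig)
  oracle <- stats::cor(t(x), t(eig$values))
  expect_equal(kme, oracle, tolerance = 1e-12)

  # gene proportional to its eigengene has kME 1; negated, -1
  e <- eig$values["ME1", ]
  x2 <- rbind(x, pos = 2 * e + 5, neg = -e)
  eig2 <- module_eigengenes(x2[1:20, ], part)
  kme2 <- compute_kme(x2, eig2)
  expect_equal(unname(kme2["pos", "ME1"]), 1, tolerance = 1e-12)
  expect_equal(unname(kme2["neg", "ME1"]), -1, tolerance = 1e-12)
})

test_that("connectivity splits into within and out by module co-membership", {
  # complete unit graph: k_total = n - 1
  n <- 6
  a <- matrix(1, n, n, dimnames = list(paste0("g", 1:n), paste0("g", 1:n)))
  part <- tibble::tibble(gene = paste0("g", 1:n),
                         module = c(1L, 1L, 1L, 2L, 2L, 0L))
  conn <- compute_connectivity(a, part)
  expect_equal(conn$k_total, rep(n - 1, n))
  expect_equal(conn$k_within[1], 2) # two other module-1 members
  expect_equal(conn$k_within[6], 0) # sole module-0 member

  # random adjacency: k_within + k_out = k_total exactly
  set.seed(4)
  r <- matrix(runif(100), 10, 10)
  adj <- (r + t(r)) / 2; diag(adj) <- 1
  dimnames(adj) <- list(paste0("g", 1:10), paste0("g", 1:10))
  part2 <- tibble::tibble(gene = paste0("g", 1:10),
                          module = sample(0:2, 10, replace = TRUE))
  conn2 <- compute_connectivity(adj, part2)
  expect_equal(conn2$k_within + conn2$k_out, conn2$k_total)
})

test_that("hub and periphery calls use strict thresholds and floor sizes", {
  n <- 20
  genes <- sprintf("g%02d", 1:n)
  conn <- tibble::tibble(gene = genes, module = rep(1:2, each = 10),
                         k_total = seq(0.5, 10, length.out = n),
                         k_within = 0, k_out = 0)
  kme <- matrix(0.5, n, 2, dimnames = list(genes, c("ME1", "ME2")))
  kme[1, "ME1"] <- 0.90        # exactly at the threshold: NOT a hub
  kme[2, "ME1"] <- 0.900001    # just above: hub
  roles <- call_hubs_periphery(kme, conn)
  expect_false(roles$is_hub[1])
  expect_true(roles$is_hub[2])

  # floor(0.1 * 20) = 2 periphery calls, lowest connectivity, stable ties
  expect_equal(sum(roles$is_periphery), 2)
  expect_true(all(roles$is_periphery[1:2]))
  expect_equal(attr(roles, "periphery_cutoff"), sort(conn$k_total)[2])

  # genes in module 0 can never be hubs
  conn0 <- conn; conn0$module[2] <- 0L
  kme0 <- cbind(kme, ME0 = 0.99)
  roles0 <- call_hubs_periphery(kme0, conn0)
  expect_false(roles0$is_hub[2])

  # periphery counts include unassigned genes
  expect_equal(sum(call_hubs_periphery(kme0, conn0)$is_periphery), 2)
})

test_that("Fisher overlap p-values match full margin enumeration", {
  # spec-style table (5, 1, 1, 13) plus exhaustive small-margin scan
  cases <- list(c(5, 1, 1, 13))
  set.seed(5)
  for (i in 1:40) cases[[i + 1]] <- sample(0:12, 4, replace = TRUE)
  for (cs in cases) {
    if (sum(cs) == 0) next
    got <- floranet:::overlap_fisher_cell(cs[1], cs[2], cs[3], cs[4])$p
    expect_equal(got, fisher_enum_p(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-9)
  }
})

test_that("module overlap table counts and odds ratios behave", {
  genes <- sprintf("g%03d", 1:60)
  pa <- tibble::tibble(gene = genes, module = rep(1:3, each = 20))
  # identical partitions: diagonal counts equal module sizes
  ov <- module_overlap_fisher(pa, pa)
  diag_rows <- ov[ov$module_a == ov$module_b, ]
  expect_equal(diag_rows$n_both, rep(20, 3))
  off_rows <- ov[ov$module_a != ov$module_b, ]
  expect_true(all(off_rows$n_both == 0))

  # universes must match
  pb <- pa; pb$gene[1] <- "zzz"
  expect_error(module_overlap_fisher(pa, pb), "universe")

  # independent random partitions: median sample OR in a sane band
  set.seed(6)
  genes2 <- sprintf("h%04d", 1:1000)
  pa2 <- tibble::tibble(gene = genes2, module = sample(1:5, 1000, TRUE))
  pb2 <- tibble::tibble(gene = genes2, module = sample(1:5, 1000, TRUE))
  ov2 <- module_overlap_fisher(pa2, pb2)
  expect_gt(stats::median(ov2$odds_ratio_sample), 0.5)
  expect_lt(stats::median(ov2$odds_ratio_sample), 2)

  # arbitrary gene sets (hub-overlap style)
  gs <- gene_set_fisher(genes[1:10], genes[6:20], genes)
  expect_equal(gs$n_both, 5)
  expect_equal(gs$n_both + gs$n_a_only + gs$n_b_only + gs$n_neither, 60)
})
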