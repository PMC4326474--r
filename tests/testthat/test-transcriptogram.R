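ord5 <- gene_ordering(paste0("g", 1:5))

test_that("box-car windows average with truncation and coverage mask", {
  v <- setNames(c(1, 2, 3, 4, 5), paste0("g", 1:5))
  # r = 0 is the transcriptome laid out along the list
  expect_equal(boxcar_profile(v, ord5, 0)$value, c(1, 2, 3, 4, 5))
  # r = 1 with truncated end windows
  expect_equal(boxcar_profile(v, ord5, 1)$value, c(1.5, 2, 3, 4, 4.5))
  # constant input stays constant under any mask with some coverage
  expect_equal(boxcar_profile(setNames(rep(7, 5), paste0("g", 1:5)), ord5, 2)$value,
               rep(7, 5))
  # theta-weighted mean over a gap: (2, -, 4) at r = 1 gives 3 in the middle
  v3 <- setNames(c(2, 4), c("g1", "g3"))
  ord3 <- gene_ordering(paste0("g", 1:3))
  p <- boxcar_profile(v3, ord3, 1)
  expect_equal(p$theta, c(1L, 0L, 1L))
  expect_equal(p$value[2], 3)
  expect_error(boxcar_profile(v, ord5, -1), class = "xgram_bad_radius")
  expect_error(boxcar_profile(setNames(1, "absent"), ord5, 1),
               class = "xgram_no_overlap")
})

test_that("fully uncovered windows are missing, not zero", {
  v <- setNames(c(1, 5), c("g1", "g5"))
  p <- boxcar_profile(v, ord5, 1)
  expect_true(is.na(p$value[3]))
  expect_equal(p$value[c(1, 5)], c(1, 5))
})

test_that("box-car smoothing is linear and mean-preserving in the interior", {
  set.seed(12)
  n <- 200
  ordn <- gene_ordering(sprintf("G%03d", 1:n))
  x <- setNames(rnorm(n), sprintf("G%03d", 1:n))
  y <- setNames(rnorm(n), sprintf("G%03d", 1:n))
  r <- 7
  bx <- boxcar_profile(x, ordn, r)$value
  by <- boxcar_profile(y, ordn, r)$value
  bxy <- boxcar_profile(2 * x + 3 * y, ordn, r)$value
  expect_equal(bxy, 2 * bx + 3 * by)
  # interior positions: smoothing redistributes but preserves the mean of
  # the contributing values exactly (full coverage, no truncation)
  interior <- (r + 1):(n - r)
  expect_equal(mean(bx[interior]),
               mean(sapply(interior, function(i) mean(x[(i - r):(i + r)]))))
})

test_that("class profiles average smoothed replicates with SD and SE", {
  genes <- sprintf("G%03d", 1:60)
  ordn <- gene_ordering(genes)
  base <- sin(seq(0, 3, length.out = 60))
  ex <- tibble::tibble(gene = genes, s1 = base, s2 = base, s3 = base + 0.3)
  des <- tibble::tibble(sample = c("s1", "s2", "s3"), condition = "A",
                        bio_rep = 1:3, tech_rep = 1L)
  cp <- class_profiles(ex, des, ordn, r = 2)
  expect_equal(cp$mean, boxcar_profile(setNames(base + 0.1, genes), ordn, 2)$value)
  expect_equal(cp$se, cp$sd / sqrt(3))
  # identical replicates have zero SD
  cp2 <- class_profiles(ex[c("gene", "s1", "s2")],
                        des[1:2, ], ordn, r = 2)
  expect_equal(max(cp2$sd), 0)
  expect_error(class_profiles(ex, des, ordn, 2, conditions = "missing"),
               class = "xgram_invalid_design")
})

test_that("technical-replicate SD shrinks like the window size square root", {
  pl <- make_planted_network(4, 100, 0.5, 0.01, seed = 8)
  sim <- make_expression(pl$labels, conditions = "A", n_b = 1, n_a = 6,
                         sigma_b = 0, sigma_xi = 0.5, seed = 8)
  ordn <- gene_ordering(sort(pl$labels$gene))
  r <- 10
  cp <- class_profiles(sim$expression, sim$design, ordn, r = r)
  interior <- (r + 1):(400 - r)
  expect_equal(mean(cp$sd[interior]), 0.5 / sqrt(2 * r + 1), tolerance = 0.15)
})

test_that("relative profiles are position-wise ratios against the reference class", {
  genes <- sprintf("G%03d", 1:30)
  ordn <- gene_ordering(genes)
  # two constant biological replicates a = 4 and b = 6
  ex <- tibble::tibble(gene = genes,
                       r1t1 = 4, r1t2 = 4, r2t1 = 6, r2t2 = 6)
  des <- tibble::tibble(sample = c("r1t1", "r1t2", "r2t1", "r2t2"),
                        condition = "F", bio_rep = c(1, 1, 2, 2),
                        tech_rep = c(1, 2, 1, 2))
  rel <- relative_profile(ex, des, ordn, r = 3, reference = "F")
  expect_equal(unique(rel$value[rel$bio_rep == 1]), 2 * 4 / (4 + 6))
  expect_equal(unique(rel$value[rel$bio_rep == 2]), 2 * 6 / (4 + 6))
  # the reference class relative to itself averages to 1
  expect_equal(mean(tapply(rel$value, rel$position, mean)), 1)

  # zero reference flagged missing, not divided
  ex0 <- tibble::tibble(gene = genes, s1 = 0, s2 = 0)
  des0 <- tibble::tibble(sample = c("s1", "s2"), condition = "Z",
                         bio_rep = 1:2, tech_rep = 1L)
  rel0 <- relative_profile(ex0, des0, ordn, r = 0, reference = "Z")
  expect_true(all(is.na(rel0$value)))
})

test_that("gene-set projection smooths the membership indicator", {
  ordn <- gene_ordering(paste0("g", 1:9))
  # full set: profile is 1 everywhere
  expect_equal(project_gene_set(paste0("g", 1:9), ordn, 2)$value, rep(1, 9))
  # empty overlap: 0 everywhere (and a note)
  expect_message(p0 <- project_gene_set("nope", ordn, 2))
  expect_equal(p0$value, rep(0, 9))
  # single member at an interior position spreads 1/3 over its window
  p1 <- project_gene_set("g5", ordn, 1)
  expect_equal(p1$value, c(0, 0, 0, 1/3, 1/3, 1/3, 0, 0, 0))
  expect_true(all(p1$value >= 0 & p1$value <= 1))
  # indicator total equals members present in the ordering
  expect_equal(sum(project_gene_set(c("g2", "g7", "zzz"), ordn, 3)$indicator), 2)
})

test_that("variance decomposition has exact degenerate behavior", {
  genes <- sprintf("G%03d", 1:20)
  ordn <- gene_ordering(genes)
  des <- tidyr::expand_grid(condition = "A", bio_rep = 1:3, tech_rep = 1:2)
  des$sample <- sprintf("b%dt%d", des$bio_rep, des$tech_rep)
  # identical technical replicates within each bio rep: sigma2_xi = 0
  set.seed(1)
  bio_vals <- matrix(rnorm(20 * 3), 20, 3)
  ex <- tibble::tibble(gene = genes)
  for (i in seq_len(nrow(des)))
    ex[[des$sample[i]]] <- 5 + bio_vals[, des$bio_rep[i]]
  vc <- decompose_variance(ex, des, ordn, r = 3)
  expect_equal(max(vc$genes$sigma2_xi), 0)
  expect_true(all(vc$genes$sigma2_b > 0))
  # all samples identical: everything is 0
  ex2 <- ex; for (s in des$sample) ex2[[s]] <- 5
  vc2 <- decompose_variance(ex2, des, ordn, r = 3)
  expect_equal(max(vc2$genes$sigma2_xi), 0)
  expect_equal(max(vc2$genes$sigma2_b), 0)
  # insufficient replication is named
  expect_error(decompose_variance(ex[c("gene", "b1t1", "b2t1", "b3t1")],
                                  des[des$tech_rep == 1, ], ordn, 3),
               class = "xgram_insufficient_replication")
})

test_that("correlated biology does not shrink with the window; independent does", {
  pl <- make_planted_network(4, 100, 0.5, 0.01, seed = 15)
  ordn <- gene_ordering(sort(pl$labels$gene))
  r <- 20
  sds <- sapply(c(0, 1), function(rho) {
    sim <- make_expression(pl$labels, conditions = "A", n_b = 8, n_a = 1,
                           sigma_b = 0.4, sigma_xi = 0.05, rho_bio = rho,
                           seed = 16)
    cp <- class_profiles(sim$expression, sim$design, ordn, r = r)
    mean(cp$sd[(r + 1):(400 - r)])
  })
  # rho 0: biological SD shrinks ~ sqrt(w); rho 1: cluster-wide drifts persist
  expect_lt(sds[1], 0.4 / sqrt(2 * r + 1) * 2)
  expect_gt(sds[2], 5 * sds[1])
})
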