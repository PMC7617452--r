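test_that("site panel filter applies strict MQ and AN gates", {
  G <- matrix(1L, nrow = 83, ncol = 4)          # 83 diploids, AN = 166 when full
  G[9:83, 2] <- NA                              # site 2: AN = 16
  G[76:83, 3] <- NA                             # site 3: AN = 150 exactly
  sites <- data.frame(chrom = "c", pos = 1:4, ref = "A",
                      alt = c("C", "C", "C", "A"),
                      mq = c(21, 60, 60, 60), an = NA,
                      is_transversion = TRUE)
  gp <- structure(list(sites = sites, genotypes = G), class = "genotype_panel")

  out <- filter_site_panel(gp)
  expect_identical(out$sites$pos, 1L)            # only site 1 survives
  expect_identical(out$sites$an, 166L)

  # MQ exactly 20 is removed (strict), AN exactly 150 is removed, 152 kept
  sites$mq[1] <- 20
  gp$sites <- sites
  G[76, 3] <- 1L                                 # site 3: AN = 152
  gp$genotypes <- G
  out2 <- filter_site_panel(gp)
  expect_identical(out2$sites$pos, 3L)
  expect_identical(unname(attr(out2, "removed")["an"]), 1L)

  # all sites passing is the identity
  ok <- structure(list(sites = data.frame(chrom = "c", pos = 1:2, ref = "A",
                                          alt = "T", mq = 60, an = NA,
                                          is_transversion = TRUE),
                       genotypes = matrix(1L, 80, 2)), class = "genotype_panel")
  expect_identical(filter_site_panel(ok)$sites$pos, 1:2)
})

test_that("pseudo-haploid calling follows mode and allele constraints", {
  sites <- data.frame(pos = c(10L, 20L, 30L, 40L), ref = "A", alt = "T")
  pile <- list(`10` = "T", `20` = c("A", "T"), `30` = character(0), `40` = "G")

  single <- pseudo_haploid_call(pile, sites, "single_read_only", seed = 1)
  expect_identical(as.integer(single), c(1L, NA, NA, NA))  # two reads -> missing,
  # zero reads -> missing, third allele -> missing

  rand <- pseudo_haploid_call(pile, sites, "random_read", seed = 1)
  expect_identical(as.integer(rand)[1], 1L)
  expect_true(as.integer(rand)[2] %in% 0:1)

  # determinism per seed
  expect_identical(as.integer(pseudo_haploid_call(pile, sites, "random_read", seed = 9)),
                   as.integer(pseudo_haploid_call(pile, sites, "random_read", seed = 9)))

  expect_error(pseudo_haploid_call(list(`99` = "A"), sites, "random_read", 1),
               "absent")
})

test_that("Hamming distances rescale missingness per the flat formula", {
  G <- rbind(s1 = c(0, 1, 2, 0, 2, 1, 0, 1, 2, 0),
             s2 = c(0, 1, 2, 0, 2, 1, 0, 1, 2, 0),
             s3 = c(2, 1, 0, 2, 0, NA, NA, NA, NA, NA))
  hd <- hamming_distance_matrix(G)
  expect_identical(hd$dist["s1", "s2"], 0)                 # identical samples
  # s1 vs s3: raw 2+0+2+2+2 = 8 over 5 observed of 10 -> rescaled 16
  expect_identical(hd$nobs["s1", "s3"], 5L)
  expect_identical(hd$dist["s1", "s3"], 16)
  # no missing data: rescaled equals raw
  raw <- hamming_distance_matrix(G[1:2, ], rescale_missing = FALSE)
  expect_identical(raw$dist, hamming_distance_matrix(G[1:2, ])$dist)

  # naive double-loop oracle on random matrices with missingness
  withr::with_seed(161, {
    for (i in 1:5) {
      M <- matrix(sample(c(0:2, NA), 60, replace = TRUE), nrow = 5)
      rownames(M) <- paste0("x", 1:5)
      expect_equal(unname(hamming_distance_matrix(M)$dist), naive_hamming(M))
    }
  })

  # zero joint observations: explicit undefined status
  B <- rbind(a = c(1, NA), b = c(NA, 1), c = c(1, 1))
  hdb <- hamming_distance_matrix(B)
  expect_true(is.na(hdb$dist["a", "b"]))
  expect_identical(hdb$undefined_pairs, "a:b")
})

test_that("rescaled Hamming distance is unbiased under MCAR thinning", {
  withr::with_seed(163, {
    G <- matrix(sample(0:2, 400, replace = TRUE, prob = c(.5, .3, .2)), nrow = 2)
    full <- hamming_distance_matrix(G)$dist[1, 2]
    est <- replicate(200, {
      H <- G
      H[2, runif(ncol(G)) < 0.6] <- NA
      hamming_distance_matrix(H)$dist[1, 2]
    })
    se <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - full), 3 * se)
  })
})

test_that("neighbor joining recovers additive trees and matches ape", {
  # 3 taxa: closed-form branch lengths
  D3 <- matrix(c(0, 5, 9, 5, 0, 8, 9, 8, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- neighbor_joining(D3)
  el <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(el[["A"]], (5 + 9 - 8) / 2)
  expect_equal(el[["B"]], (5 + 8 - 9) / 2)
  expect_equal(el[["C"]], (9 + 8 - 5) / 2)

  # additive 4-taxon matrix: exact topology and branch lengths recovered
  tr <- ape::read.tree(text = "((A:2,B:3):1,(C:4,D:5):2);")
  D4 <- ape::cophenetic.phylo(tr)
  t4 <- neighbor_joining(D4)
  expect_equal(ape::cophenetic.phylo(t4)[rownames(D4), colnames(D4)], D4)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), t4)), 0)

  # permutation invariance of the unrooted topology
  perm <- c(3, 1, 4, 2)
  t4p <- neighbor_joining(D4[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(t4, t4p)), 0)

  # oracle equivalence against ape::nj on random additive matrices
  withr::with_seed(171, {
    for (i in 1:10) {
      rt <- ape::rtree(sample(5:9, 1))
      D <- ape::cophenetic.phylo(rt)
      mine <- neighbor_joining(D)
      ref <- ape::nj(D)
      expect_equal(as.numeric(ape::dist.topo(mine, ref)), 0)
      expect_equal(ape::cophenetic.phylo(mine)[rownames(D), colnames(D)], D,
                   tolerance = 1e-6)
    }
  })

  expect_error(neighbor_joining(matrix(NA_real_, 3, 3)), "undefined")
})

test_that("PCA projection reproduces fitted scores for complete samples", {
  p <- simulate_multilocus_panel(20, 8, 2, 0.6, 8, seed = 181)
  G <- panel_genotypes(p)
  fit <- pca_fit_project(G[-1, , drop = FALSE],
                         list(self = G[1, ]), k = 2)
  # held-in complete sample: projection equals its fitted score
  refit <- pca_fit_project(G[-1, , drop = FALSE], list(), k = 2)
  expect_equal(unname(fit$model$scores), unname(refit$model$scores))
  full_in <- pca_fit_project(G[-1, , drop = FALSE],
                             list(s2 = G[2, ]), k = 2)
  expect_equal(unname(full_in$projections[1, ]),
               unname(full_in$model$scores[1, ]), tolerance = 1e-8)

  # loadings orthonormal, eigenvalues nonincreasing
  V <- fit$model$loadings
  expect_equal(crossprod(V), diag(2), tolerance = 1e-8)
  expect_true(diff(fit$model$eigenvalues) <= 0)

  # all-missing ancient vector is an error
  allna <- rep(NA_real_, ncol(G))
  expect_error(pca_fit_project(G[-1, ], list(bad = allna), k = 2), "missing")
})

test_that("f4 algebraic identities hold exactly", {
  withr::with_seed(191, {
    fr <- matrix(runif(4 * 300), ncol = 4,
                 dimnames = list(NULL, c("A", "B", "C", "D")))
  })
  fr2 <- cbind(fr, A2 = fr[, "A"])
  # f4(A,A;C,D) = 0 exactly
  expect_identical(f4_statistic(fr2, c("A", "A2", "C", "D"), 50)$estimate, 0)
  # antisymmetry
  expect_identical(f4_statistic(fr, c("A", "B", "C", "D"), 50)$estimate,
                   -f4_statistic(fr, c("B", "A", "C", "D"), 50)$estimate)
  # single site p = (1,0,1,0) -> estimate 1
  one <- matrix(c(1, 0, 1, 0), 1, dimnames = list(NULL, c("A", "B", "C", "D")))
  expect_identical(f4_statistic(one, c("A", "B", "C", "D"))$estimate, 1)
  # estimate invariant to site order; SE changes only via block composition
  perm <- rev(seq_len(nrow(fr)))
  a <- f4_statistic(fr, c("A", "B", "C", "D"), 50)
  b <- f4_statistic(fr[perm, ], c("A", "B", "C", "D"), 50)
  expect_equal(a$estimate, b$estimate)
  # NA rows are excluded from usable sites
  frna <- fr; frna[1:10, "C"] <- NA
  expect_identical(f4_statistic(frna, c("A", "B", "C", "D"), 50)$n_sites, 290L)
  expect_error(f4_statistic(frna[1:10, ], c("A", "B", "C", "D")), "usable")
})

test_that("weighted block jackknife reduces to the standard delete-one form", {
  withr::with_seed(193, {
    fr <- matrix(runif(4 * 200), ncol = 4,
                 dimnames = list(NULL, c("A", "B", "C", "D")))
  })
  d <- (fr[, 1] - fr[, 2]) * (fr[, 3] - fr[, 4])
  g <- 10
  block <- rep(1:g, each = 20)
  loo <- vapply(1:g, function(j) mean(d[block != j]), numeric(1))
  se_simple <- sqrt((g - 1) / g * sum((loo - mean(loo))^2))
  r <- f4_statistic(fr, c("A", "B", "C", "D"), block_size_snps = 20)
  expect_equal(r$se, se_simple, tolerance = 1e-12)
  expect_equal(r$z, r$estimate / r$se)
})

test_that("pseudo-haploid inflation is visible in self distances", {
  # a pseudo-haploid sample re-drawn from the same diploid individual has
  # positive distance to itself at heterozygous sites (documented, not hidden)
  p <- simulate_coalescent_panel(4, 1, 0, 40, seed = 195)
  G <- panel_genotypes(p)
  het <- G[1, ] == 1L
  expect_gte(sum(het), 5)
  withr::with_seed(196, {
    draw <- function() ifelse(G[1, ] == 1L, sample(c(0L, 2L), ncol(G), TRUE), G[1, ])
    M <- rbind(ph1 = draw(), ph2 = draw())
  })
  d <- hamming_distance_matrix(M)$dist["ph1", "ph2"]
  expect_gt(d, 0)
})
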