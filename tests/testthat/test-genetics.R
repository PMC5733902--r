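# Filtering, 0/1/2 encoding, Bray-Curtis distances, PCA, Weir-Cockerham
# Fst/Fis and rarefaction, each against an independent oracle where the spec
# provides one.

test_that("missing-loci filter removes only individuals exceeding the cap", {
  calls <- list(
    L1 = c("1/1", "",    "1/2", "1/1"),
    L2 = c("1/1", "",    "",    "1/1"),
    L3 = c("1/1", "",    "",    "1/2"),
    L4 = c("1/2", "1/1", "1/1", "2/2")
  )
  gt <- make_gt(calls)
  f <- suppressMessages(filter_individuals(gt, max_missing_loci = 2))
  # ind2 misses 3 loci -> removed; ind3 misses exactly 2 -> retained
  expect_setequal(f$meta$individual_id, c("ind01", "ind03", "ind04"))
  expect_equal(attr(f, "n_removed"), 1L)
  full <- make_gt(list(L1 = c("1/1", "1/2"), L2 = c("2/2", "1/2")))
  expect_identical(filter_individuals(full)$meta, full$meta)
})

test_that("drop_loci removes named loci and rejects unknown ones", {
  gt <- make_gt(list(Mon01 = c("1/1", "1/2"), Mon08 = c("2/2", "1/1"),
                     Mon27 = c("1/2", "1/1")))
  out <- drop_loci(gt, c("Mon01", "Mon27"))
  expect_equal(colnames(out$a1), "Mon08")
  expect_identical(drop_loci(gt, character(0)), gt)
  expect_error(drop_loci(gt, "MonXX"), "unknown loci")
})

test_that("0/1/2 encoding: homozygote, heterozygote, masked missing", {
  gt <- make_gt(list(L1 = c("120/120", "120/124", "")))
  am <- encode_alleles(gt)
  expect_equal(unname(am[1, ]), c(2, 0))   # homozygote 120/120
  expect_equal(unname(am[2, ]), c(1, 1))   # heterozygote 120/124
  expect_true(all(is.na(am[3, ])))         # missing locus masked
  expect_equal(colnames(am), c("L1.120", "L1.124"))
})

test_that("encoding row sums are exactly 2 per non-missing locus (property)", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 15; L <- 6
    calls <- lapply(seq_len(L), function(l) {
      a <- sample(100:110, 2 * n, replace = TRUE)
      cl <- paste0(a[seq_len(n)], "/", a[n + seq_len(n)])
      cl[sample(n, 2)] <- ""   # some missing
      cl
    })
    names(calls) <- paste0("L", seq_len(L))
    am <- encode_alleles(make_gt(calls))
    locus_of <- attr(am, "locus")
    for (l in unique(locus_of)) {
      rs <- rowSums(am[, locus_of == l, drop = FALSE])
      expect_true(all(rs[!is.na(rs)] == 2))
    }
  }
})

# Independent Bray-Curtis oracle on allele multisets: for each pair, over
# loci typed in both, d = 1 - 2*|intersection| / (|x| + |y|) with multiset
# intersection of the four allele copies.
bc_oracle <- function(gt) {
  n <- n_individuals(gt)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      inter <- tot <- 0
      for (l in seq_len(n_loci(gt))) {
        xi <- c(gt$a1[i, l], gt$a2[i, l]); yj <- c(gt$a1[j, l], gt$a2[j, l])
        if (anyNA(xi) || anyNA(yj)) next
        shared <- 0
        pool <- yj
        for (a in xi) {
          hit <- match(a, pool)
          if (!is.na(hit)) { shared <- shared + 1; pool <- pool[-hit] }
        }
        inter <- inter + shared
        tot <- tot + 4
      }
      d[i, j] <- d[j, i] <- 1 - 2 * inter / tot
    }
  }
  dimnames(d) <- list(gt$meta$individual_id, gt$meta$individual_id)
  d
}

test_that("Bray-Curtis matches hand values and the multiset oracle", {
  # identical genotypes -> 0; disjoint alleles everywhere -> 1
  gt0 <- make_gt(list(L1 = c("1/2", "1/2"), L2 = c("3/3", "3/3")))
  expect_equal(unname(bray_curtis(encode_alleles(gt0))[1, 2]), 0)
  gt1 <- make_gt(list(L1 = c("1/1", "2/2"), L2 = c("3/4", "5/6")))
  expect_equal(unname(bray_curtis(encode_alleles(gt1))[1, 2]), 1)
  # one locus, x = (2,0), y = (1,1) -> 0.5
  gt2 <- make_gt(list(L1 = c("120/120", "120/124")))
  expect_equal(unname(bray_curtis(encode_alleles(gt2))[1, 2]), 0.5)

  for (seed in 1:4) {
    set.seed(seed)
    n <- 10
    calls <- lapply(1:5, function(l) {
      a <- sample(1:6, 2 * n, replace = TRUE)
      cl <- paste0(a[seq_len(n)], "/", a[n + seq_len(n)])
      cl[sample(n, 1)] <- ""
      cl
    })
    names(calls) <- paste0("L", 1:5)
    gt <- make_gt(calls)
    expect_equal(bray_curtis(encode_alleles(gt)), bc_oracle(gt),
                 tolerance = 1e-12)
  }
})

test_that("Bray-Curtis agrees with vegan on complete data", {
  skip_if_not_installed("vegan")
  set.seed(9)
  n <- 12
  calls <- lapply(1:6, function(l) {
    a <- sample(1:5, 2 * n, replace = TRUE)
    paste0(a[seq_len(n)], "/", a[n + seq_len(n)])
  })
  names(calls) <- paste0("L", 1:6)
  am <- encode_alleles(make_gt(calls))
  ref <- as.matrix(vegan::vegdist(unclass(am), method = "bray"))
  ours <- bray_curtis(am)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
})

test_that("PCA conserves variance, duplicates coincide, clusters separate", {
  set.seed(4)
  n <- 12
  calls <- lapply(1:5, function(l) {
    a <- sample(1:4, 2 * n, replace = TRUE)
    paste0(a[seq_len(n)], "/", a[n + seq_len(n)])
  })
  names(calls) <- paste0("L", 1:5)
  gt <- make_gt(calls)
  gt$a1[2, ] <- gt$a1[1, ]; gt$a2[2, ] <- gt$a2[1, ]  # duplicate individual
  am <- encode_alleles(gt)
  p <- pca_scores(am, 3)
  expect_equal(p$scores[1, ], p$scores[2, ], tolerance = 1e-10)
  x <- unclass(am)
  total_var <- sum(apply(scale(x, scale = FALSE), 2, stats::var))
  expect_equal(sum(p$eigenvalues), total_var, tolerance = 1e-10 * total_var)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_warning(pca_scores(am, 100), "truncated")

  # two clusters with fully disjoint alleles: axis 1 separates completely
  cl <- make_gt(list(L1 = c(rep("1/2", 5), rep("8/9", 5)),
                     L2 = c(rep("1/1", 5), rep("9/9", 5))))
  s1 <- pca_scores(encode_alleles(cl), 1)$scores[, 1]
  expect_true(max(s1[1:5]) < min(s1[6:10]) || min(s1[1:5]) > max(s1[6:10]))
})

# Literal transcription of the two-deme variance-component estimator, scalar
# arithmetic per allele (the brute-force oracle).
theta_oracle <- function(gt, da, db) {
  ia <- gt$meta$deme_id == da; ib <- gt$meta$deme_id == db
  num <- den <- 0
  for (l in colnames(gt$a1)) {
    av <- c(gt$a1[ia | ib, l], gt$a2[ia | ib, l])
    alleles <- sort(unique(av[!is.na(av)]))
    if (length(alleles) < 2) next
    for (al in alleles) {
      ni <- c(sum(!is.na(gt$a1[ia, l])), sum(!is.na(gt$a1[ib, l])))
      pi_ <- c(
        (sum(gt$a1[ia, l] == al, na.rm = TRUE) + sum(gt$a2[ia, l] == al, na.rm = TRUE)) / (2 * ni[1]),
        (sum(gt$a1[ib, l] == al, na.rm = TRUE) + sum(gt$a2[ib, l] == al, na.rm = TRUE)) / (2 * ni[2])
      )
      hi <- c(
        sum((gt$a1[ia, l] == al | gt$a2[ia, l] == al) & gt$a1[ia, l] != gt$a2[ia, l], na.rm = TRUE) / ni[1],
        sum((gt$a1[ib, l] == al | gt$a2[ib, l] == al) & gt$a1[ib, l] != gt$a2[ib, l], na.rm = TRUE) / ni[2]
      )
      r <- 2
      nbar <- (ni[1] + ni[2]) / 2
      nC <- (r * nbar - (ni[1]^2 + ni[2]^2) / (r * nbar)) / (r - 1)
      pbar <- (ni[1] * pi_[1] + ni[2] * pi_[2]) / (r * nbar)
      s2 <- (ni[1] * (pi_[1] - pbar)^2 + ni[2] * (pi_[2] - pbar)^2) / ((r - 1) * nbar)
      hbar <- (ni[1] * hi[1] + ni[2] * hi[2]) / (r * nbar)
      a <- (nbar / nC) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  num / den
}

test_that("Weir-Cockerham Fst: limits, oracle equality, invariances", {
  # identical allele frequencies in two large demes -> ~ 0
  set.seed(5)
  pool <- rep(c(1L, 2L), each = 40)
  mk <- function(deme) {
    a <- sample(pool, 40)
    data.frame(id = paste0(deme, 1:20), deme = deme,
               a1 = a[1:20], a2 = a[21:40])
  }
  df <- rbind(mk("A"), mk("B"))
  gt_eq <- genotype_table(
    data.frame(individual_id = df$id, deme_id = df$deme, lon = 0, lat = 0),
    matrix(df$a1, ncol = 1, dimnames = list(NULL, "L1")),
    matrix(df$a2, ncol = 1, dimnames = list(NULL, "L1"))
  )
  expect_lt(abs(fst_wc(gt_eq, "A", "B")), 0.05)

  # demes fixed for alternate alleles -> 1
  gt_fix <- make_gt(list(L1 = c(rep("1/1", 5), rep("2/2", 5))),
                    deme_id = rep(c("A", "B"), each = 5))
  expect_equal(fst_wc(gt_fix, "A", "B"), 1)

  # toy fixture equals the brute-force variance-component evaluation
  gt_toy <- make_gt(
    list(L1 = c("1/1", "1/2", "2/2", "1/2", "2/2", "2/2", "1/2"),
         L2 = c("3/4", "3/3", "4/4", "3/4", "4/4", "3/4", "3/3")),
    deme_id = c("A", "A", "A", "A", "B", "B", "B")
  )
  expect_equal(fst_wc(gt_toy, "A", "B"), theta_oracle(gt_toy, "A", "B"),
               tolerance = 1e-12)
  # symmetry in deme order
  expect_equal(fst_wc(gt_toy, "A", "B"), fst_wc(gt_toy, "B", "A"))
  # invariance to allele relabeling
  gt_rl <- gt_toy
  gt_rl$a1[gt_toy$a1 == 1L] <- 7L; gt_rl$a2[gt_toy$a2 == 1L] <- 7L
  gt_rl$a1[gt_toy$a1 == 2L] <- 1L; gt_rl$a2[gt_toy$a2 == 2L] <- 1L
  expect_equal(fst_wc(gt_rl, "A", "B"), fst_wc(gt_toy, "A", "B"),
               tolerance = 1e-12)
  # monomorphic everywhere -> NA
  gt_mono <- make_gt(list(L1 = rep("1/1", 6)), deme_id = rep(c("A", "B"), 3))
  expect_true(is.na(fst_wc(gt_mono, "A", "B")))
})

test_that("Fis: full heterozygosity -> -1, full homozygosity -> 1, HWE -> ~0", {
  gt_het <- make_gt(list(L1 = rep("1/2", 8)))
  expect_equal(fis(gt_het, "d1"), -1)
  gt_hom <- make_gt(list(L1 = rep(c("1/1", "2/2"), 4)))
  expect_equal(fis(gt_hom, "d1"), 1)
  # simulate under HWE, n = 500
  set.seed(12)
  n <- 500
  calls <- lapply(1:5, function(l) {
    p <- runif(1, 0.3, 0.7)
    a <- ifelse(runif(2 * n) < p, 1L, 2L)
    paste0(a[seq_len(n)], "/", a[n + seq_len(n)])
  })
  names(calls) <- paste0("L", 1:5)
  expect_lt(abs(fis(make_gt(calls), "d1")), 0.05)
})

test_that("rarefied richness matches enumeration and limits", {
  gt <- make_gt(list(L1 = c("1/2", "1/2")))   # counts (2, 2), N = 4
  # exhaustive oracle: all C(4,2) subsamples of the 4 copies
  copies <- c(1, 1, 2, 2)
  subs <- utils::combn(4, 2)
  expected <- mean(apply(subs, 2, function(ix) length(unique(copies[ix]))))
  expect_equal(rarefied_richness(gt, "d1", 2), expected)  # = 5/3
  expect_equal(rarefied_richness(gt, "d1", 2), 5 / 3)
  # monomorphic locus -> 1 for any g; g = 1 -> exactly 1
  gt2 <- make_gt(list(L1 = rep("1/1", 4), L2 = c("1/2", "2/3", "1/3", "1/1")))
  expect_equal(rarefied_richness(gt2, "d1", 1), 1)
  gt_mono <- make_gt(list(L1 = rep("5/5", 4)))
  expect_equal(rarefied_richness(gt_mono, "d1", 4), 1)
  expect_error(rarefied_richness(gt, "d1", 9), "g must lie")
})

test_that("deme_summary assembles n, A, AR, Fis per deme", {
  gt <- make_gt(list(L1 = c("1/2", "1/1", "2/2", "1/2", "1/2", "3/3"),
                     L2 = c("4/4", "4/5", "5/5", "4/5", "4/4", "4/5")),
                deme_id = rep(c("A", "B"), each = 3))
  s <- deme_summary(gt)
  expect_equal(s$deme_id, c("A", "B"))
  expect_equal(s$n, c(3L, 3L))
  expect_true(all(s$AR <= s$A + 1e-12))
  expect_equal(attr(s, "g"), 6)
})
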