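# The five similarity measures: printed extremes, hand-computed cases,
# symmetry and invariance properties.

test_that("dice spans its extremes and matches the hand formula", {
  a <- array(FALSE, c(2, 2, 2)); a[1:4] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- array(FALSE, c(2, 2, 2)); b[5:8] <- TRUE
  expect_equal(dice(a, b), 0)
  # |A| = 4, |B| = 4, |A ^ B| = 2 -> 0.5
  c2 <- array(FALSE, c(2, 2, 2)); c2[3:6] <- TRUE
  expect_equal(dice(a, c2), 0.5)
  empty <- array(FALSE, c(2, 2, 2))
  expect_equal(dice(empty, empty), 1)
  expect_equal(dice(a, empty), 0)
  expect_error(dice(a, array(TRUE, c(3, 3, 3))), "shape")
})

test_that("nmi is 2 for a map with itself and matches hand entropy arithmetic", {
  m <- random_density(1)
  expect_equal(nmi(m, m, bins = 16), 2, tolerance = 1e-12)

  # two-bin hand case: a = (0,0,1,1), b = (0,1,1,1)
  # pa = (1/2, 1/2), pb = (1/4, 3/4), joint = {(1,1):1/4, (1,2):1/4, (2,2):1/2}
  a <- array(c(0, 0, 1, 1, 0, 0, 1, 1), c(2, 2, 2))
  b <- array(c(0, 1, 1, 1, 0, 1, 1, 1), c(2, 2, 2))
  ha <- log(2)
  hb <- -(1 / 4) * log(1 / 4) - (3 / 4) * log(3 / 4)
  hab <- -2 * (1 / 4) * log(1 / 4) - (1 / 2) * log(1 / 2)
  expect_equal(nmi(a, b, bins = 2), (ha + hb) / hab, tolerance = 1e-12)
})

test_that("nmi of independent maps approaches 1 and degenerates to 1 on constants", {
  set.seed(42)
  a <- array(runif(20^3), c(20, 20, 20))
  b <- array(runif(20^3), c(20, 20, 20))
  v <- nmi(a, b, bins = 8)
  expect_gte(v, 1)
  expect_lt(v, 1.05)
  expect_warning(vc <- nmi(array(1, c(2, 2, 2)), a[1:2, 1:2, 1:2]),
                 "degenerate")
  expect_equal(vc, 1)
})

test_that("nss averages the z-scored saliency over fixation voxels", {
  f <- array(FALSE, c(2, 2, 2)); f[1] <- TRUE
  expect_warning(v0 <- nss(array(1, c(2, 2, 2)), f), "zero-variance")
  expect_equal(v0, 0)
  expect_error(nss(random_density(2), array(FALSE, c(8, 8, 8))), "no marked")

  # 8-voxel hand case: saliency (5,1,1,1,1,1,1,1), fixation on voxel 1
  s <- array(c(5, rep(1, 7)), c(2, 2, 2))
  z1 <- (5 - mean(s)) / sd(as.vector(s))
  expect_equal(nss(s, f), z1)
  expect_gt(nss(s, f), 0)

  # fixation everywhere -> mean of a zero-mean z-map
  expect_equal(nss(s, array(TRUE, c(2, 2, 2))), 0, tolerance = 1e-12)
})

test_that("cc matches hand covariance arithmetic and rejects constants", {
  m <- random_density(3)
  expect_equal(cc(m, m), 1)
  expect_equal(cc(m, max(m) - m), -1)
  a <- array(c(1, 2, 3, 4, 1, 2, 3, 4), c(2, 2, 2))
  b <- array(c(2, 1, 4, 3, 2, 1, 4, 3), c(2, 2, 2))
  expect_equal(cc(a, b), o_cc(a, b))
  expect_error(cc(array(1, c(2, 2, 2)), m[1:2, 1:2, 1:2]), "`a` is constant")
  expect_error(cc(m[1:2, 1:2, 1:2], array(1, c(2, 2, 2))), "`b` is constant")
})

test_that("sim sums voxelwise minima of two densities", {
  m <- random_density(4)
  expect_equal(sim(m, m), 1)
  a <- array(c(0.5, 0.5, 0, 0), c(2, 2, 1))
  b <- array(c(0, 0, 0.5, 0.5), c(2, 2, 1))
  expect_equal(sim(a, b), 0)
  a3 <- array(c(0.5, 0.5, 0, 0, 0, 0, 0, 0), c(2, 2, 2))
  b3 <- array(c(0.25, 0.25, 0.5, 0, 0, 0, 0, 0), c(2, 2, 2))
  expect_equal(sim(a3, b3), 0.5)
  expect_error(sim(a3, 2 * b3), "normalized")
})

test_that("dc, nmi, cc, sim are symmetric; nss is not", {
  a <- random_density(5)
  b <- random_density(6)
  ab <- binarize_saliency(a, k = 20)
  bb <- binarize_saliency(b, k = 35)
  expect_equal(dice(ab, bb), dice(bb, ab))
  expect_equal(nmi(a, b), nmi(b, a), tolerance = 1e-12)
  expect_equal(cc(a, b), cc(b, a))
  expect_equal(sim(a, b), sim(b, a))
  expect_false(isTRUE(all.equal(nss(a, bb), nss(b, ab))))
})

test_that("cc and nss are invariant to affine rescaling; dice and sim to voxel relabeling", {
  a <- random_density(7)
  b <- random_density(8)
  f <- binarize_saliency(b, k = 40)
  expect_equal(cc(3 * a + 0.2, b), cc(a, b), tolerance = 1e-12)
  expect_equal(nss(3 * a + 0.2, f), nss(a, f), tolerance = 1e-12)
  set.seed(9)
  perm <- sample(length(a))
  ap <- array(a[perm], dim(a)); bp <- array(b[perm], dim(b))
  fp <- array(f[perm], dim(f))
  expect_equal(sim(ap, bp), sim(a, b))
  expect_equal(dice(binarize_saliency(ap, k = 40), fp),
               dice(binarize_saliency(a, k = 40), f))
})

test_that("binarization marks the top-k voxels with deterministic tie-breaks", {
  g <- array(0, c(2, 2, 2)); g[c(2, 5)] <- 1; g[7] <- 2
  expect_identical(which(binarize_saliency(g, k = 1)), 7L)
  expect_identical(which(binarize_saliency(g, k = 2)), c(2L, 7L))  # tie -> lower index
  expect_identical(sum(binarize_saliency(g, k = 100)), 8L)
})

test_that("evaluate_method returns the identity bundle for the ground truth itself", {
  gt <- structure(list(density = random_density(10) * 0, support = NULL),
                  class = "vb_ground_truth")
  d <- array(0, c(8, 8, 8)); d[1:40] <- abs(rnorm(40)) + 0.1
  d <- d / sum(d)
  gt$density <- d
  gt$support <- d > 0
  sal <- structure(list(density = d, method = "GT"), class = "vb_saliency")
  r <- evaluate_method(sal, gt)
  expect_equal(r$dc, 1)
  expect_equal(r$nmi, 2, tolerance = 1e-9)
  expect_gt(r$nss, 0)
  expect_equal(r$cc, 1)
  expect_equal(r$sim, 1)

  # a diffuse (near-uniform, non-constant) map scores strictly worse
  set.seed(101)
  dif <- 1 / 512 + rnorm(512, sd = 1e-5)
  dif <- array(dif / sum(dif), c(8, 8, 8))
  uni <- structure(list(density = dif, method = "U"), class = "vb_saliency")
  ru <- evaluate_method(uni, gt)
  expect_lt(ru$sim, r$sim)
  expect_true(all(c(ru$dc, ru$sim) >= 0 & c(ru$dc, ru$sim) <= 1))
  expect_true(ru$nmi >= 1 - 1e-9 && ru$nmi <= 2 + 1e-9)
})

test_that("percentage table is zero on the baseline and linear in the measures", {
  rep3 <- data.frame(method = c("MG", "A", "B"),
                     dc = c(0.5, 1.0, 0.75),
                     nmi = c(1.2, 1.2, 1.2),
                     nss = c(2, 4, 1),
                     cc = c(0.4, 0.8, 0.2),
                     sim = c(0, 0.1, 0.2))
  tab <- percentage_table(rep3)
  expect_equal(unlist(tab[tab$method == "MG", -1]), c(dc = 0, nmi = 0, nss = 0,
                                                      cc = 0, sim = 0))
  expect_equal(tab$dc[tab$method == "A"], 100)
  expect_equal(tab$dc[tab$method == "B"], 50)
  expect_equal(tab$nss[tab$method == "B"], -50)
  expect_true(all(is.na(tab$sim[tab$method != "MG"])))  # baseline 0 -> undefined
  expect_error(percentage_table(rep3[-1, ]), "absent")
})
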