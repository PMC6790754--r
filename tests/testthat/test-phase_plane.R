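# closed-form corner conditions used as the oracle throughout:
#   (1,1) pinned-stable  iff  sigma2_mol <= 2 sigma2_cel / s
#   (1,0) pinned-stable  iff  sigma2_cel (1 + e^-s)/s <= sigma2_mol
#                             <= sigma2_cel (1 + e^s)/s
corner11_stable <- function(sm, sc = 1, s = 1) sc - s * sm / 2 >= 0
corner10_stable <- function(sm, sc = 1, s = 1) {
  wP <- exp(-s) / (exp(-s) + 1)
  (sc - s * sm * wP >= 0) && (sc - s * sm * (1 - wP) <= 0)
}

test_that("reproductive-value weights are a softmax of activities", {
  expect_equal(unname(omega_bar(1, 1)[1, ]), c(0.5, 0.5))
  w <- omega_bar(1, 0)[1, ]
  expect_equal(unname(w), c(1 / (1 + exp(1)), exp(1) / (1 + exp(1))),
               tolerance = 1e-12)
  expect_equal(sum(w), 1)
  # s -> 0: no molecular cost discrimination
  expect_equal(unname(omega_bar(0.9, 0.1, s = 1e-12)[1, ]), c(0.5, 0.5),
               tolerance = 1e-9)
})

test_that("the flow matches hand evaluation and one-sided clamping", {
  pp <- pp_params(sigma2_mol = 1)
  expect_equal(unname(pp_rhs(1, 1, pp, clamp = FALSE)[1, ]), c(0.5, 0.5))
  expect_equal(unname(pp_rhs(1, 1, pp, clamp = TRUE)[1, ]), c(0, 0))

  pp3 <- pp_params(sigma2_mol = 3)
  expect_equal(unname(pp_rhs(1, 1, pp3, clamp = FALSE)[1, ]), c(-0.5, -0.5))
  # inward flow is not clamped: the boundary can be left
  expect_equal(unname(pp_rhs(1, 1, pp3, clamp = TRUE)[1, ]), c(-0.5, -0.5))

  # exchange symmetry on the diagonal and under P <-> Q relabelling
  set.seed(1)
  for (r in 1:20) {
    x <- runif(2)
    f <- pp_rhs(x[1], x[2], pp3, clamp = FALSE)[1, ]
    g <- pp_rhs(x[2], x[1], pp3, clamp = FALSE)[1, ]
    expect_equal(unname(f), unname(rev(g)), tolerance = 1e-14)
    d <- pp_rhs(x[1], x[1], pp3, clamp = FALSE)[1, ]
    expect_equal(d[[1]], d[[2]], tolerance = 1e-14)
  }
})

test_that("positive feedback: the more catalytic type gains faster", {
  for (sm in c(0.5, 1, 2, 4)) {
    pp <- pp_params(sigma2_mol = sm)
    g <- seq(0.02, 0.98, length.out = 50)
    pts <- expand.grid(kP = g, kQ = g)
    f <- pp_rhs(pts$kP, pts$kQ, pp, clamp = FALSE)
    up <- pts$kP > pts$kQ
    expect_true(all(f[up, "dkP"] > f[up, "dkQ"]))
  }
})

test_that("equilibria and stability match the corner oracle", {
  # bistability window: symmetric and asymmetric corners both stable
  eq <- find_equilibria(pp_params(sigma2_mol = 1.5))
  stab <- eq[eq$stability == "stable", ]
  expect_true(any(stab$kP == 1 & stab$kQ == 1))
  expect_true(any(stab$kP == 1 & stab$kQ == 0))
  expect_true(any(stab$kP == 0 & stab$kQ == 1))
  expect_true(corner11_stable(1.5) && corner10_stable(1.5))

  # past the tipping point (1,1) is no longer a stable state
  eq2 <- find_equilibria(pp_params(sigma2_mol = 2.5))
  stab2 <- eq2[eq2$stability == "stable", ]
  expect_false(any(stab2$kP == 1 & stab2$kQ == 1))
  expect_true(any(stab2$kP == 1 & stab2$kQ == 0))
  expect_true(any(stab2$kP == 0 & stab2$kQ == 1))
  expect_false(corner11_stable(2.5)); expect_true(corner10_stable(2.5))

  # no molecular-level variance: cellular selection maximizes everything
  eq3 <- find_equilibria(pp_params(sigma2_mol = 0))
  stab3 <- eq3[eq3$stability == "stable", ]
  expect_equal(nrow(stab3), 1)
  expect_equal(c(stab3$kP, stab3$kQ), c(1, 1))
  f <- pp_rhs(runif(20), runif(20), pp_params(sigma2_mol = 0), clamp = FALSE)
  expect_true(all(f > 0))  # flow increases everywhere
})

test_that("edge equilibria are saddles on the basin boundary", {
  eq <- find_equilibria(pp_params(sigma2_mol = 1.8))
  edge <- eq[eq$boundary & eq$kind == "asymmetric" &
               eq$kP > 0 & eq$kP < 1 | eq$kQ > 0 & eq$kQ < 1, ]
  edge <- eq[(eq$kP %in% c(0, 1)) != (eq$kQ %in% c(0, 1)), ]
  expect_gt(nrow(edge), 0)
  expect_true(all(edge$stability == "saddle"))
})

test_that("stability thresholds converge to the closed forms by bisection", {
  bisect <- function(pred, lo, hi, tol = 1e-9) {
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (pred(mid)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  is11 <- function(sm) {
    eq <- find_equilibria(pp_params(sigma2_mol = sm))
    any(eq$stability == "stable" & eq$kP == 1 & eq$kQ == 1)
  }
  expect_equal(bisect(is11, 1, 3), 2, tolerance = 1e-6)

  is10 <- function(sm) {
    eq <- find_equilibria(pp_params(sigma2_mol = sm))
    any(eq$stability == "stable" & eq$kP == 1 & eq$kQ == 0)
  }
  lower <- bisect(function(sm) !is10(sm), 1, 2)   # entering the window
  upper <- bisect(is10, 2, 5)                      # leaving the window
  expect_equal(lower, 1 + exp(-1), tolerance = 1e-6)
  expect_equal(upper, 1 + exp(1), tolerance = 1e-6)
})

test_that("the flow is the gradient of the inclusive-fitness potential", {
  set.seed(8)
  for (r in 1:10) {
    pp <- pp_params(sigma2_mol = runif(1, 0.1, 4),
                    sigma2_cel = runif(1, 0.1, 2), s = runif(1, 0.2, 3))
    kP <- runif(100, 0.01, 0.99); kQ <- runif(100, 0.01, 0.99)
    expect_lt(potential_gradient_check(kP, kQ, pp), 1e-10)
  }
  # independent numerical-gradient oracle at a few points
  skip_if_not_installed("pracma")
  pp <- pp_params(sigma2_mol = 1.7, s = 1.3)
  s2 <- pp$sigma2_cel + pp$sigma2_mol
  for (pt in list(c(0.3, 0.8), c(0.5, 0.5), c(0.9, 0.2))) {
    g <- pracma::grad(function(x) potential_value(x[1], x[2], pp), pt)
    f <- pp_rhs(pt[1], pt[2], pp, clamp = FALSE)[1, ]
    expect_equal(unname(f), s2 * g, tolerance = 1e-6)
  }
})

test_that("limiting relatedness regimes reduce to pure B or pure C flows", {
  # R = 1: flow = sigma2_tot * grad(B) = sigma2_tot * (1, 1)
  pp1 <- pp_params(sigma2_mol = 0, sigma2_cel = 1.3)
  f <- pp_rhs(c(0.2, 0.7), c(0.5, 0.1), pp1, clamp = FALSE)
  expect_true(all(abs(f - 1.3) < 1e-14))
  # R = 0: flow = -sigma2_tot * grad(C) = -sigma2_tot * s * omega
  pp0 <- pp_params(sigma2_mol = 2, sigma2_cel = 0, s = 1.5, beta = 1,
                   gamma = 1.5)
  kP <- c(0.3, 0.6); kQ <- c(0.8, 0.2)
  f0 <- pp_rhs(kP, kQ, pp0, clamp = FALSE)
  w <- omega_bar(kP, kQ, 1.5)
  expect_equal(unname(f0[, "dkP"]), unname(-2 * 1.5 * w[, "P"]),
               tolerance = 1e-14)
})

test_that("basins: the diagonal is invariant and attractors are reached", {
  # all-dominant cellular selection: everything flows to (1,1)
  pp <- pp_params(sigma2_mol = 0.5)
  for (start in list(c(0, 0), c(0.1, 0.9), c(0.7, 0.2))) {
    fin <- integrate_flow(start[1], start[2], pp, dt = 0.05)
    expect_equal(unname(fin), c(1, 1), tolerance = 1e-6)
  }

  # bistable regime: diagonal starts stay diagonal, off-diagonal starts
  # near an asymmetric corner reach it
  pp18 <- pp_params(sigma2_mol = 1.8)
  fin_d <- integrate_flow(0.4, 0.4, pp18, dt = 0.05)
  expect_equal(fin_d[["kP"]], fin_d[["kQ"]], tolerance = 1e-12)
  fin_a <- integrate_flow(1, 0.6, pp18, dt = 0.05)
  expect_equal(unname(fin_a), c(1, 0), tolerance = 1e-6)

  b <- basins(pp18, n = 9, dt = 0.05)
  expect_true(all(c("1,1", "1,0", "0,1") %in% unique(b$basin)))
  diag_pts <- b[b$kP == b$kQ, "basin"]
  expect_true(all(diag_pts %in% c("1,1", "0,0", "undetermined")))
})
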