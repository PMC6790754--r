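test_that("mean activities average each entry over all replicators", {
  snap <- snapshot_from_traits(list(c(1, 1), c(1, 1)))
  expect_true(all(mean_activities(snap) == 1))

  snap2 <- snapshot_from_traits(list(0.2, 0.8))
  expect_true(all(abs(mean_activities(snap2) - 0.5) < 1e-15))

  # invariant under cell relabelling
  snap3 <- snapshot_from_traits(list(c(0.1, 0.9), c(0.4)))
  snap4 <- snapshot_from_traits(list(c(0.4), c(0.1, 0.9)))
  expect_equal(unname(mean_activities(snap3)), unname(mean_activities(snap4)))

  empty <- snapshot_from_traits(list(numeric(0)))
  expect_error(mean_activities(empty), "empty")
})

test_that("minority frequency filters small cells and uses replicators only", {
  reps <- data.frame(
    cell_id = c(rep(1, 100), rep(2, 10), rep(3, 49)),
    rep_id = 1:159,
    rtype = c(rep("P", 30), rep("Q", 70),  # cell 1: 30/70
              rep("P", 5), rep("Q", 5),    # cell 2: 50/50
              rep("P", 49)),               # cell 3: under V/2 = 50
    state = "free")
  for (nm in k_entry_names()) reps[[nm]] <- 1
  snap <- replicell:::new_snapshot(0L, reps,
    data.frame(cell_id = 1:3, substrate = c(0L, 40L, 0L)))
  mf <- minority_frequency(snap, V = 100)
  expect_equal(unname(mf[c("1", "2")]), c(0.3, 0.5))
  expect_false("3" %in% names(mf))  # 49 particles < V/2
})

test_that("variance decomposition matches brute-force moments", {
  # two cells {1,1} and {0,0}: all variance between cells
  vd <- variance_decomposition(snapshot_from_traits(list(c(1, 1), c(0, 0))))
  expect_equal(vd$sigma2_cel, 0.25)
  expect_equal(vd$sigma2_mol, 0)
  expect_equal(as.numeric(vd$R), 1)

  # one cell {0,1}: all variance within
  vd2 <- variance_decomposition(snapshot_from_traits(list(c(0, 1))))
  expect_equal(vd2$sigma2_cel, 0)
  expect_equal(vd2$sigma2_mol, 0.25)
  expect_equal(as.numeric(vd2$R), 0)

  # degenerate: identical traits -> R undefined with a reason
  vd3 <- variance_decomposition(snapshot_from_traits(list(c(.5, .5), c(.5, .5))))
  expect_true(is.na(vd3$R))
  expect_match(attr(vd3$R, "reason"), "identical")
})

test_that("law of total variance holds on random snapshots", {
  set.seed(21)
  for (r in 1:20) {
    traits <- lapply(seq_len(sample(2:6, 1)),
                     function(i) runif(sample(1:8, 1)))
    if (sum(lengths(traits)) < 2) next
    snap <- snapshot_from_traits(traits)
    kappa <- trait_projection(snap, "P")
    vd <- variance_decomposition(snap, "P")
    total <- mean((kappa - mean(kappa))^2)
    expect_equal(vd$sigma2_cel + vd$sigma2_mol, total, tolerance = 1e-12)
    # oracle: direct replicator-weighted sums
    cellm <- ave(kappa, snap$replicators$cell_id)
    expect_equal(vd$sigma2_cel, mean((cellm - mean(kappa))^2))
    expect_equal(vd$sigma2_mol, mean((kappa - cellm)^2))
  }
})

test_that("fixtures recover their prescribed variance targets", {
  for (tgt in list(c(0.25, 0), c(0, 0.25), c(0.04, 0.01))) {
    fx <- generate_fixture(fixture_spec(n_cells = 10, cell_size = 10,
                                        sigma2_cel = tgt[1],
                                        sigma2_mol = tgt[2],
                                        mean_trait = 0.5, seed = 3))
    vd <- variance_decomposition(fx)
    expect_equal(vd$sigma2_cel, tgt[1], tolerance = 1e-12)
    expect_equal(vd$sigma2_mol, tgt[2], tolerance = 1e-12)
  }
  expect_error(fixture_spec(10, 10, 0.5, 0.5), "unattainable")
  # deterministic per seed
  f1 <- generate_fixture(fixture_spec(4, 4, 0.01, 0.01, seed = 9))
  f2 <- generate_fixture(fixture_spec(4, 4, 0.01, 0.01, seed = 9))
  expect_identical(f1, f2)
})

test_that("Price terms vanish without fitness differences", {
  set.seed(2)
  tr <- runif(10); cell <- rep(1:2, each = 5)
  pt <- price_decompose(tr, rep(2, 10), cell)
  expect_equal(pt$lhs, 0)
  expect_equal(pt$between, 0)
  expect_equal(pt$within, 0)
})

test_that("Price decomposition matches offspring-pool enumeration", {
  # cells A: (k=1, lambda=2), (k=0, lambda=1); B: (k=1, l=1), (k=0, l=1)
  trait <- c(1, 0, 1, 0)
  lam <- c(2, 1, 1, 1)
  cell <- c("A", "A", "B", "B")
  pt <- price_decompose(trait, lam, cell)
  # oracle: expected offspring pool = traits repeated lambda times
  pool_mean <- sum(lam * trait) / sum(lam)
  lhs_oracle <- mean(lam) * (pool_mean - mean(trait))
  expect_equal(pt$lhs, lhs_oracle, tolerance = 1e-15)
  expect_equal(pt$lhs, pt$between + pt$within, tolerance = 1e-15)
  # frozen values from the enumeration: <lam>=1.25, pool mean 3/5, <k>=1/2
  expect_equal(pt$lhs, 1.25 * (3 / 5 - 1 / 2))  # = 0.125
  expect_equal(pt$between, 0)   # both cells have mean trait 1/2
  expect_equal(pt$within, 0.125)
})

test_that("the Price identity is exact on random fixtures", {
  set.seed(33)
  for (r in 1:200) {
    n_cells <- sample(2:6, 1)
    sizes <- sample(1:7, n_cells, replace = TRUE)
    cell <- rep(seq_len(n_cells), sizes)
    trait <- runif(length(cell), -2, 2)
    lam <- rexp(length(cell))
    pt <- price_decompose(trait, lam, cell)
    expect_lt(abs(pt$lhs - (pt$between + pt$within)), 1e-12)
  }
})

test_that("Price terms are invariant under trait translation", {
  set.seed(4)
  cell <- rep(1:3, each = 4)
  trait <- runif(12); lam <- rexp(12)
  a <- price_decompose(trait, lam, cell)
  b <- price_decompose(trait + 7.3, lam, cell)
  expect_equal(a$lhs, b$lhs, tolerance = 1e-12)
  expect_equal(a$between, b$between, tolerance = 1e-12)
  expect_equal(a$within, b$within, tolerance = 1e-12)
})

test_that("reproductive values are the left eigenvector of the projection", {
  rv <- reproductive_value(0.3, 0.7)
  expect_equal(rv$lambda, 1)
  expect_equal(unname(rv$u), c(0.3, 0.7))

  # the role that is never copied has zero reproductive value
  expect_equal(unname(reproductive_value(0, 0.4)$u), c(0, 1))
  expect_equal(unname(reproductive_value(0.5, 0.5)$u), c(0.5, 0.5))
  expect_error(reproductive_value(0, 0), "both rates")

  # cross-check against a generic eigensolver
  set.seed(5)
  for (r in 1:50) {
    w <- rexp(2)
    rv <- reproductive_value(w[1], w[2])
    M <- matrix(c(w[1], w[1], w[2], w[2]), 2, 2)  # column-major: [[wP,wQ],[wP,wQ]]
    ev <- eigen(t(M))  # left eigenvectors of M
    i <- which.max(Re(ev$values))
    expect_equal(rv$lambda, Re(ev$values[i]), tolerance = 1e-12)
    u <- Re(ev$vectors[, i]); u <- u / sum(u)
    expect_equal(unname(rv$u), u, tolerance = 1e-12)
  }
})

test_that("phase classification follows the declared thresholds", {
  base <- setNames(rep(1, 8), k_entry_names())
  expect_equal(classify_phase(base, 0.45)$label, "none")

  # differentiated: Q catalytic, P template
  mk <- setNames(rep(0.02, 8), k_entry_names())
  mk[5:8] <- 0.8                             # A_Q = 0.8, A_P = 0.02
  mk[k_index("Q", "Q", "P")] <- 0.8          # transcription P -> Q
  mk[k_index("Q", "P", "Q")] <- 0.01         # reverse transcription
  cls <- classify_phase(mk, minority_median = 0.18)
  expect_equal(cls$label, "threefold")
  expect_equal(cls$catalyst_type, "Q")
  cls2 <- classify_phase(mk, minority_median = 0.48)
  expect_equal(cls2$label, "catalytic_informatic_only")

  # catalytic asymmetry with two-way information flow
  mk2 <- mk
  mk2[k_index("Q", "P", "Q")] <- 0.6
  expect_equal(classify_phase(mk2, 0.48)$label, "incomplete")

  # everything lost: not "none", not differentiated
  expect_equal(classify_phase(setNames(rep(0.01, 8), k_entry_names()),
                              0.5)$label, "uncategorized")

  expect_error(classify_phase(base, 0.5, window_len = 10, min_window = 100),
               "window")
})

test_that("empirical offspring rates normalize to a unit mean fitness", {
  births <- data.frame(step = c(1, 1, 2, 3, 3, 4),
                       rep_id = 101:106,
                       rtype = c("P", "Q", "P", "P", "Q", "Q"),
                       template_id = c(1, 1, 2, 2, 3, 3))
  om <- empirical_omega(births, c(1, 4))
  expect_equal(sum(om$omega_P + om$omega_Q) * 4 / 6, 1)
  rv <- reproductive_value(sum(om$omega_P), sum(om$omega_Q))
  expect_equal(sum(rv$u), 1)
})
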