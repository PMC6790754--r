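test_that("channel rates follow the catalyst's own-type entries", {
  X <- list(rtype = "P", k = rep(1, 8))
  Y <- list(rtype = "Q", k = rep(1, 8))
  ch <- channel_rates(X, Y)
  expect_true(all(ch$rates == 1))
  expect_equal(ch$total, 4)

  # X (type P) catalyses product P from template of type Q: entry kP.PQ
  kx <- rep(0, 8); kx[k_index("P", "P", "Q")] <- 0.5
  ch2 <- channel_rates(list(rtype = "P", k = kx),
                       list(rtype = "Q", k = rep(0, 8)))
  expect_equal(ch2$rates["X", "P"], 0.5)
  expect_equal(ch2$total, 0.5)
  expect_true(all(ch2$rates[c(2, 3, 4)] == 0))

  # negative entries contribute zero
  kx[k_index("P", "Q", "Q")] <- -0.7
  ch3 <- channel_rates(list(rtype = "P", k = kx),
                       list(rtype = "Q", k = rep(-1, 8)))
  expect_equal(ch3$rates["X", "Q"], 0)
  expect_equal(ch3$total, 0.5)

  # swapping arguments relabels the roles
  ch4 <- channel_rates(Y, list(rtype = "P", k = kx))
  expect_equal(ch4$rates["Y", "P"], 0.5)
})

test_that("mutation is per-entry, uniform, and reflects at k_max", {
  set.seed(1)
  k <- runif(8)
  expect_identical(mutate_profile(k, m = 0, 0.05), k)
  # reflection arithmetic: 0.99 + 0.03 -> 2*1 - 1.02 = 0.98
  expect_equal(2 * 1 - (0.99 + 0.03), 0.98)
  set.seed(42)
  for (i in 1:200) {
    out <- mutate_profile(rep(0.99, 8), m = 1, delta_mut = 0.05)
    expect_true(all(out <= 1))
    expect_true(all(abs(out - 0.99) <= 0.05 + 1e-12))
  }
  # away from the boundary the increments are uniform on (-delta, delta)
  set.seed(7)
  inc <- replicate(4000, mutate_profile(rep(0.5, 8), 1, 0.05)) - 0.5
  ks <- suppressWarnings(stats::ks.test(as.numeric(inc),
                                        "punif", -0.05, 0.05))
  expect_gt(ks$p.value, 0.01)
  expect_error(mutate_profile(rep(1.2, 8), 0.1, 0.05), "k_max")
})

test_that("complex formation pairs disjointly and respects rates", {
  p <- sim_params(V = 10, m = 0, density_collisions = FALSE)
  # all entries <= 0: no complexes
  cell <- make_cell(n = 10, k = -0.5)
  set.seed(1)
  fc <- form_complexes(cell, p)
  expect_equal(nrow(fc$complexes), 0)
  expect_true(all(fc$cell$state == 0))

  # all entries at k_max: every sampled pair reacts, floor(n/2) complexes
  for (n in c(2, 5, 8, 9)) {
    cell <- make_cell(n = n, k = 1)
    fc <- form_complexes(cell, p)
    expect_equal(nrow(fc$complexes), n %/% 2)
    members <- c(fc$complexes$catalyst, fc$complexes$template)
    expect_equal(anyDuplicated(members), 0L)  # disjoint
    expect_true(all(fc$cell$state[members] > 0))
  }

  # single replicator: nothing to pair
  fc1 <- form_complexes(make_cell(n = 1), p)
  expect_equal(nrow(fc1$complexes), 0)

  # the mass-action factor suppresses reactions in dilute cells
  pd <- sim_params(V = 1000, m = 0, density_collisions = TRUE)
  set.seed(2)
  got <- mean(replicate(300, nrow(form_complexes(make_cell(n = 2), pd)$complexes)))
  expect_lt(got, 0.05)  # acceptance ~ 1/1000
})

test_that("bound replicators cannot simultaneously serve both roles", {
  p <- sim_params(V = 10, m = 0, density_collisions = FALSE)
  set.seed(3)
  cell <- make_cell(n = 10, k = 1)
  fc <- form_complexes(cell, p)
  expect_true(all(fc$complexes$catalyst != fc$complexes$template))
  # a replicator appears in at most one complex, in exactly one role
  expect_equal(anyDuplicated(c(fc$complexes$catalyst,
                               fc$complexes$template)), 0L)
})

test_that("synthesis consumes substrate, inherits from template, dissociates", {
  p <- sim_params(V = 10, m = 0, density_collisions = FALSE)

  # substrate 0: no births, everyone freed
  set.seed(1)
  cell <- make_cell(n = 6, k = 1, substrate = 0L)
  fc <- form_complexes(cell, p)
  sp <- synthesize_products(fc$cell, fc$complexes, p)
  expect_equal(nrow(sp$births), 0)
  expect_true(all(sp$cell$state == 0))

  # 1 complex, substrate 3: one birth, substrate 2
  cell <- make_cell(n = 2, k = 1, substrate = 3L)
  fc <- form_complexes(cell, p)
  sp <- synthesize_products(fc$cell, fc$complexes, p, step = 5L,
                            next_rep_id = 100L)
  expect_equal(nrow(sp$births), 1)
  expect_equal(sp$cell$substrate, 2L)
  expect_equal(length(sp$cell$rep_id) + sp$cell$substrate, 2 + 3)

  # child inherits the template profile exactly when m = 0
  tmpl_row <- fc$complexes$template[1]
  expect_equal(unname(sp$cell$k[3, ]), unname(cell$k[tmpl_row, ]))
  expect_equal(sp$births$template_id, cell$rep_id[tmpl_row])

  # 5 complexes, substrate 2: exactly 2 births; producers uniform among 5
  prod_counts <- integer(5)
  set.seed(9)
  for (r in 1:600) {
    cell <- make_cell(n = 10, k = 1, substrate = 2L)
    fc <- form_complexes(cell, p)
    expect_equal(nrow(fc$complexes), 5)
    sp <- synthesize_products(fc$cell, fc$complexes, p)
    expect_equal(nrow(sp$births), 2)
    hit <- match(sp$births$template_id,
                 cell$rep_id[fc$complexes$template])
    prod_counts[hit] <- prod_counts[hit] + 1
  }
  # each of the 5 complexes produces with probability 2/5
  expect_true(all(abs(prod_counts / 600 - 0.4) < 0.08))
})

test_that("decay is binomial and returns substrate to the cell", {
  cell <- make_cell(n = 50, k = 1, substrate = 5L)
  set.seed(1)
  dc <- decay_step(cell, d = 0)
  expect_equal(length(dc$cell$rep_id), 50)
  expect_equal(dc$cell$substrate, 5L)

  dc1 <- decay_step(cell, d = 1)
  expect_equal(length(dc1$cell$rep_id), 0)
  expect_equal(dc1$cell$substrate, 55L)
  expect_equal(nrow(dc1$deaths), 50)

  set.seed(2)
  surv <- replicate(400, length(decay_step(make_cell(n = 100), 0.02)$cell$rep_id))
  expect_equal(mean(surv), 98, tolerance = 0.005)
})

test_that("within-cell particle count is conserved by the reaction substeps", {
  p <- sim_params(V = 50, m = 0.5, delta_mut = 0.05)
  set.seed(11)
  for (r in 1:20) {
    cell <- make_cell(n = sample(2:30, 1), k = runif(1),
                      substrate = sample(0:10, 1))
    before <- length(cell$rep_id) + cell$substrate
    fc <- form_complexes(cell, p)
    sp <- synthesize_products(fc$cell, fc$complexes, p)
    dc <- decay_step(sp$cell, p$d)
    after <- length(dc$cell$rep_id) + dc$cell$substrate
    expect_equal(after, before)
  }
})

test_that("heritability: child profiles equal template profiles when m = 0", {
  p <- sim_params(V = 20, m = 0, density_collisions = FALSE)
  set.seed(4)
  cell <- make_cell(n = 10, k = 1, substrate = 10L)
  for (i in seq_len(nrow(cell$k))) cell$k[i, ] <- runif(8)
  fc <- form_complexes(cell, p)
  sp <- synthesize_products(fc$cell, fc$complexes, p, next_rep_id = 50L)
  for (b in seq_len(nrow(sp$births))) {
    child_row <- 10 + b
    tmpl_row <- match(sp$births$template_id[b], cell$rep_id)
    expect_equal(unname(sp$cell$k[child_row, ]), unname(cell$k[tmpl_row, ]))
  }
})

test_that("per-capita birth rate increases with the common activity level", {
  p <- sim_params(V = 20, m = 0, density_collisions = FALSE)
  births_at <- function(k) {
    set.seed(123)
    mean(replicate(150, {
      cell <- make_cell(n = 20, k = k, substrate = 10L)
      fc <- form_complexes(cell, p)
      nrow(synthesize_products(fc$cell, fc$complexes, p)$births)
    }))
  }
  rates <- vapply(c(0.1, 0.3, 0.6, 1), births_at, numeric(1))
  expect_true(all(diff(rates) > 0))
})
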