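test_that("QP solver agrees with a direct KKT solve on random equality-constrained problems", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(5:15, 1)
    m <- sample(1:4, 1)
    A <- matrix(rnorm(m * n), m, n)
    x0 <- rnorm(n)
    b <- as.numeric(A %*% x0)       # guaranteed consistent
    fit <- fluxmeth:::qp_active_set(diag(2, n), NULL, A, b,
                                    rep(-Inf, n), rep(Inf, n))
    expect_identical(fit$status, "optimal")
    expect_lt(max(abs(fit$x - kkt_oracle(A, b))), 1e-6)
    expect_lt(max(abs(A %*% fit$x - b)), 1e-8)
  }
})

test_that("QP solver respects active bounds (KKT conditions hold)", {
  set.seed(9)
  n <- 8
  A <- matrix(rnorm(2 * n), 2, n)
  b <- as.numeric(A %*% runif(n, 0.05, 0.35))  # feasible inside the box
  lb <- rep(0, n); ub <- rep(0.4, n)
  fit <- fluxmeth:::qp_active_set(diag(2, n), NULL, A, b, lb, ub)
  expect_identical(fit$status, "optimal")
  expect_true(all(fit$x >= lb - 1e-9) && all(fit$x <= ub + 1e-9))
  expect_lt(max(abs(A %*% fit$x - b)), 1e-8)
  # stationarity on the free coordinates: the gradient 2x must equal
  # A' lambda there (bound multipliers vanish off the active set)
  g <- 2 * fit$x
  free <- fit$x > lb + 1e-7 & fit$x < ub - 1e-7
  lam <- qr.solve(t(A[, free, drop = FALSE]), g[free])
  expect_lt(max(abs(t(A[, free, drop = FALSE]) %*% lam - g[free])), 1e-6)
})

test_that("inconsistent equalities and crossed bounds are reported", {
  A <- rbind(c(1, 0), c(1, 0))
  fit <- fluxmeth:::qp_active_set(diag(2, 2), NULL, A, c(1, 2),
                                  rep(-Inf, 2), rep(Inf, 2))
  expect_identical(fit$status, "inconsistent_equalities")
  fit2 <- fluxmeth:::qp_active_set(diag(2, 2), NULL, NULL, NULL,
                                   c(1, 0), c(0, 1))
  expect_identical(fit2$status, "infeasible")
})

test_that("snapshot solve is unique and independent of reaction order", {
  toy <- make_toy_network(seed = 11)
  cons <- rbind(flux_constraint("upt_glc", 10, day = 6, condition = "G+"),
                flux_constraint("exp_gly", 0.5, day = 6, condition = "G+"))
  sol <- solve_snapshot_fluxes(toy$network, cons)
  expect_identical(sol$status, "optimal")
  # permute reactions and solve again
  net2 <- toy$network
  perm <- rev(seq_len(nrow(net2$reactions)))
  net2 <- reaction_network(net2$metabolites, net2$reactions[perm, ],
                           net2$stoichiometry[perm])
  sol2 <- solve_snapshot_fluxes(net2, cons)
  expect_lt(max(abs(sol2$fluxes[names(sol$fluxes)] - sol$fluxes)), 1e-7)
})

test_that("two-stage relaxation reaches the closed-form compromise", {
  # chain: -> A -> ; measuring uptake = 2 and export = 3 is inconsistent
  # with steady state. Stage 1 minimises (v-2)^2 + (v-3)^2 over the line
  # uptake = export = v, giving v = 2.5 with residuals +/- 0.5.
  net <- reaction_network(
    data.frame(id = "A", is_internal = TRUE),
    data.frame(id = c("upt", "exp"), reversible = FALSE, lb = 0, ub = 1000),
    list(upt = c(A = 1), exp = c(A = -1)))
  cons <- rbind(flux_constraint("upt", 2, day = 1, condition = "c"),
                flux_constraint("exp", 3, day = 1, condition = "c"))
  sol <- solve_snapshot_fluxes(net, cons)
  expect_identical(sol$status, "relaxed")
  expect_equal(unname(sol$fluxes), c(2.5, 2.5), tolerance = 1e-7)
  expect_equal(unname(sol$constraint_residuals), c(0.5, 0.5),
               tolerance = 1e-7)
  expect_lt(sol$max_steady_state_residual, 1e-8)
})

test_that("band constraints relax an otherwise inconsistent measurement pair", {
  net <- reaction_network(
    data.frame(id = "A", is_internal = TRUE),
    data.frame(id = c("upt", "exp"), reversible = FALSE, lb = 0, ub = 1000),
    list(upt = c(A = 1), exp = c(A = -1)))
  cons <- rbind(flux_constraint("upt", 2, tolerance = 0.6, day = 1, condition = "c"),
                flux_constraint("exp", 3, tolerance = 0.6, day = 1, condition = "c"))
  sol <- solve_snapshot_fluxes(net, cons)
  expect_identical(sol$status, "optimal")
  # minimum-norm point of the feasible band overlap [2.4, 2.6]
  expect_equal(unname(sol$fluxes), c(2.4, 2.4), tolerance = 1e-7)
})

test_that("infeasible bound systems produce a named diagnostic", {
  net <- reaction_network(
    data.frame(id = "A", is_internal = TRUE),
    data.frame(id = c("upt", "exp"), reversible = FALSE,
               lb = c(5, 0), ub = c(1000, 1)),
    list(upt = c(A = 1), exp = c(A = -1)))
  sol <- solve_snapshot_fluxes(net, flux_constraint("upt", 6, day = 1,
                                                    condition = "c"))
  expect_identical(sol$status, "infeasible")
  expect_match(sol$diagnostic, "A")
  expect_match(sol$diagnostic, "bound")
})

test_that("unknown reactions and mixed snapshots are rejected", {
  toy <- make_toy_network(seed = 2)
  expect_error(solve_snapshot_fluxes(toy$network,
                                     flux_constraint("nope", 1)),
               "unknown reaction")
  cons <- rbind(flux_constraint("upt_glc", 1, day = 1, condition = "a"),
                flux_constraint("exp_gly", 1, day = 2, condition = "a"))
  expect_error(solve_snapshot_fluxes(toy$network, cons), "share")
})

test_that("flux activity balances production and consumption", {
  toy <- make_toy_network(seed = 4)
  cons <- rbind(flux_constraint("upt_glc", toy$v_true[["upt_glc"]],
                                day = 6, condition = "G+"),
                flux_constraint("exp_gly", toy$v_true[["exp_gly"]],
                                day = 6, condition = "G+"),
                flux_constraint("exp_cellwall", toy$v_true[["exp_cellwall"]],
                                day = 6, condition = "G+"),
                flux_constraint("exp_protein", toy$v_true[["exp_protein"]],
                                day = 6, condition = "G+"))
  sol <- solve_snapshot_fluxes(toy$network, cons)
  expect_identical(sol$status, "optimal")
  internal <- toy$network$metabolites$id[toy$network$metabolites$is_internal]
  act <- flux_activity(sol, toy$network, internal)
  expect_lt(max(abs(act$producing - act$consuming)), 1e-8)
  expect_error(flux_activity(sol, toy$network, "NOT_A_MET"), "unknown")
})

test_that("timecourse driver splits snapshots, reports skips and infeasibility", {
  toy <- make_toy_network(seed = 6)
  cons <- rbind(flux_constraint("upt_glc", 5, day = 2, condition = "G+"),
                flux_constraint("upt_glc", 1, day = 4, condition = "G+"))
  expect_message(
    tc <- run_flux_timecourse(toy$network, cons, watchlist = "SAM",
                              days = c(2, 4, 6)),
    "skipping")
  expect_length(tc$solutions, 2L)
  expect_setequal(unique(tc$fluxes$day), c(2, 4))
  expect_named(tc$activity,
               c("condition", "day", "metabolite_id", "producing", "consuming"))
})
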