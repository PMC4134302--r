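test_that("a single highly-cued chain reaction is forced active", {
  m <- chain_model()
  sol <- solve_imat(imat_problem(m, R_H = "R1", epsilon = 1))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 1L)
  expect_gte(abs(sol$flux[["R1"]]), 1)
})

test_that("no cues yield objective zero with a feasible optimum", {
  m <- chain_model()
  sol <- solve_imat(imat_problem(m))
  expect_equal(sol$objective, 0L)
  S <- stoichiometric_matrix(m)
  expect_lt(max(abs(S %*% sol$flux)), 1e-6)
})

test_that("a branch with one high and one low cue satisfies both", {
  m <- branch_model()
  sol <- solve_imat(imat_problem(m, R_H = "B1", R_L = "B2"))
  expect_equal(sol$objective, 2L)
  expect_gte(abs(sol$flux[["B1"]]), 1)
  expect_equal(sol$flux[["B2"]], 0)
})

test_that("unsatisfiable and conflicting cues degrade gracefully", {
  # high cue on a reaction producing a dead-end metabolite
  m <- metabolic_model(
    data.frame(id = c("A", "D"), name = c("A", "D"), compartment = "c"),
    data.frame(id = c("EX_A", "Rdead"), lb = c(-1000, 0), ub = 1000,
               gpr = c("", "g1"), exchange = c(TRUE, FALSE)),
    list(EX_A = c(A = -1), Rdead = c(A = -1, D = 1)))
  sol <- solve_imat(imat_problem(m, R_H = "Rdead"))
  expect_equal(sol$objective, 0L)
  expect_equal(sol$flux[["Rdead"]], 0)
  expect_equal(brute_force_imat(imat_problem(m, R_H = "Rdead"))$objective, 0L)

  # two high cues competing for one unit of an irreversible substrate
  m2 <- metabolic_model(
    data.frame(id = c("S", "P", "Q"), name = c("S", "P", "Q"),
               compartment = "c"),
    data.frame(id = c("EX_S", "B1", "B2", "EX_P", "EX_Q"),
               lb = c(0, 0, 0, -1000, -1000),
               ub = c(1.5, 1000, 1000, 1000, 1000),
               gpr = c("", "g1", "g2", "", ""),
               exchange = c(TRUE, FALSE, FALSE, TRUE, TRUE)),
    list(EX_S = c(S = 1), B1 = c(S = -1, P = 1), B2 = c(S = -1, Q = 1),
         EX_P = c(P = -1), EX_Q = c(Q = -1)))
  prob <- imat_problem(m2, R_H = c("B1", "B2"), epsilon = 1)
  expect_equal(solve_imat(prob)$objective, 1L)
  expect_equal(brute_force_imat(prob)$objective, 1L)
})

test_that("the MILP matches the brute-force oracle on random problems", {
  for (seed in 1:6) {
    prob <- random_cue_problem(seed, max_cues = 6)
    sol <- solve_imat(prob)
    bf <- brute_force_imat(prob)
    expect_equal(sol$objective, bf$objective, label = paste("seed", seed))
  }
})

test_that("reported fluxes satisfy mass balance, bounds and the objective", {
  for (seed in c(3, 7)) {
    prob <- random_cue_problem(seed)
    sol <- solve_imat(prob)
    m <- prob$model
    S <- stoichiometric_matrix(m)
    expect_lt(max(abs(S %*% sol$flux)), 1e-6)
    expect_true(all(sol$flux >= m$reactions$lb - 1e-7))
    expect_true(all(sol$flux <= m$reactions$ub + 1e-7))
    # objective equals the flux-level count of satisfied cues
    n_hi <- sum(abs(sol$flux[prob$R_H]) >= prob$epsilon - 1e-6)
    n_lo <- sum(abs(sol$flux[prob$R_L]) <= 1e-6)
    expect_equal(sol$objective, n_hi + n_lo)
  }
})

test_that("removing a cue never increases the optimum", {
  prob <- random_cue_problem(4, max_cues = 6)
  full <- solve_imat(prob)$objective
  for (r in prob$R_H) {
    less <- solve_imat(imat_problem(prob$model, setdiff(prob$R_H, r),
                                    prob$R_L, prob$epsilon))$objective
    expect_gte(full, less)
    expect_lte(full - less, 1L)
  }
})

test_that("the objective is invariant under reaction reordering", {
  m <- fig_fixture()
  cs <- cue_sets(m$states)
  obj1 <- solve_imat(imat_problem(m$model, cs$R_H, cs$R_L))$objective
  perm <- rev(seq_len(nrow(m$model$reactions)))
  m2 <- m$model
  m2$reactions <- m2$reactions[perm, ]
  m2$stoich <- m2$stoich[m2$reactions$id]
  m2$gpr_trees <- m2$gpr_trees[m2$reactions$id]
  obj2 <- solve_imat(imat_problem(m2, cs$R_H, cs$R_L))$objective
  expect_equal(obj1, obj2)
})

test_that("post-transcriptional regulation flags follow the cue/flux grid", {
  m <- chain_model()
  sol <- solve_imat(imat_problem(m, R_H = "R1"))
  # low cue but active -> up; high cue but inactive -> down; else none
  states <- c(EX_A = 0L, R1 = -1L, EX_B = 0L)
  expect_equal(detect_ptr(states, sol)[["R1"]], "up")
  states <- c(EX_A = 1L, R1 = 0L, EX_B = 0L)
  sol0 <- solve_imat(imat_problem(m, R_L = c("EX_A", "EX_B", "R1")))
  expect_equal(detect_ptr(c(EX_A = 1L, R1 = 0L, EX_B = 0L), sol0)[["EX_A"]],
               "down")
  expect_equal(detect_ptr(c(EX_A = 0L, R1 = 0L, EX_B = 0L), sol0)[["R1"]],
               "none")
})
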