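test_that("uncued networks span their bounds and dead ends pin to zero", {
  m <- chain_model(lb_r1 = -1000) # fully reversible chain
  iv <- fva(m, lock = FALSE)
  # the chain couples all three reactions; with everything reversible and
  # uncued each spans the full default bounds
  for (r in m$reactions$id) {
    expect_equal(iv$min[iv$reaction == r], -1000, label = r)
    expect_equal(iv$max[iv$reaction == r], 1000, label = r)
  }
  # irreversible interior reaction caps the upstream exchange at zero
  iv2 <- fva(chain_model(), lock = FALSE)
  expect_equal(iv2$max[iv2$reaction == "EX_A"], 0)
  expect_equal(iv2$min[iv2$reaction == "R1"], 0)

  mdead <- metabolic_model(
    data.frame(id = c("A", "D"), name = c("A", "D"), compartment = "c"),
    data.frame(id = c("EX_A", "Rdead"), lb = c(-1000, 0), ub = 1000,
               gpr = "", exchange = c(TRUE, FALSE)),
    list(EX_A = c(A = -1), Rdead = c(A = -1, D = 1)))
  ivd <- fva(mdead, lock = FALSE)
  expect_equal(ivd$min[ivd$reaction == "Rdead"], 0)
  expect_equal(ivd$max[ivd$reaction == "Rdead"], 0)
})

test_that("locking the consistency optimum pins cued chains", {
  m <- chain_model() # R1 irreversible
  prob <- imat_problem(m, R_H = "R1", epsilon = 1)
  sol <- solve_imat(prob)
  iv <- fva(m, prob, lock = TRUE, solution = sol)
  expect_equal(iv$min[iv$reaction == "R1"], 1)
  expect_equal(iv$max[iv$reaction == "R1"], 1000)
  # incumbent flux always lies inside the locked intervals
  for (k in seq_len(nrow(iv))) {
    v <- sol$flux[[iv$reaction[k]]]
    expect_gte(v, iv$min[k] - 1e-6)
    expect_lte(v, iv$max[k] + 1e-6)
  }
})

test_that("locked FVA agrees with enumeration over optimal cue states", {
  # oracle: enumerate cue-satisfaction assignments achieving the optimal
  # objective; per assignment run plain per-direction LPs with tightened
  # bounds; aggregate min/max
  for (seed in c(2, 5)) {
    prob <- random_cue_problem(seed, max_cues = 5)
    m <- prob$model
    sol <- solve_imat(prob)
    iv <- fva(m, prob, lock = TRUE, solution = sol)
    S <- stoichiometric_matrix(m)
    rx <- m$reactions
    cues <- c(prob$R_H, prob$R_L)
    is_high <- cues %in% prob$R_H
    eps <- prob$epsilon
    lo0 <- rx$lb; hi0 <- rx$ub
    opts <- lapply(seq_along(cues), function(k) {
      i <- match(cues[k], rx$id)
      if (is_high[k]) {
        o <- list(NULL) # unsatisfied
        if (hi0[i] >= eps) o <- c(o, list(c(i, 1)))
        if (lo0[i] <= -eps) o <- c(o, list(c(i, -1)))
        o
      } else list(NULL, c(i, 0))
    })
    grid <- expand.grid(lapply(opts, seq_along))
    omin <- setNames(rep(Inf, nrow(rx)), rx$id)
    omax <- setNames(rep(-Inf, nrow(rx)), rx$id)
    for (g in seq_len(nrow(grid))) {
      sat <- 0L; lo <- lo0; hi <- hi0; ok <- TRUE
      for (k in seq_along(cues)) {
        ch <- opts[[k]][[grid[g, k]]]
        if (is.null(ch)) next
        sat <- sat + 1L
        i <- ch[1]
        if (ch[2] == 1) lo[i] <- max(lo[i], eps)
        else if (ch[2] == -1) hi[i] <- min(hi[i], -eps)
        else { lo[i] <- 0; hi[i] <- 0 }
        if (lo[i] > hi[i]) { ok <- FALSE; break }
      }
      if (!ok || sat != sol$objective) next
      feas <- solve_lp(rep(0, nrow(rx)), S, rep("==", nrow(S)),
                       rep(0, nrow(S)), lo, hi)
      if (!identical(feas$status, "optimal")) next
      for (j in seq_len(nrow(rx))) {
        obj <- rep(0, nrow(rx)); obj[j] <- 1
        lo_r <- solve_lp(obj, S, rep("==", nrow(S)), rep(0, nrow(S)),
                         lo, hi, maximize = FALSE)
        hi_r <- solve_lp(obj, S, rep("==", nrow(S)), rep(0, nrow(S)),
                         lo, hi, maximize = TRUE)
        omin[j] <- min(omin[j], lo_r$objval)
        omax[j] <- max(omax[j], hi_r$objval)
      }
    }
    expect_equal(iv$min, unname(omin[iv$reaction]), tolerance = 1e-6,
                 label = paste("seed", seed))
    expect_equal(iv$max, unname(omax[iv$reaction]), tolerance = 1e-6,
                 label = paste("seed", seed))
  }
})

test_that("the printed interval ordering rule is applied verbatim", {
  # A = [0,1], B = [2,10]: minA < minB and maxA <= maxB
  cmp <- compare_intervals(c(0, 1), c(2, 10), delta = 0.9)
  expect_equal(cmp$relation, "A_less")
  # identical intervals: no strict inequality anywhere
  expect_equal(compare_intervals(c(1, 5), c(1, 5))$relation, "none")
  # significance arithmetic: 0.5 <= 0.1 * 10
  cmp <- compare_intervals(c(0, 0.5), c(0, 10), delta = 0.9)
  expect_true(cmp$significant)
  cmp <- compare_intervals(c(0, 2), c(0, 10), delta = 0.9)
  expect_equal(cmp$relation, "A_less")
  expect_false(cmp$significant) # 2 > 1
})

test_that("interval comparison is antisymmetric and none is symmetric", {
  grid <- expand.grid(a1 = c(-4, 0, 1), a2 = c(1, 3), b1 = c(-4, 0, 1),
                      b2 = c(1, 3))
  grid <- grid[grid$a1 <= grid$a2 & grid$b1 <= grid$b2, ]
  for (i in seq_len(nrow(grid))) {
    A <- c(grid$a1[i], grid$a2[i]); B <- c(grid$b1[i], grid$b2[i])
    ab <- compare_intervals(A, B, 0.9)
    ba <- compare_intervals(B, A, 0.9)
    expect_false(ab$relation == "A_less" && ba$relation == "A_less")
    if (ab$relation == "A_less") expect_equal(ba$relation, "B_less")
    if (ab$relation == "none") expect_equal(ba$relation, "none")
    if (ab$significant) expect_true(ab$relation != "none")
  }
})

test_that("altered-reaction calls shrink as delta tightens", {
  set.seed(31)
  ctrl <- data.frame(reaction = paste0("r", 1:30),
                     min = runif(30, 0, 5))
  ctrl$max <- ctrl$min + runif(30, 0, 10)
  dis <- data.frame(reaction = ctrl$reaction,
                    min = ctrl$min * runif(30, 0, 1.5))
  dis$max <- dis$min + (ctrl$max - ctrl$min) * runif(30, 0, 1.5)
  n_prev <- Inf
  for (d in c(0, 0.5, 0.9)) {
    n <- nrow(altered_reactions(ctrl, dis, delta = d))
    expect_lte(n, n_prev)
    n_prev <- n
  }
  expect_error(altered_reactions(ctrl, dis[-1, ]), "different reactions")
  expect_equal(nrow(altered_reactions(ctrl, ctrl, 0.9)), 0)
})

test_that("biomarker directions follow the exchange sign convention", {
  m <- chain_model()
  base <- data.frame(reaction = c("EX_A", "R1", "EX_B"),
                     min = c(-10, 2, 2), max = c(-2, 10, 10))
  dis <- data.frame(reaction = c("EX_A", "R1", "EX_B"),
                    min = c(-1, 2, 0), max = c(0, 10, 0.5))
  calls <- call_biomarkers(base, dis, m, delta = 0.9)
  expect_setequal(calls$direction,
                  c("uptake_decrease", "secretion_decrease"))
  # secretion decrease with disjoint intervals is high-confidence
  expect_equal(calls$confidence[calls$metabolite == "B"], "high")
  expect_equal(calls$metabolite[calls$direction == "uptake_decrease"], "A")
  # interior reaction R1 never yields a biomarker
  expect_false("R1" %in% calls$reaction)
  # unchanged exchange: no call
  expect_equal(nrow(call_biomarkers(base, base, m)), 0)
})

test_that("shared biomarkers keep both contexts' directions", {
  a <- data.frame(metabolite = c("glc", "lac"), reaction = c("EX1", "EX2"),
                  direction = c("secretion_decrease", "uptake_decrease"),
                  confidence = "high")
  b <- data.frame(metabolite = c("glc", "ala"), reaction = c("EX1", "EX3"),
                  direction = c("secretion_increase", "uptake_increase"),
                  confidence = "standard")
  tab <- intersect_biomarker_calls(a, b, labels = c("cortex", "blood"))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$metabolite, "glc")
  expect_equal(tab$direction_cortex, "secretion_decrease")
  expect_equal(tab$direction_blood, "secretion_increase")
  empty <- intersect_biomarker_calls(a[0, ], b)
  expect_equal(nrow(empty), 0)
})
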