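test_that("transformation specs partition the reaction set", {
  m <- branch_model()
  src <- setNames(rep(0, 5), m$reactions$id)
  spec <- transformation_spec(m, src, R_F = "B2", R_B = "B1")
  expect_setequal(c(spec$R_F, spec$R_B, spec$R_S), m$reactions$id)
  expect_length(intersect(spec$R_F, spec$R_B), 0)
  expect_error(transformation_spec(m, src, R_F = "B1", R_B = "B1"))
  expect_error(transformation_spec(m, src, R_F = "nope"))
})

test_that("identical conditions give empty change sets", {
  m <- generate_toy_model(2, 3, seed = 6)
  ds <- simulate_expression(m, n_samples = 8, seed = 6)
  ctrl <- ds$expression[, ds$conditions == "control"]
  cs <- derive_change_sets(ctrl, ctrl, m)
  expect_length(cs$R_F, 0)
  expect_length(cs$R_B, 0)
  expect_setequal(cs$R_S, m$reactions$id)
})

test_that("a strongly shifted pathway lands in the changed sets", {
  hits <- 0L
  for (s in 1:5) {
    m <- generate_toy_model(3, 3, seed = s, cross_links = FALSE)
    spec_cfg <- list(conditions = list(
      src = list(), tgt = list(pathway_shifts = c(P2 = 3))))
    ds <- simulate_expression(m, spec_cfg, n_samples = 20, seed = 40 + s)
    cs <- derive_change_sets(ds$expression[, ds$conditions == "src"],
                             ds$expression[, ds$conditions == "tgt"], m)
    p2 <- m$reactions$id[m$reactions$pathway == "P2" &
                           nzchar(m$reactions$gpr)]
    if (all(p2 %in% cs$R_F)) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("single-sample arms fall back to the fold-change rule", {
  m <- generate_toy_model(2, 3, seed = 9, cross_links = FALSE)
  genes <- m$genes
  src <- matrix(8, length(genes), 1, dimnames = list(genes, "s1"))
  tgt <- src
  tgt[1:2, 1] <- 8 + 2.5  # beyond log2(2) = 1
  colnames(tgt) <- "t1"
  cs <- derive_change_sets(src, tgt, m, fc_threshold = 2)
  up_genes <- genes[1:2]
  up_rxns <- m$reactions$id[vapply(m$reactions$id, function(r)
    any(up_genes %in% gpr_genes(m$gpr_trees[[r]])), TRUE)]
  expect_true(all(up_rxns %in% cs$R_F))
})

test_that("wildtype achieves nothing and knockouts of idle reactions tie it", {
  m <- branch_model()
  # source state: all flux through branch 1
  src <- setNames(c(-5, 5, 0, 5, 0), m$reactions$id)
  spec <- transformation_spec(m, src, R_F = "B2", R_B = "B1")
  wt <- score_knockout(m, spec, "wildtype")
  expect_equal(wt$achieved, 0L)
  expect_equal(wt$steady_deviation, 0)
  expect_equal(wt$score, 0)
  # B2 carries no source flux and is not steady: knocking it out leaves
  # the source state reachable, so nothing changes vs wildtype
  k2 <- score_knockout(m, spec, "B2")
  expect_equal(k2$achieved, wt$achieved)
  expect_equal(k2$total_deviation, wt$total_deviation)
})

test_that("silencing the active branch forces the desired transformation", {
  m <- branch_model()
  src <- setNames(c(-5, 5, 0, 5, 0), m$reactions$id)
  spec <- transformation_spec(m, src, R_F = "B2", R_B = "B1")
  k1 <- score_knockout(m, spec, "B1")
  expect_gte(k1$achieved, 1L)
  expect_gt(k1$score, score_knockout(m, spec, "wildtype")$score)
  # a knockout inside R_F cannot count its own increase
  kf <- score_knockout(m, spec, "B2")
  expect_equal(kf$achieved, 0L)
})

test_that("scores agree with the exhaustive-enumeration oracle", {
  m <- generate_toy_model(2, 4, seed = 12, gpr_complexity = 0)
  cand <- implant_candidates(m)
  pair <- implant_knockout_pair(m, cand[1], seed = 12)
  st <- reaction_states_from_expression(m, pair$source)
  sol <- solve_imat(imat_problem(m, st$cues$R_H, st$cues$R_L))
  spec <- derive_change_sets(pair$source, pair$target, m,
                             source_flux = sol$flux)
  for (ko in c("wildtype", cand[1], sample(m$reactions$id, 3))) {
    mine <- score_knockout(m, spec, ko)
    oracle <- mta_enum_oracle(m, spec, ko)
    expect_equal(mine$achieved, oracle$achieved, label = ko)
    expect_equal(mine$total_deviation, oracle$total_deviation,
                 tolerance = 1e-5, label = ko)
  }
})

test_that("rankings are deterministic, complete and tie-broken as stated", {
  m <- branch_model()
  src <- setNames(c(-5, 5, 0, 5, 0), m$reactions$id)
  spec <- transformation_spec(m, src, R_F = "B2", R_B = "B1")
  rk <- rank_perturbations(m, spec)
  expect_equal(nrow(rk), nrow(m$reactions) + 1L)
  expect_equal(rk$rank, seq_len(nrow(rk)))
  expect_true(all(diff(rk$score) <= 1e-12))
  expect_equal(rk$percentile[1], 100)
  expect_equal(rk$percentile[nrow(rk)], 0)
  # empty change sets: every score 0
  spec0 <- transformation_spec(m, src)
  rk0 <- rank_perturbations(m, spec0)
  expect_true(all(rk0$score == 0))
})

test_that("duplicate reactions receive identical scores", {
  m <- metabolic_model(
    data.frame(id = c("S", "P"), name = c("S", "P"), compartment = "c"),
    data.frame(id = c("EX_S", "Ra", "Rb", "EX_P"),
               lb = c(-1000, 0, 0, -1000), ub = 1000,
               gpr = c("", "g1", "g2", ""),
               exchange = c(TRUE, FALSE, FALSE, TRUE)),
    list(EX_S = c(S = -1), Ra = c(S = -1, P = 1), Rb = c(S = -1, P = 1),
         EX_P = c(P = -1)))
  src <- setNames(c(-4, 2, 2, 4), m$reactions$id)
  spec <- transformation_spec(m, src, R_B = "EX_P")
  sa <- score_knockout(m, spec, "Ra")
  sb <- score_knockout(m, spec, "Rb")
  expect_equal(sa$achieved, sb$achieved)
  expect_equal(sa$score, sb$score, tolerance = 1e-9)
})

test_that("top-fraction target pathways use the stated universe", {
  m <- generate_toy_model(5, 2, seed = 21, cross_links = FALSE)
  # synthetic ranking: pathway P1's reactions on top
  rx <- m$reactions$id
  rk <- data.frame(perturbation = c(rx[order(m$reactions$pathway != "P1")],
                                    "wildtype"),
                   achieved = 0L, steady_deviation = 0, score = 0)
  rk$score <- rev(seq_len(nrow(rk)))
  rk$rank <- seq_len(nrow(rk))
  rk$percentile <- 100 * (nrow(rk) - rk$rank) / (nrow(rk) - 1)
  # top 20% of 20 reactions = P1's 4 members
  tp <- mta_target_pathways(rk, m, top_fraction = 0.2)
  expect_equal(tp$pathway[1], "P1")
  expect_equal(tp$p[1],
               1 / choose(20, 4) * choose(16, 0) * choose(4, 4) *
                 choose(20, 4) / choose(20, 4), tolerance = 1e-9)
  expect_equal(tp$p[1], choose(4, 4) * choose(16, 0) / choose(20, 4),
               tolerance = 1e-12)
  # fraction 1: every pathway fully drawn, all p = 1
  tp1 <- mta_target_pathways(rk, m, top_fraction = 1)
  expect_true(all(tp1$p == 1))
})
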