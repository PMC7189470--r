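test_that("event generation is deterministic and conserves labels", {
  sp <- flow_spec(n_events = 2000, seed = 11)
  a <- generate_flow_events(sp)
  b <- generate_flow_events(sp)
  expect_identical(a$events, b$events)
  expect_identical(a$truth, b$truth)
  ## labels partition all events
  expect_equal(length(a$truth$population), 2000)
  expect_true(all(a$truth$population %in% tiquant:::FLOW_POPULATIONS))
  tab <- table(a$truth$population)
  expect_equal(sum(tab), 2000)
})

test_that("an all-negative mixture yields no CD45+ events", {
  sp <- flow_spec(n_events = 1000,
                  population_fractions = c(macrophage = 0, dc = 0, gmdsc = 0,
                                           mmdsc = 0, other_cd45 = 0,
                                           non_cd45 = 1),
                  seed = 12)
  fl <- generate_flow_events(sp)
  thr <- c(CD45 = 1000, PI = 1000, CD11b = 1000, CD11c = 1000, MHCII = 1000,
           Ly6C = 1000, Ly6G = 1000, F480 = 1000, CD38 = 1000, CD206 = 1000)
  gates <- apply_gate_tree(fl$events, default_gate_tree(thr))
  expect_equal(gates$count[gates$name == "cd45"], 0)
  expect_true(all(gates$count[gates$name %in%
    c("macrophage", "dc", "gmdsc", "mmdsc")] == 0))
  expect_true(all(gates$flag[gates$name == "macrophage"] == "empty_parent"))
})

test_that("labelled macrophage fraction is recovered within 3 binomial SD", {
  frac <- c(macrophage = 0.45, dc = 0.08, gmdsc = 0.10, mmdsc = 0.07,
            other_cd45 = 0.30) * 0.5
  sp <- flow_spec(n_events = 10000,
                  population_fractions = c(frac, non_cd45 = 0.5), seed = 11)
  fl <- generate_flow_events(sp)
  thr <- auto_gate_thresholds(fl$events)
  gates <- apply_gate_tree(fl$events, default_gate_tree(thr))
  est <- gates$pct_of_cd45[gates$name == "macrophage"] / 100
  tr <- fl$truth$fraction_of_cd45[["macrophage"]]
  sdv <- sqrt(tr * (1 - tr) / fl$truth$n_live_cd45)
  expect_lt(abs(est - tr), 3 * sdv)
})

test_that("identity spillover is a no-op and mixing round-trips", {
  sp <- flow_spec(n_events = 500, seed = 13)
  fl <- generate_flow_events(sp)
  I10 <- diag(10); dimnames(I10) <- list(colnames(fl$events),
                                         colnames(fl$events))
  expect_equal(compensate(fl$events, I10), fl$events, tolerance = 1e-12)
  ## identity spillover in the generator equals no spillover at all
  sp2 <- flow_spec(n_events = 500, spillover = I10, seed = 13)
  expect_identical(generate_flow_events(sp2)$events, fl$events)
})

test_that("compensation inverts a hand-computed 2x2 spill", {
  ev <- data.frame(A = 100, B = 10)
  S <- matrix(c(1, 0, 0.1, 1), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  out <- compensate(ev, S)
  expect_equal(out$A, 100, tolerance = 1e-12)
  expect_equal(out$B, 0, tolerance = 1e-12)
  expect_error(compensate(ev, matrix(1, 2, 2,
    dimnames = list(c("A", "B"), c("A", "B")))), "singular")
})

test_that("mix-then-compensate is identity within 1e-6 relative", {
  err <- eval_compensation_roundtrip(n_events = 2000, seed = 14)
  expect_lt(err, 1e-6)
})

test_that("gates with -Inf thresholds pass every parent event through", {
  sp <- flow_spec(n_events = 1000, seed = 15)
  fl <- generate_flow_events(sp)
  thr <- setNames(rep(-Inf, 10), colnames(fl$events))
  tree <- list(gate_node("live", "root", thr["PI"] * -1, c(PI = -1)),
               gate_node("cd45", "live", thr["CD45"], c(CD45 = 1)),
               gate_node("macrophage", "cd45", thr[c("CD11b", "F480")],
                         c(CD11b = 1, F480 = 1)))
  ## live gate: PI < Inf keeps everything; children with -Inf keep parents
  res <- apply_gate_tree(fl$events, tree)
  expect_equal(res$count[res$name == "live"], 1000)
  expect_equal(res$count[res$name == "cd45"], 1000)
  expect_equal(res$count[res$name == "macrophage"], 1000)
})

test_that("sequential gating never resurrects an excluded event", {
  sp <- flow_spec(n_events = 5000, seed = 16)
  fl <- generate_flow_events(sp)
  thr <- auto_gate_thresholds(fl$events)
  res <- apply_gate_tree(fl$events, default_gate_tree(thr))
  memb <- attr(res, "membership")
  for (nm in c("macrophage", "dc", "gmdsc", "mmdsc"))
    expect_true(all(memb$cd45[memb[[nm]]]))
  expect_true(all(memb$live[memb$cd45]))
})

test_that("quadrant counts partition the macrophage gate exactly", {
  sp <- flow_spec(n_events = 5000,
                  macrophage_quadrant_fractions = c(M0 = 0.45, M1 = 0.15,
                                                    M2 = 0.10, co = 0.30),
                  population_fractions = c(macrophage = 0.40, dc = 0.02,
                                           gmdsc = 0.03, mmdsc = 0.02,
                                           other_cd45 = 0.13, non_cd45 = 0.40),
                  seed = 17)
  fl <- generate_flow_events(sp)
  thr <- auto_gate_thresholds(fl$events)
  res <- apply_gate_tree(fl$events, default_gate_tree(thr))
  memb <- attr(res, "membership")
  mac <- fl$events[memb$macrophage, ]
  q <- macrophage_quadrants(mac, thr["CD38"], thr["CD206"])
  expect_equal(sum(q$count), nrow(mac))
  n_mac <- fl$truth$n_live_macrophage
  for (nm in c("M0", "M1", "M2", "co")) {
    tr <- fl$truth$quadrant_fractions[[nm]]
    est <- q$pct_of_parent[q$name == nm] / 100
    expect_lt(abs(est - tr), 3 * sqrt(tr * (1 - tr) / n_mac))
  }
})

test_that("events exactly at a threshold count as positive, totals conserved", {
  ev <- data.frame(CD38 = c(1, 2, 2, 3), CD206 = c(5, 5, 7, 7))
  q <- macrophage_quadrants(ev, cd38_thr = 2, cd206_thr = 7)
  expect_equal(sum(q$count), 4)
  expect_equal(q$count[q$name == "M0"], 1)   # (1,5)
  expect_equal(q$count[q$name == "M1"], 1)   # (2,5): CD38 at threshold
  expect_equal(q$count[q$name == "co"], 2)   # (2,7) and (3,7)
})

test_that("all events below both thresholds are M0", {
  ev <- data.frame(CD38 = runif(50, 0, 1), CD206 = runif(50, 0, 1))
  q <- macrophage_quadrants(ev, 2, 2)
  expect_equal(q$pct_of_parent[q$name == "M0"], 100)
})

test_that("raising the CD38 threshold never increases the CD38+ fraction", {
  set.seed(18)
  ev <- data.frame(CD38 = rlnorm(2000, 5, 1), CD206 = rlnorm(2000, 5, 1))
  f <- vapply(c(50, 100, 200, 400, 800), function(t) {
    q <- macrophage_quadrants(ev, t, 150)
    sum(q$count[q$name %in% c("M1", "co")])
  }, numeric(1))
  expect_true(all(diff(f) <= 0))
})

test_that("viability is the PI-negative fraction", {
  ev <- data.frame(PI = c(0, 0, 0, 10))
  expect_equal(viability_fraction(ev, 5), 75)
  expect_equal(viability_fraction(data.frame(PI = rep(0, 10)), 1), 100)
  expect_error(viability_fraction(data.frame(PI = numeric(0)), 1), "empty")
  ## planted 40% dead recovered within 3 binomial SD
  sp <- flow_spec(n_events = 10000, live_fraction = 0.6, seed = 19)
  fl <- generate_flow_events(sp)
  thr <- valley_threshold(fl$events$PI)
  expect_lt(abs(viability_fraction(fl$events, thr) - 60),
            300 * sqrt(0.6 * 0.4 / 10000))
})

test_that("fraction sum and spillover invariants are validated", {
  expect_error(flow_spec(population_fractions = c(macrophage = 0.5, dc = 0.1,
    gmdsc = 0.1, mmdsc = 0.1, other_cd45 = 0.1, non_cd45 = 0.2)), "sum to 1")
  S <- diag(10) * 2
  dimnames(S) <- list(tiquant:::FLOW_CHANNELS, tiquant:::FLOW_CHANNELS)
  expect_error(flow_spec(spillover = S), "diagonal")
})

test_that("gate trees round-trip through YAML", {
  thr <- setNames(rep(100, 10), tiquant:::FLOW_CHANNELS)
  tree <- default_gate_tree(thr)
  path <- tempfile(fileext = ".yaml")
  write_gate_tree(tree, path)
  back <- read_gate_tree(path)
  expect_equal(length(back), length(tree))
  expect_equal(back[[3]]$name, tree[[3]]$name)
  expect_equal(back[[3]]$thresholds, tree[[3]]$thresholds)
  expect_equal(back[[3]]$signs, tree[[3]]$signs)
})
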