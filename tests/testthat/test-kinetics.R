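# Closed-form rate formulas, and Monte-Carlo frequency checks that the
# engine's empirical event rates match those formulas within binomial
# 3-sigma bands.

test_that("rate formulas reproduce the published closed forms", {
  p <- sim_params()
  expect_equal(end_decay_probability(FALSE, p), 1e-4)
  expect_equal(end_decay_probability(TRUE, p), 1e-6)
  expect_equal(bond_break_probability(FALSE, p), 1e-5)
  expect_equal(bond_break_probability(TRUE, p), (1e-5)^1.5)
  expect_equal(separation_probability(1, p), 0.3)
  expect_equal(separation_probability(3, p), 0.09)
  # strictly decreasing in the number of base pairs
  expect_true(all(diff(separation_probability(1:30, p)) < 0))
  expect_error(separation_probability(0, p), ">= 1")
  expect_equal(movement_probability(precursor("D"), p), 0.002)
  expect_equal(movement_probability(rna_chain("ACGU", "D"), p), 1e-4 / 2)
  expect_equal(movement_probability(nucleotide("A", "D"), p), 1e-4)
  expect_equal(movement_probability(9, p), 1e-4 / 3)
  # all formulas stay in [0, 1] across parameter extremes
  for (ps in list(zero_params(), sim_params(P_NDE = 1, P_BB = 1, P_SP = 1,
                                            P_MN = 1, P_MPN = 1))) {
    expect_true(all(end_decay_probability(c(TRUE, FALSE), ps) >= 0 &
                      end_decay_probability(c(TRUE, FALSE), ps) <= 1))
    expect_true(all(separation_probability(1:10, ps) >= 0 &
                      separation_probability(1:10, ps) <= 1))
    expect_true(all(movement_probability(1:10, ps) >= 0 &
                      movement_probability(1:10, ps) <= 1))
  }
})

test_that("precursor racemization matches P_CIC and only flips precursors", {
  n <- 1e5
  st <- make_state(1, precursors = prec_df(n, "D"))
  # P_CIC = 0: chirality never flips
  out <- step_once(st, zero_params(N = 1), seed = 1)
  expect_equal(sum(out$state$precursors$chirality == "L"), 0L)
  # published default P_CIC = 0.5
  out <- step_once(st, zero_params(N = 1, P_CIC = 0.5), seed = 2)
  expect_binomial(sum(out$state$precursors$chirality == "L"), n, 0.5,
                  "racemization (P_CIC = 0.5)")
  # a non-symmetric rate
  out <- step_once(st, zero_params(N = 1, P_CIC = 0.2), seed = 3)
  expect_binomial(sum(out$state$precursors$chirality == "L"), n, 0.2,
                  "racemization (P_CIC = 0.2)")
  # involution at the single-event level
  pr <- precursor("D")
  ev <- racemize(pr, sim_params(P_CIC = 1))
  ev2 <- racemize(ev$products[[1]], sim_params(P_CIC = 1))
  expect_equal(ev2$products[[1]]$chirality, "D")
})

test_that("nucleotide formation matches P_NF, draws uniform bases and keeps handedness", {
  n <- 2e5
  st <- make_state(1, precursors = prec_df(n, "L"))
  out <- step_once(st, zero_params(N = 1, P_NF = 0.001), seed = 4)
  formed <- out$state$chains
  expect_binomial(nrow(formed), n, 0.001, "non-enzymatic formation")
  expect_true(all(formed$chir == "L"))
  # base uniformity at a high rate for statistical power
  out <- step_once(st, zero_params(N = 1, P_NF = 0.5), seed = 5)
  counts <- table(factor(out$state$chains$seq, levels = c("A", "U", "C", "G")))
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
  # mass is conserved: precursors + nucleotides = n
  expect_equal(nrow(out$state$chains) + nrow(out$state$precursors), n)
})

test_that("NSR catalysis uses P_NFR with per-room credit accounting", {
  # one NSR and one same-handed precursor per room, over 10^4 rooms
  N <- 100
  rooms <- expand.grid(row = 0:(N - 1), col = 0:(N - 1))
  nsr <- chain_df(rep("ACUGGC", N * N), rep("DDDDDD", N * N),
                  row = rooms$row, col = rooms$col)
  prec <- prec_df(N * N, "D", row = rooms$row, col = rooms$col)
  st <- make_state(N, precursors = prec, chains = nsr)
  out <- step_once(st, zero_params(N = N, P_NFR = 0.2), seed = 6)
  formed <- sum(nchar(out$state$chains$seq) == 1)
  expect_binomial(formed, N * N, 0.2, "NSR-catalysed formation")
  # opposite-handed precursors see no credit and fall back to P_NF = 0
  stL <- make_state(N, precursors = prec_df(N * N, "L", rooms$row, rooms$col),
                    chains = nsr)
  outL <- step_once(stL, zero_params(N = N, P_NFR = 0.2), seed = 7)
  expect_equal(sum(nchar(outL$state$chains$seq) == 1), 0L)
  # credit ceiling: 5 precursors but one NSR -> exactly one catalysis at
  # P_NFR = 1 per room
  st5 <- make_state(N, precursors = prec_df(5 * N * N, "D",
                                            rep(rooms$row, each = 5),
                                            rep(rooms$col, each = 5)),
                    chains = nsr)
  out5 <- step_once(st5, zero_params(N = N, P_NFR = 1), seed = 8)
  expect_equal(sum(nchar(out5$state$chains$seq) == 1), N * N)
})

test_that("free nucleotide decay matches P_ND and keeps handedness", {
  n <- 1e5
  st <- make_state(1, chains = chain_df(rep("A", n), rep("D", n)))
  out <- step_once(st, zero_params(N = 1, P_ND = 0.01), seed = 9)
  expect_binomial(nrow(out$state$precursors), n, 0.01, "nucleotide decay")
  expect_true(all(out$state$precursors$chirality == "D"))
  # P_ND = 0: never decays
  out0 <- step_once(st, zero_params(N = 1), seed = 10)
  expect_equal(nrow(out0$state$precursors), 0L)
})

test_that("chain-end decay matches P_NDE single-strand and P_NDE^(3/2) duplex", {
  n <- 2e4
  # single-stranded 3-mers: two ends each
  st <- make_state(1, chains = chain_df(rep("AUC", n), rep("DDD", n)))
  out <- step_once(st, zero_params(N = 1, P_NDE = 0.05), seed = 11)
  expect_binomial(nrow(out$state$precursors), 2 * n, 0.05,
                  "single-strand end decay")
  # full duplexes: both template ends are paired, so both strands lose the
  # terminal pair at P_NDE^(3/2)
  cxs <- lapply(seq_len(n), function(i)
    complex_spec(0, 0, "AAAA", "DDDD", 0, "UUUU", "DDDD"))
  std <- make_state(1, complexes = cxs)
  p2 <- 0.09^1.5
  outd <- step_once(std, zero_params(N = 1, P_NDE = 0.09), seed = 12)
  # each firing end releases two residues (one per strand)
  fired <- nrow(outd$state$precursors) / 2
  expect_binomial(fired, 2 * n, p2, "duplex end decay")
})

test_that("bond breaking matches P_BB single-strand and P_BB^(3/2) duplex", {
  n <- 2e4
  # free dimers have one single-strand bond each; a break adds one chain
  st <- make_state(1, chains = chain_df(rep("AU", n), rep("DD", n)))
  out <- step_once(st, zero_params(N = 1, P_BB = 0.02), seed = 13)
  expect_binomial(nrow(out$state$chains) - n, n, 0.02,
                  "single-strand bond break")
  # full 2-bp duplexes have one pair of parallel bonds; a double break
  # yields two 1-bp complexes
  cxs <- lapply(seq_len(n), function(i)
    complex_spec(0, 0, "AA", "DD", 0, "UU", "DD"))
  std <- make_state(1, complexes = cxs)
  outd <- step_once(std, zero_params(N = 1, P_BB = 0.04), seed = 14)
  expect_binomial(length(outd$state$complexes) - n, n, 0.04^1.5,
                  "duplex double bond break")
  # fragments partition the residues: total mass unchanged
  expect_equal(state_mass(outd$state), 4L * n)
})

test_that("duplex separation matches P_SP^((r+1)/2)", {
  n <- 2e4
  cxs <- lapply(seq_len(n), function(i)
    complex_spec(0, 0, "AAA", "DDD", 0, "UUU", "DDD"))  # r = 3
  st <- make_state(1, complexes = cxs)
  out <- step_once(st, zero_params(N = 1, P_SP = 0.3), seed = 15)
  separated <- n - length(out$state$complexes)
  expect_binomial(separated, n, 0.3^2, "separation at r = 3")
  # separation frees the template and each substrate as single strands
  expect_equal(nrow(out$state$chains), 2L * separated)
})

test_that("movement matches P_MPN for precursors and P_MN/sqrt(m) for chains", {
  n <- 1e5
  st <- make_state(10, precursors = prec_df(n, "D", row = 4, col = 4))
  out <- step_once(st, zero_params(N = 10, P_MPN = 0.2), seed = 16)
  stay <- sum(out$state$precursors$row == 4 & out$state$precursors$col == 4)
  expect_binomial(n - stay, n, 0.2, "precursor movement")
  # movers land only in the four von Neumann neighbours
  moved <- out$state$precursors[!(out$state$precursors$row == 4 &
                                    out$state$precursors$col == 4), ]
  expect_true(all(paste(moved$row, moved$col) %in%
                    c("3 4", "5 4", "4 3", "4 5")))
  # a 4-mer moves at P_MN / 2
  m <- 4e4
  stc <- make_state(10, chains = chain_df(rep("AUCG", m), rep("DDDD", m),
                                          row = 4, col = 4))
  outc <- step_once(stc, zero_params(N = 10, P_MN = 0.2), seed = 17)
  stayc <- sum(outc$state$chains$row == 4 & outc$state$chains$col == 4)
  expect_binomial(m - stayc, m, 0.1, "4-mer movement")
})
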