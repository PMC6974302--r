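test_that("cross-inhibition blocking is a heterochiral terminal junction", {
  expect_true(end_blocked(rna_chain("AAAU", "DDDL"), "back"))
  expect_false(end_blocked(rna_chain("AAAU", "DDDL"), "front"))
  expect_false(end_blocked(rna_chain("AAAA", "DDDD"), "back"))
  expect_false(end_blocked(rna_chain("AAAA", "LLLL"), "front"))
  # a single nucleotide has no junction and is never blocked
  expect_false(end_blocked(nucleotide("A", "L"), "back"))
  # breaking behind the junction leaves an unblocked homochiral fragment
  expect_false(end_blocked(rna_chain("AAA", "DDD"), "back"))
})

test_that("surface ligation rate combines base rate, primer ladder and chiral selection", {
  p <- sim_params(P_RL = 1e-6, F_CSS = 0.5)
  lad <- primer_ladder(1, 10, 200)
  # primer effect: extension from a long polymer is 20 x the dimer rate and
  # 200 x the monomer rate
  r1 <- surface_ligation_rate("D", "D", 1, p, lad)
  r2 <- surface_ligation_rate("D", "D", 2, p, lad)
  rn <- surface_ligation_rate("D", "D", 7, p, lad)
  expect_equal(r1, 1e-6)
  expect_equal(r2 / r1, 10)
  expect_equal(rn / r2, 20)
  expect_equal(rn / r1, 200)
  # chiral selection factor
  expect_equal(surface_ligation_rate("D", "L", 3, p, lad),
               surface_ligation_rate("D", "D", 3, p, lad) * 0.5)
  # complete selection forbids opposite-handed incorporation
  p0 <- sim_params(P_RL = 1e-6, F_CSS = 0)
  expect_equal(surface_ligation_rate("D", "L", 3, p0, lad), 0)
  # uniform ladder and F_CSS = 1: no primer effect, no selection
  p1 <- sim_params(P_RL = 1e-6, F_CSS = 1)
  expect_equal(surface_ligation_rate("D", "L", 5, p1, primer_ladder()),
               surface_ligation_rate("L", "L", 1, p1, primer_ladder()))
  # effective rates are clamped to 1
  expect_equal(surface_ligation_rate("D", "D", 4, sim_params(P_RL = 0.9),
                                     primer_ladder(1, 1, 200)), 1)
})

test_that("template ligation rate applies F_CST and blocking", {
  p <- sim_params(P_TL = 0.002, F_CST = 0.5)
  expect_equal(template_ligation_rate("D", "D", "D", 4, p), 0.002)
  expect_equal(template_ligation_rate("L", "D", "D", 4, p), 0.001)
  expect_equal(template_ligation_rate("D", "D", "L", 4, p), 0.001)
  expect_equal(template_ligation_rate("D", "D", "D", 4, p, blocked = TRUE), 0)
  p0 <- sim_params(P_TL = 0.002, F_CST = 0)
  expect_equal(template_ligation_rate("L", "D", "D", 4, p0), 0)
})

test_that("attraction probability multiplies P_FP per mismatch", {
  p <- sim_params(P_AT = 0.5, P_FP = 0.001)
  expect_equal(attraction_probability("A", "U", p), 0.5)
  expect_equal(attraction_probability("A", "A", p), 5e-4)
  expect_equal(attraction_probability("AC", "UG", p), 0.5)
  expect_equal(attraction_probability("AC", "UC", p), 5e-4)
  expect_equal(attraction_probability("AC", "AC", p), 0.5 * 1e-6)
  expect_error(attraction_probability("AC", "A", p), "equal length")
})

test_that("surface ligation in the engine matches the closed-form rate", {
  # two homochiral D 3-mers per room over 10^4 rooms, one collision round;
  # the collision picks the ligation branch with probability 1/2 and then
  # ligates at P_RL x R3
  N <- 100
  rooms <- expand.grid(row = 0:(N - 1), col = 0:(N - 1))
  ch <- chain_df(rep("AAA", 2 * N * N), rep("DDD", 2 * N * N),
                 row = rep(rooms$row, each = 2), col = rep(rooms$col, each = 2))
  st <- make_state(N, chains = ch)
  lad <- primer_ladder(1, 1, 10)
  out <- step_once(st, zero_params(N = N, P_RL = 0.04, C_T = 1), seed = 20,
                   surface_ladder = lad)
  merged <- sum(nchar(out$state$chains$seq) == 6)
  expect_binomial(merged, N * N, 0.5 * 0.04 * 10, "surface ligation")
  # opposite-handed pairs ligate at the F_CSS-reduced rate
  ch2 <- chain_df(rep(c("AAA", "AAA"), N * N),
                  rep(c("DDD", "LLL"), N * N),
                  row = rep(rooms$row, each = 2),
                  col = rep(rooms$col, each = 2))
  st2 <- make_state(N, chains = ch2)
  out2 <- step_once(st2, zero_params(N = N, P_RL = 0.04, F_CSS = 0.5,
                                     C_T = 1),
                    seed = 21, surface_ladder = lad)
  merged2 <- sum(nchar(out2$state$chains$seq) == 6)
  expect_binomial(merged2, N * N, 0.5 * 0.04 * 10 * 0.5,
                  "cross-chiral surface ligation")
  # P_RL = 0: no ligation ever
  out0 <- step_once(st, zero_params(N = N, C_T = 8), seed = 22)
  expect_equal(sum(nchar(out0$state$chains$seq) == 6), 0L)
})

test_that("template attraction in the engine matches P_AT and P_FP", {
  N <- 100
  rooms <- expand.grid(row = 0:(N - 1), col = 0:(N - 1))
  # complementary monomer onto a 6-mer template: success at P_AT, halved by
  # the branch choice between ligation and attraction
  ch <- chain_df(rep(c("AAAAAA", "U"), N * N),
                 rep(c("DDDDDD", "D"), N * N),
                 row = rep(rooms$row, each = 2),
                 col = rep(rooms$col, each = 2))
  st <- make_state(N, chains = ch)
  out <- step_once(st, zero_params(N = N, P_AT = 0.5, C_T = 1), seed = 23)
  expect_binomial(length(out$state$complexes), N * N, 0.25,
                  "complementary attraction")
  # mismatched monomer: P_AT x P_FP
  chm <- chain_df(rep(c("AAAAAA", "A"), N * N),
                  rep(c("DDDDDD", "D"), N * N),
                  row = rep(rooms$row, each = 2),
                  col = rep(rooms$col, each = 2))
  stm <- make_state(N, chains = chm)
  outm <- step_once(stm, zero_params(N = N, P_AT = 0.5, P_FP = 0.1,
                                     C_T = 1), seed = 24)
  expect_binomial(length(outm$state$complexes), N * N, 0.5 * 0.5 * 0.1,
                  "mismatched attraction")
  # P_AT = 0 disables template-directed synthesis entirely
  out0 <- step_once(st, zero_params(N = N, C_T = 8), seed = 25)
  expect_equal(length(out0$state$complexes), 0L)
})

test_that("template-directed ligation matches P_TL, F_CST and REP catalysis", {
  n <- 1e4
  mk <- function(chirB) lapply(seq_len(n), function(i)
    complex_spec(0, 0, "AAAA", "DDDD", c(0, 2), c("UU", "UU"),
                 c("DD", chirB)))
  # same-handed junction: P_TL
  st <- make_state(1, complexes = mk("DD"))
  out <- step_once(st, zero_params(N = 1, P_TL = 0.4), seed = 26)
  lig <- sum(vapply(out$state$complexes,
                    function(cx) length(cx$att_seq) == 1L, TRUE))
  expect_binomial(lig, n, 0.4, "template ligation")
  # opposite-handed junction: P_TL x F_CST
  st2 <- make_state(1, complexes = mk("LL"))
  out2 <- step_once(st2, zero_params(N = 1, P_TL = 0.4, F_CST = 0.5),
                    seed = 27)
  lig2 <- sum(vapply(out2$state$complexes,
                     function(cx) length(cx$att_seq) == 1L, TRUE))
  expect_binomial(lig2, n, 0.2, "cross-chiral template ligation")
  # complete chiral selection: opposite-handed junctions never ligate
  out0 <- step_once(st2, zero_params(N = 1, P_TL = 0.4, F_CST = 0),
                    seed = 28)
  expect_true(all(vapply(out0$state$complexes,
                         function(cx) length(cx$att_seq) == 2L, TRUE)))
  # REP catalysis: an all-D junction with a D-REP in the room ligates at
  # P_TLR even when P_TL = 0
  N <- 100
  rooms <- expand.grid(row = 0:(N - 1), col = 0:(N - 1))
  rep_ch <- chain_df(rep("GUUCAG", N * N), rep("DDDDDD", N * N),
                     rooms$row, rooms$col)
  cxs <- lapply(seq_len(N * N), function(i)
    complex_spec(rooms$row[i], rooms$col[i], "AAAA", "DDDD", c(0, 2),
                 c("UU", "UU"), c("DD", "DD")))
  str <- make_state(N, chains = rep_ch, complexes = cxs)
  outr <- step_once(str, zero_params(N = N, P_TLR = 0.9), seed = 29)
  ligr <- sum(vapply(outr$state$complexes,
                     function(cx) length(cx$att_seq) == 1L, TRUE))
  expect_binomial(ligr, N * N, 0.9, "REP-catalysed ligation")
  # credit ceiling: one REP cannot catalyse two junctions in one step
  cx2 <- c(lapply(seq_len(N * N), function(i)
    complex_spec(rooms$row[i], rooms$col[i], "AAAA", "DDDD", c(0, 2),
                 c("UU", "UU"), c("DD", "DD"))),
    lapply(seq_len(N * N), function(i)
      complex_spec(rooms$row[i], rooms$col[i], "AAAA", "DDDD", c(0, 2),
                   c("UU", "UU"), c("DD", "DD"))))
  st2r <- make_state(N, chains = rep_ch, complexes = cx2)
  out2r <- step_once(st2r, zero_params(N = N, P_TLR = 1), seed = 30)
  lig2r <- sum(vapply(out2r$state$complexes,
                      function(cx) length(cx$att_seq) == 1L, TRUE))
  expect_equal(lig2r, N * N)
})

test_that("complete chiral selection keeps every chain homochiral", {
  p <- zero_params(N = 6, T_NPB = 400, P_CIC = 0.5, P_NF = 0.05, P_ND = 0.01,
                   P_RL = 0.01, P_AT = 0.5, P_TL = 0.05, P_SP = 0.3,
                   P_MN = 1e-3, P_MPN = 2e-3, F_CSS = 0, F_CST = 0)
  cfg <- sim_config(p, steps = 2000, seed = 31, record_every = 2000)
  tr <- run_sim(cfg)
  chirs <- all_chirs(tr$final_state)
  expect_gt(length(chirs), 10)          # polymerization actually happened
  expect_true(any(nchar(chirs) > 2))    # including real oligomers
  expect_true(all(vapply(chirs, is_homochiral, TRUE)))
})

test_that("without termination chimeric chains with several switches arise", {
  p <- zero_params(N = 4, T_NPB = 300, P_CIC = 0.5, P_NF = 0.1,
                   P_RL = 0.5, F_CSS = 1)
  cfg <- sim_config(p, steps = 1500, seed = 32, record_every = 1500,
                    no_termination = TRUE)
  tr <- run_sim(cfg)
  sw <- vapply(all_chirs(tr$final_state), n_switches, 1L)
  expect_gt(max(sw), 1L)
  # with termination on, extension through a blocked end is impossible, so
  # under the same conditions chains stay far shorter
  cfg2 <- sim_config(p, steps = 1500, seed = 32, record_every = 1500)
  tr2 <- run_sim(cfg2)
  expect_gt(max(nchar(all_chirs(tr$final_state))),
            max(nchar(all_chirs(tr2$final_state))))
})

test_that("ligation and attraction preserve residues exactly", {
  # a successful surface ligation concatenates without altering residues
  st <- make_state(1, chains = chain_df(c("AUC", "GGG"), c("DDD", "DDD")))
  out <- step_once(st, zero_params(N = 1, P_RL = 1, C_T = 1), seed = 40)
  if (nrow(out$state$chains) == 1) {
    sq <- out$state$chains$seq
    expect_equal(nchar(sq), 6L)
    expect_equal(sort(strsplit(sq, "")[[1]]),
                 sort(c("A", "U", "C", "G", "G", "G")))
  }
  expect_equal(state_mass(out$state), 6L)
})
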