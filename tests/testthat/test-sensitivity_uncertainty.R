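test_that("parameter registry addresses every tunable input", {
  ids <- param_ids(uk_fix)
  expect_true(all(c("utilities.u_pf", "second_line_uptake",
                    "arms.Gefitinib+PbCT.hr_pfs",
                    "arms.Gefitinib.acq_maintenance",
                    "sae_costs.neutropenia") %in% ids))
  for (id in ids) expect_s3_class(get_param(uk_fix, id), "param_value")
  expect_error(get_param(uk_fix, "no.such.param"), "unknown parameter")
  # set_param changes only the named parameter
  mod <- set_param(uk_fix, "utilities.u_pf", 0.5)
  expect_equal(get_param(mod, "utilities.u_pf")$base, 0.5)
  others <- setdiff(ids, "utilities.u_pf")
  expect_equal(vapply(others, function(i) get_param(mod, i)$base, numeric(1)),
               vapply(others, function(i) get_param(uk_fix, i)$base, numeric(1)))
})

test_that("one-way analysis varies a single parameter over its stated range", {
  ti <- tiny_inputs()
  comparison <- c("TKI1", "Reference")
  base <- run_all(ti, arms = comparison)
  base_icer <- icer(base[1, ], base[2, ])$value
  # zero-width range collapses to the base-case ICER
  ti$management_costs$bsc_per_week <- param_value(100, 100, 100)
  ow <- one_way(ti, "management_costs.bsc_per_week", comparison)
  expect_equal(ow$low_icer, ow$high_icer)
  # a parameter with a real range brackets and moves the ICER monotonically
  ow2 <- one_way(ti, "arms.TKI1.acq_maintenance", comparison)
  expect_lt(ow2$low_icer, ow2$high_icer)  # dearer drug, dearer ICER
  # the original inputs are untouched (frozen-input audit)
  expect_equal(run_all(ti, arms = comparison)$cost, base$cost, tolerance = 1e-9)
})

test_that("the most influential parameters for combination chemotherapy vs
           reference chemotherapy are the PFS HR, PF utility and OS HR", {
  ids <- c("arms.Gefitinib+PbCT.hr_pfs", "arms.Gefitinib+PbCT.hr_os",
           "utilities.u_pf", "utilities.u_pd",
           "arms.Gefitinib+PbCT.acq_chemo_phase",
           "arms.Gefitinib+PbCT.acq_maintenance",
           "management_costs.pf_per_week", "management_costs.bsc_per_week",
           "management_costs.terminal_one_off", "second_line_uptake",
           "discount_rate_annual", "sae_costs.neutropenia",
           "sae_costs.febrile_neutropenia", "admin_costs.infusion_per_week",
           "second_line_costs.docetaxel_per_week")
  tor <- tornado(uk_fix, comparison = c("Gefitinib+PbCT", "PfCT"), ids = ids)
  expect_setequal(tor$param[1:3],
                  c("arms.Gefitinib+PbCT.hr_pfs", "arms.Gefitinib+PbCT.hr_os",
                    "utilities.u_pf"))
})

test_that("scenario analyses apply their documented overrides", {
  base <- run_all(china_fix)
  # replacing the progressed-disease utility with 0.473 raises every arm's QALYs
  alt <- run_scenario(china_fix, "alt_utilities")
  expect_true(all(alt$qaly > base$qaly))
  expect_equal(alt$cost, base$cost, tolerance = 1e-9)
  # mature osimertinib OS data raise osimertinib's QALYs
  fla <- run_scenario(china_fix, "flaura_os_update")
  expect_gt(fla$qaly[fla$arm == "Osimertinib"], base$qaly[base$arm == "Osimertinib"])
  expect_equal(fla$qaly[fla$arm != "Osimertinib"],
               base$qaly[base$arm != "Osimertinib"], tolerance = 1e-12)
  # second-line osimertinib for T790M carriers raises TKI-class arm costs
  t79 <- run_scenario(china_fix, "t790m_osimertinib_second_line")
  tki_class <- vapply(china_fix$arms, function(a)
    a$second_line_pathway == "pem_platinum_then_docetaxel", logical(1))
  nm <- arm_names(china_fix)[tki_class]
  expect_true(all(t79$cost[t79$arm %in% nm] >= base$cost[base$arm %in% nm]))
  expect_equal(t79$cost[!t79$arm %in% nm], base$cost[!base$arm %in% nm],
               tolerance = 1e-9)
  # BNF list prices raise gefitinib-containing arm costs well above the
  # procurement-price base case, leaving the reference chemotherapy undominated
  bnf <- run_scenario(uk_fix, "bnf_prices_uk")
  base_uk <- run_all(uk_fix)
  expect_gt(bnf$cost[bnf$arm == "Gefitinib"],
            base_uk$cost[base_uk$arm == "Gefitinib"] + 10000)
  expect_gt(bnf$cost[bnf$arm == "Gefitinib"], bnf$cost[bnf$arm == "PfCT"])
  fr_bnf <- build_frontier(bnf)
  expect_false(identical(
    fr_bnf$classification[fr_bnf$arm == "PfCT"], "dominated") &&
      fr_bnf$cost[fr_bnf$arm == "Gefitinib"] <= fr_bnf$cost[fr_bnf$arm == "PfCT"])
  expect_error(run_scenario(china_fix, "bnf_prices_uk"), "UK")
  expect_error(run_scenario(uk_fix, "no_such_scenario"))
})

test_that("probabilistic draws are reproducible and distribution-faithful", {
  s1 <- sample_params(uk_fix, 123)
  s2 <- sample_params(uk_fix, 123)
  expect_equal(s1, s2, tolerance = 0)
  s3 <- sample_params(uk_fix, 124)
  expect_false(isTRUE(all.equal(s3$utilities$u_pf$base, s1$utilities$u_pf$base)))
  # sampled inputs remain structurally valid
  expect_silent(validate_inputs(s1))
  # fixed parameters never move
  expect_equal(s1$sae_costs$hair_loss$base, 0)
  # joint Weibull draws move both the scale and the shape
  expect_false(s1$pfs_ref$scale == uk_fix$pfs_ref$scale)
  expect_false(s1$pfs_ref$shape == uk_fix$pfs_ref$shape)
  # marginal spread of many draws matches the printed 95% range of the scale
  draws <- vapply(1:400, function(s) sample_params(uk_fix, s)$pfs_ref$scale,
                  numeric(1))
  expect_equal(unname(quantile(draws, 0.975)), 0.0625, tolerance = 0.08)
  expect_equal(unname(quantile(draws, 0.025)), 0.0359, tolerance = 0.08)
})

test_that("the PSA is seed-deterministic and composes with sample_params", {
  arms <- c("Gefitinib", "PfCT")
  p1 <- run_psa(uk_fix, n = 5, seed = 11, arms = arms)
  p2 <- run_psa(uk_fix, n = 5, seed = 11, arms = arms)
  expect_equal(p1, p2, tolerance = 0)
  # n = 1 is exactly one sample_params followed by one model run
  p3 <- run_psa(uk_fix, n = 1, seed = 17, arms = arms)
  si <- sample_params(uk_fix, attr(p3, "seeds")[1])
  manual <- run_all(si, arms = arms)
  expect_equal(p3$cost, manual$cost, tolerance = 1e-12)
  expect_equal(p3$qaly, manual$qaly, tolerance = 1e-12)
})

test_that("PSA means stabilise with iteration count", {
  arms <- c("Gefitinib", "PfCT")
  small <- run_psa(china_fix, n = 40, seed = 3, arms = arms)
  large <- run_psa(china_fix, n = 400, seed = 4, arms = arms)
  for (a in arms) {
    mu_s <- mean(small$cost[small$arm == a])
    xs <- large$cost[large$arm == a]
    se <- sd(xs) * sqrt(1 / 40 + 1 / 400)
    expect_lt(abs(mu_s - mean(xs)), 4 * se)
  }
})

test_that("CEAC probabilities are coherent", {
  arms <- c("Gefitinib", "Gefitinib+PbCT", "PfCT")
  ps <- run_psa(uk_fix, n = 60, seed = 5, arms = arms)
  thr <- c(0, 10000, 20000, 50000, 100000)
  cc <- ceac(ps, thr)
  sums <- tapply(cc$probability, cc$threshold, sum)
  expect_equal(as.vector(sums), rep(1, length(thr)), tolerance = 1e-9)
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  # threshold 0: the cheapest arm per iteration wins
  win0 <- tapply(seq_len(nrow(ps)), ps$iteration, function(i)
    ps$arm[i][which.min(ps$cost[i])])
  p0 <- table(factor(win0, levels = arms)) / length(win0)
  cc0 <- cc[cc$threshold == 0, ]
  expect_equal(cc0$probability[match(arms, cc0$arm)], unname(as.vector(p0)),
               tolerance = 1e-9)
  # single arm: probability one everywhere
  cc1 <- ceac(ps[ps$arm == "Gefitinib", ], thr)
  expect_equal(cc1$probability, rep(1, length(thr)))
})

test_that("two deterministic point clouds cross over at their ICER", {
  # arm A: (100, 1), arm B: (200, 2) in every iteration -> ICER 100
  n <- 10
  ps <- rbind(data.frame(iteration = 1:n, arm = "A", cost = 100, qaly = 1),
              data.frame(iteration = 1:n, arm = "B", cost = 200, qaly = 2))
  cc <- ceac(ps, c(50, 100, 150))
  getp <- function(thr, arm) cc$probability[cc$threshold == thr & cc$arm == arm]
  expect_equal(getp(50, "A"), 1)
  expect_equal(getp(150, "B"), 1)
  # exact tie at the crossover threshold is split equally
  expect_equal(getp(100, "A"), 0.5)
  expect_equal(getp(100, "B"), 0.5)
})
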