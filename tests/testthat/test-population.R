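test_that("uniform sampling respects bounds, moments and the seed", {
  base <- table1_params("baseline")
  m <- sample_parameters(20000, base, seed = 5)
  b <- free_params(base)
  for (k in colnames(m)) {
    expect_gte(min(m[, k]), 0)
    expect_lte(max(m[, k]), 5 * b[[k]])
    # mean of U(0, 5b) is 2.5b; allow 3 standard errors
    se <- 5 * b[[k]] / sqrt(12) / sqrt(nrow(m))
    expect_lt(abs(mean(m[, k]) - 2.5 * b[[k]]), 3 * se)
  }
  expect_identical(m, sample_parameters(20000, base, seed = 5))
  expect_false(identical(m[1, ], sample_parameters(1, base, seed = 6)[1, ]))
})

test_that("classification is inclusive at the bounds and rejects failures", {
  b <- table2_bounds("nonCF")
  on_edge <- setNames(b[, "lower"], rownames(b))
  expect_equal(classify_observables(on_edge, b), "accepted")
  outside <- on_edge
  outside[["V_t"]] <- b["V_t", "lower"] - 1e-9
  expect_equal(classify_observables(outside, b), "rejected")
  flagged <- on_edge
  attr(flagged, "physiological") <- FALSE
  expect_equal(classify_observables(flagged, b), "rejected")
  expect_equal(classify_observables(
    evaluate_observables(transport_params(0, 0, 0, 0, 0, 0, P_pa = 0)), b),
    "rejected")
})

test_that("fitted columns pass their own condition's filter", {
  expect_equal(classify_observables(
    evaluate_observables(table1_params("nonCF")), table2_bounds("nonCF")),
    "accepted")
  expect_equal(classify_observables(
    evaluate_observables(table1_params("CF")), table2_bounds("CF")),
    "accepted")
})

test_that("filter labels are consistent and accepted sets are disjoint", {
  pop <- population_fixture()
  expect_equal(sum(pop$counts), pop$N)
  # the dVt_amil boxes of the two conditions do not overlap
  expect_equal(sum(pop$accepted_nonCF & pop$accepted_CF), 0)
  expect_true(all(pop$label[pop$accepted_nonCF] == "nonCF"))
  expect_true(all(pop$label[pop$accepted_CF] == "CF"))
  # percentile tables are monotone
  for (cond in c("nonCF", "CF")) {
    pct <- pop$percentiles[[cond]]
    expect_true(all(apply(pct, 2, function(x) all(diff(x) >= 0))))
  }
})

test_that("accepted parameter sets are accepted again on re-evaluation", {
  pop <- population_fixture()
  idx <- head(which(pop$accepted_nonCF), 5)
  pnames <- c("P_Na_ap", "P_Cl_ap", "P_K_bl", "rho_NaK", "rho_NKCC", "P_Cl_bl")
  for (i in idx) {
    p <- table1_params("baseline")
    p[pnames] <- as.list(pop$params[i, ])
    obs <- evaluate_observables(p)
    expect_equal(classify_observables(obs, pop$bounds_nonCF), "accepted")
    expect_equal(as.numeric(obs[1:5]),
                 as.numeric(pop$observables[i, 1:5]), tolerance = 1e-6)
  }
})

test_that("chunked evaluation reproduces the single-pass filter", {
  pop <- run_filter(400, seed = 99)
  pop_a <- run_filter(400, seed = 99, early_reject = FALSE)
  # early rejection never changes which samples are accepted (it only skips
  # perturbation solves for samples already outside both basal boxes, whose
  # rejected/discarded distinction is then left undetermined)
  expect_identical(pop$accepted_nonCF, pop_a$accepted_nonCF)
  expect_identical(pop$accepted_CF, pop_a$accepted_CF)
  keep <- pop$accepted_nonCF | pop$accepted_CF
  expect_equal(pop$observables[keep, ], pop_a$observables[keep, ],
               tolerance = 1e-12)
  expect_identical(pop$params, pop_a$params)
})

test_that("median shifts hold in the paracellular variants", {
  for (variant in c("low_Ppa_CF", "cation_selective")) {
    pop <- run_filter(30000, seed = 314, variant = variant)
    med_non <- pop$percentiles$nonCF["50%", ]
    med_cf <- pop$percentiles$CF["50%", ]
    expect_lt(med_cf[["P_Cl_ap"]], med_non[["P_Cl_ap"]])
    expect_gt(med_cf[["P_Na_ap"]], med_non[["P_Na_ap"]])
  }
})
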