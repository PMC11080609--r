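cal45 <- unit_cal(45)
win <- c(30, Inf)

test_that("modal calling takes the tallest peak, ties toward smaller CAG", {
  expect_identical(call_modal_peak(make_trace(c(`54` = 700)), cal45,
                                   window = win), 54L)
  # cerebellar-type trace: main peak one repeat below the diagnostic allele
  tr <- make_trace(c(`72` = 900, `73` = 880, `74` = 300))
  expect_identical(call_modal_peak(tr, cal45, window = win), 72L)
  # exact tie in both input orderings
  expect_identical(call_modal_peak(make_trace(c(`45` = 500, `46` = 500)),
                                   cal45, window = win), 45L)
  expect_identical(call_modal_peak(make_trace(c(`46` = 500, `45` = 500)),
                                   cal45, window = win), 45L)
  expect_error(call_modal_peak(make_trace(c(`20` = 500)), cal45,
                               window = win), "no peak")
})

test_that("EI matches the hand-worked definition and its degenerate cases", {
  tr <- make_trace(c(`45` = 1000, `46` = 300, `47` = 90, `48` = 20))
  p <- compute_ei(tr, cal = cal45, window = win)
  # +3 peak (20) falls below 0.03 * 1000 and is excluded; S = 1390
  expect_equal(p$ei, (300 * 1 + 90 * 2) / 1390, tolerance = 1e-12)
  expect_equal(p$ei, oracle_ei(45:48, c(1000, 300, 90, 20), 45, 0.03),
               tolerance = 1e-12)
  expect_identical(p$n_additional_cags, 2L)
  # modal peak alone: no expansion beyond the inherited allele
  expect_equal(compute_ei(make_trace(c(`45` = 800)), cal = cal45,
                          window = win)$ei, 0)
  # threshold saturation: every expanded peak below theta * h0
  expect_equal(compute_ei(make_trace(c(`45` = 1000, `46` = 25, `47` = 10)),
                          cal = cal45, window = win)$ei, 0)
  # stutter side never counts
  expect_equal(compute_ei(make_trace(c(`43` = 400, `44` = 600, `45` = 1000)),
                          cal = cal45, window = win)$ei, 0)
})

test_that("percent-mutant-allele profiles are normalized to 100", {
  pct <- percent_mutant_alleles(make_trace(c(`45` = 1000, `46` = 300,
                                             `47` = 90)),
                                threshold = 0.03, cal = cal45, window = win)
  expect_equal(unname(pct), 100 * c(1000, 300, 90) / 1390, tolerance = 1e-9)
  expect_equal(names(pct), c("45", "46", "47"))
  expect_equal(sum(pct), 100, tolerance = 1e-9)
  expect_equal(unname(percent_mutant_alleles(make_trace(c(`45` = 777)),
                                             threshold = 0.03, cal = cal45,
                                             window = win)), 100)
  expect_equal(unname(percent_mutant_alleles(
    make_trace(c(`45` = 640, `46` = 640)), threshold = 0.03, cal = cal45,
    window = win)), c(50, 50))
})

test_that("a fixed reference modal below the trace modal keeps EI defined", {
  # trace drifted +1: taller peak right of the reference is expansion signal
  tr <- make_trace(c(`42` = 800, `43` = 1000))
  p <- compute_ei(tr, reference_modal = 42, cal = cal45, window = win)
  expect_equal(p$ei, 1000 / 1800, tolerance = 1e-12)
  expect_identical(p$modal_cag, 43L)
  expect_identical(p$reference_modal, 42L)
  expect_error(compute_ei(tr, reference_modal = 40, cal = cal45,
                          window = win), "missing-modal")
})

test_that("the longitudinal reference modal is fixed per individual", {
  t1 <- make_trace(c(`42` = 1000, `43` = 200), id = "v1", age = 30)
  t2 <- make_trace(c(`42` = 700, `43` = 900), id = "v2", age = 40)
  t3 <- make_trace(c(`44` = 900), id = "v3", age = 50)
  # diagnostic repeat wins over later calls
  expect_identical(longitudinal_reference_modal(list(t1, t2, t3), 42,
                                                cal45, win), 42L)
  # fallback: modal of the earliest trace
  expect_identical(longitudinal_reference_modal(list(t2, t1), cal = cal45,
                                                window = win), 42L)
  expect_identical(longitudinal_reference_modal(list(t1), cal = cal45,
                                                window = win), 42L)
  # identical traces give the same reference regardless of order
  expect_identical(longitudinal_reference_modal(list(t2, t2), cal = cal45,
                                                window = win),
                   call_modal_peak(t2, cal45, win))
})

test_that("the expanded window excludes the normal allele cluster", {
  tr <- make_trace(c(`22` = 2000, `23` = 2400, `56` = 900, `57` = 300),
                   gene = "ATXN3")
  expect_identical(call_modal_peak(tr, cal45), 56L) # window from gene
  p <- compute_ei(tr, cal = cal45)
  expect_equal(p$ei, 300 / 1200, tolerance = 1e-12)
})

test_that("EI obeys its invariants on random traces", {
  set.seed(202)
  for (rep in 1:100) {
    tr <- random_trace()
    theta <- runif(1, 0.01, 0.2)
    p <- compute_ei(tr, reference_modal = 45, threshold = theta,
                    cal = cal45, window = c(20, Inf))
    cag <- bp_to_cag(tr$peaks$size_bp, cal45)
    # oracle equivalence
    expect_equal(p$ei, oracle_ei(cag, tr$peaks$height, 45, theta,
                                 c(20, Inf)),
                 tolerance = 1e-12)
    # scale invariance
    tr2 <- tr; tr2$peaks$height <- tr2$peaks$height * 137.3
    p2 <- compute_ei(tr2, reference_modal = 45, threshold = theta,
                     cal = cal45, window = c(20, Inf))
    expect_equal(p2$ei, p$ei, tolerance = 1e-12)
    expect_equal(p2$percent_by_cag, p$percent_by_cag, tolerance = 1e-9)
    expect_identical(call_modal_peak(tr2, cal45, c(20, Inf)),
                     call_modal_peak(tr, cal45, c(20, Inf)))
    # EI null iff no retained expanded peak
    retained <- cag > 45 &
      tr$peaks$height >= theta * tr$peaks$height[match(45, cag)]
    expect_identical(p$ei > 0, any(retained))
    if (any(retained)) {
      expect_lt(p$ei, max(cag[retained]) - 45)
      # raising the farthest retained peak strictly increases EI
      far <- which(cag == max(cag[retained]))
      tr3 <- tr; tr3$peaks$height[far] <- tr3$peaks$height[far] * 2
      expect_gt(compute_ei(tr3, reference_modal = 45, threshold = theta,
                           cal = cal45, window = c(20, Inf))$ei, p$ei)
    }
    # monotone non-increasing in the threshold on decaying tails (raising
    # theta then drops the farthest retained peak first)
    trd <- decay_trace()
    eis <- vapply(c(0.01, 0.05, 0.1, 0.3, 0.6),
                  function(th) compute_ei(trd, reference_modal = 45,
                                          threshold = th, cal = cal45,
                                          window = c(20, Inf))$ei,
                  numeric(1))
    expect_true(all(diff(eis) <= 1e-12))
    # dropping all expanded peaks forces EI = 0 and a pure modal profile
    keep <- cag <= 45
    tr0 <- new_trace("t0", tr$peaks[keep, ])
    p0 <- compute_ei(tr0, reference_modal = 45, threshold = theta,
                     cal = cal45, window = c(20, Inf))
    expect_equal(p0$ei, 0)
    expect_equal(p0$percent_by_cag, c(`45` = 100))
  }
})

test_that("normalizing over all candidate peaks is available as a variant", {
  tr <- make_trace(c(`45` = 1000, `46` = 300, `47` = 90, `48` = 20))
  p_ret <- compute_ei(tr, cal = cal45, window = win)
  p_all <- compute_ei(tr, cal = cal45, window = win, normalize = "all")
  # larger denominator (sub-threshold peak still in S) shrinks EI
  expect_equal(p_all$ei, (300 + 180) / 1410, tolerance = 1e-12)
  expect_lt(p_all$ei, p_ret$ei)
  # identical when every candidate is retained
  tr2 <- make_trace(c(`45` = 1000, `46` = 300, `47` = 90))
  expect_equal(compute_ei(tr2, cal = cal45, window = win)$ei,
               compute_ei(tr2, cal = cal45, window = win,
                          normalize = "all")$ei)
})

test_that("instability_table applies per-individual references", {
  cfg <- trace_gen_config(gene = "ATXN7", modal_cag = 44, noise_cv = 0)
  s1 <- generate_trace(cfg, 0.4, sample_id = "a_v1", individual_id = "a")
  cfg2 <- cfg; cfg2$modal_cag <- 45L # drifted later visit
  s2 <- generate_trace(cfg2, 0.8, sample_id = "a_v2", individual_id = "a")
  tab <- instability_table(list(s1$trace, s2$trace), s1$cal,
                           diagnostic_cag = c(a = 44))
  expect_equal(tab$reference_modal, c(44L, 44L))
  expect_equal(tab$modal_cag, c(44L, 45L))
  expect_equal(tab$ei[1], 0.4, tolerance = 1e-6)
  expect_gt(tab$ei[2], 1) # drift adds a whole repeat to every retained peak
})
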