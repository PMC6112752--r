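test_that("the two-fraction sweep shows the drop-and-recovery shape", {
  eff <- function(gap) ied_efficacy(schedule_uniform(2, 2, interval = gap),
                                    ref_params, ref_kinetics)
  expect_gt(eff(0.25), eff(3))   # short gap: second hit before necrosis
  expect_gt(eff(21), eff(3))     # long gap: activation already complete
  expect_gte(eff(21), 0.9 * eff(0.25))  # recovery regains most of the value
  sw <- interfraction_sweep(2, 2, 0.25, 21, n_points = 9,
                            params = ref_params, kinetics = ref_kinetics)
  expect_equal(nrow(sw), 9L)
  expect_true(all(diff(sw$gap_days) > 0))
  expect_true(all(sw$efficacy >= 0 & sw$efficacy < 1))
})

test_that("sweeps are deterministic and refining the grid never contradicts it", {
  coarse <- interfraction_sweep(2, 2, 1, 9, n_points = 5)
  fine <- interfraction_sweep(2, 2, 1, 9, n_points = 9)
  shared <- match(coarse$gap_days, fine$gap_days)
  expect_false(anyNA(shared))
  expect_lt(max(abs(coarse$efficacy - fine$efficacy[shared])), 1e-12)
  again <- interfraction_sweep(2, 2, 1, 9, n_points = 5)
  expect_identical(coarse$efficacy, again$efficacy)
  # a single fraction ignores the gap entirely
  flat <- interfraction_sweep(4, 1, 0.5, 20, n_points = 6)
  expect_equal(flat$efficacy, rep(kill_fraction(4, rt_params()), 6),
               tolerance = 1e-12)
  expect_error(interfraction_sweep(2, 2, 5, 1), "gap_min")
})

test_that("interfraction timing matters less for radio-resistant tumours", {
  sensitive <- sf2_params(0.43)
  resistant <- sf2_params(0.70)
  spread <- function(p) {
    sw <- interfraction_sweep(2, 2, 0.25, 21, n_points = 30, params = p,
                              kinetics = ref_kinetics)
    max(sw$efficacy) - min(sw$efficacy)
  }
  expect_gt(spread(sensitive), spread(resistant))
})

test_that("comparison rows agree field-by-field with direct evaluation", {
  schedules <- list("3x8" = schedule_uniform(3, 8),
                    "5x6" = schedule_uniform(5, 6))
  tab <- compare_schedules(schedules, ref_params, ref_kinetics)
  expect_equal(tab$label, c("3x8", "5x6"))
  for (i in 1:2) {
    r <- ied_evaluate(schedules[[i]], ref_params, ref_kinetics)
    expect_equal(tab$eqd2_gy[i], r$eqd2_gy)
    expect_equal(tab$bed_gy[i], r$bed_gy)
    expect_equal(tab$ied_efficacy[i], r$efficacy)
    expect_equal(tab$efficacy_pct[i], round(100 * r$efficacy))
  }
  one <- compare_schedules(list(schedule(0, 2)))
  expect_equal(nrow(one), 1L)
  expect_equal(one$label, "schedule_1")
})

test_that("constrained search ranks feasible schedules reproducibly", {
  cands <- hybrid_candidates()
  cons <- list(bed = c(70, 85), eqd2 = c(40, 56), max_span = 32, max_dose = 3)
  res <- constrained_search(cands, cons, ref_params, ref_kinetics)
  expect_gt(nrow(res), 1L)
  expect_true(all(diff(res$ied_efficacy) <= 0))
  expect_true(all(res$bed_gy >= 70 & res$bed_gy <= 85))
  expect_true(all(res$span_days <= 32))
  # the classic weekday course is feasible but dominated by hybrids
  expect_true("weekday_25x2Gy" %in% res$label)
  expect_false(res$label[1] == "weekday_25x2Gy")
  # deterministic re-run, stable tie-breaking
  res2 <- constrained_search(cands, cons, ref_params, ref_kinetics)
  expect_identical(res$label, res2$label)
  # top_k on a one-candidate space returns that candidate
  solo <- constrained_search(cands["weekday_25x2Gy"], list(), top_k = 1)
  expect_equal(solo$label, "weekday_25x2Gy")
  # tightening the span can only shrink the attainable best efficacy
  tighter <- constrained_search(cands, modifyList(cons, list(max_span = 31)),
                                ref_params, ref_kinetics)
  if (nrow(tighter) > 0)
    expect_lte(tighter$ied_efficacy[1], res$ied_efficacy[1])
  # infeasible constraints: empty frame plus a notice
  expect_message(empty <- constrained_search(cands, list(bed = c(0, 1))),
                 "no candidate")
  expect_equal(nrow(empty), 0L)
})

test_that("reports serialize to TSV and JSON with schedules as spec strings", {
  tab <- compare_schedules(list("3x8" = schedule_uniform(3, 8)))
  p_tsv <- tempfile(fileext = ".tsv")
  p_json <- tempfile(fileext = ".json")
  write_report(tab, p_tsv)
  write_report(tab, p_json)
  lines <- readLines(p_tsv)
  expect_match(lines[1], "^label\t")
  expect_match(lines[1], "\teqd2_gy\t")
  back <- jsonlite::fromJSON(p_json)
  expect_equal(back$ied_efficacy, tab$ied_efficacy, tolerance = 1e-12)
  res <- constrained_search(hybrid_candidates()["weekday_25x2Gy"], list())
  write_report(res, p_tsv)
  expect_match(readLines(p_tsv)[2], "(0,2);(1,2)", fixed = TRUE)
  unlink(c(p_tsv, p_json))
})
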