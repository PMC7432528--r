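test_that("task dose matches the published arithmetic at 2 significant figures", {
  # 1.30e1 mSv/h for 135 min -> 2.9e1 mSv
  t1 <- task("Cutter 1", "cutter", 135, 1.30e1)
  expect_equal(signif(task_dose(t1), 2), 2.9e1)
  expect_equal(task_dose(t1), 13 * 135 / 60)   # full precision retained
  # 5.70e2 mSv/h for 165 min -> 1.6e3 mSv
  t2 <- task("Cutter_7", "cutter", 165, 5.70e2)
  expect_equal(signif(task_dose(t2), 2), 1.6e3)
  expect_equal(task_dose(task("z", "rpo", 100, 0)), 0)
  expect_error(task_dose(task("u", "cutter", 10)), "no dose rate")
})

test_that("plan summaries reproduce the published totals", {
  fix <- build_kori_fixture()
  s_uf <- summarize_plan(fix$work_plans$upper_fragmentation)
  expect_equal(s_uf$total_work_time_min, 1896.0)
  s_us <- summarize_plan(fix$work_plans$upper_segmentation)
  expect_equal(s_us$total_work_time_min, 2810.0)
  # all three fragmentation plans share 1896 min, segmentation 2810 min
  for (p in c("active_fragmentation", "lower_fragmentation"))
    expect_equal(summarize_plan(fix$work_plans[[p]])$total_work_time_min, 1896)
  for (p in c("active_segmentation", "lower_segmentation"))
    expect_equal(summarize_plan(fix$work_plans[[p]])$total_work_time_min, 2810)
  # max/min prognoses bracket the totals symmetrically
  expect_equal(s_uf$max_work_time_min, 1896 * 1.038)
  expect_equal(s_uf$min_work_time_min, 1896 * (1 - 0.038))
  # empty plan
  s0 <- summarize_plan(work_plan(list()))
  expect_equal(s0$total_work_time_min, 0)
  expect_equal(s0$accumulated_dose_msv, 0)
})

test_that("accumulated dose is non-decreasing and consistent with the tables", {
  fix <- build_kori_fixture()
  printed <- printed_task_doses()
  for (nm in names(printed)) {
    s <- summarize_plan(fix$work_plans[[nm]])
    acc <- s$task_table$accumulated_dose_msv
    expect_true(all(diff(acc) >= 0))
    expect_equal(acc[length(acc)], sum(s$task_table$task_dose_msv),
                 tolerance = 1e-12)
    # published task doses agree within the 2-significant-figure rounding of
    # their inputs (dose rates are printed at 2 s.f.)
    expect_equal(s$task_table$task_dose_msv, printed[[nm]], tolerance = 0.06)
  }
})

test_that("collective metrics and the grand total reproduce", {
  fix <- build_kori_fixture()
  cu <- collective(fix$work_plans$upper_fragmentation)
  expect_equal(cu$collective_time_man_h, 189.60)
  # published 6.0e2 man-mSv; recomputed from dose rates x durations: 592.96
  expect_equal(cu$collective_dose_man_msv, 6.0e2, tolerance = 0.02)
  ca <- collective(fix$work_plans$active_fragmentation)
  expect_equal(ca$collective_time_man_h, 189.60)
  expect_equal(ca$collective_dose_man_msv, 1.7e4, tolerance = 0.02)
  cl <- collective(fix$work_plans$lower_fragmentation)
  expect_equal(cl$collective_time_man_h, 252.80)

  gt <- grand_total(lapply(fix$work_plans, collective))
  expect_equal(gt$man_days_display, 196)
  expect_equal(gt$collective_time_man_h, 1568.6, tolerance = 1e-4)

  # repetitions = 1 collapses collective dose to the per-cutting dose
  p1 <- work_plan(fix$work_plans$upper_fragmentation$tasks, repetitions = 1)
  expect_equal(collective(p1)$collective_dose_man_msv,
               summarize_plan(p1)$accumulated_dose_msv)
  # linearity in repetitions
  p3 <- work_plan(fix$work_plans$upper_fragmentation$tasks, repetitions = 3)
  expect_equal(collective(p3)$collective_dose_man_msv,
               3 * collective(p1)$collective_dose_man_msv)
  expect_equal(collective(p3)$collective_time_man_h,
               3 * collective(p1)$collective_time_man_h)

  expect_equal(grand_total(list()), list(collective_time_man_h = 0,
                                         man_days = 0, man_days_display = 0))
  one <- collective(work_plan(list(task("a", "cutter", 80 * 60, 0)),
                              repetitions = 1))
  expect_equal(grand_total(list(one))$man_days_display, 10)
})

test_that("task totals are order-independent", {
  fix <- build_kori_fixture()
  p <- fix$work_plans$active_fragmentation
  set.seed(31)
  sh <- work_plan(sample(p$tasks), repetitions = p$repetitions,
                  uncertainty_fraction = p$uncertainty_fraction)
  expect_equal(summarize_plan(sh)$total_work_time_min,
               summarize_plan(p)$total_work_time_min)
  expect_equal(summarize_plan(sh)$accumulated_dose_msv,
               summarize_plan(p)$accumulated_dose_msv, tolerance = 1e-12)
  expect_equal(collective(sh)$collective_dose_man_msv,
               collective(p)$collective_dose_man_msv, tolerance = 1e-12)
})

test_that("dose limit check flags exceedances with inclusive limit", {
  r <- dose_limit_check(c(worker_a = 15, worker_b = 29, worker_c = 20))
  expect_equal(r$pass, c(TRUE, FALSE, TRUE))
  expect_equal(r$margin_msv, c(5, -9, 0))
  # the published Cutter 1 task dose of 29 mSv exceeds a 20 mSv/y limit
  fix <- build_kori_fixture()
  d <- task_dose(fix$work_plans$upper_fragmentation$tasks[[1]])
  expect_false(dose_limit_check(c(cutter1 = d))$pass)
})

test_that("work plans round-trip through JSON bit-exactly", {
  fix <- build_kori_fixture()
  tmp <- tempfile(fileext = ".json")
  write_work_plans(fix$work_plans, tmp)
  back <- read_work_plans(tmp)
  expect_identical(names(back), names(fix$work_plans))
  for (nm in names(back)) {
    a <- back[[nm]]; b <- fix$work_plans[[nm]]
    expect_identical(a$repetitions, b$repetitions)
    expect_identical(a$uncertainty_fraction, b$uncertainty_fraction)
    for (i in seq_along(a$tasks)) {
      expect_identical(a$tasks[[i]]$duration_min, b$tasks[[i]]$duration_min)
      expect_identical(a$tasks[[i]]$dose_rate_msv_h, b$tasks[[i]]$dose_rate_msv_h)
    }
  }
})
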