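# ALARA detailed-planning layer: tasks, per-worker dose accumulation,
# prognosis ranges and collective metrics.

#' A work task
#'
#' @param label task identifier (e.g. "Cutter 1", "RPO").
#' @param role `"cutter"` or `"rpo"`.
#' @param duration_min task duration, minutes, > 0.
#' @param dose_rate_msv_h dose rate at the worker position, mSv/h, >= 0
#'   (computed by the dose engine or supplied from a published table).
#' @param position optional position (metres) or trajectory (matrix of
#'   positions with an attribute `dwell` of fractions).
#' @export
task <- function(label, role = c("cutter", "rpo"), duration_min,
                 dose_rate_msv_h = NA_real_, position = NULL) {
  role <- match.arg(role)
  stopifnot_scalar_num(duration_min, "duration_min", positive = TRUE)
  if (!is.na(dose_rate_msv_h))
    stopifnot_scalar_num(dose_rate_msv_h, "dose_rate_msv_h", nonneg = TRUE)
  structure(list(label = label, role = role, duration_min = duration_min,
                 dose_rate_msv_h = dose_rate_msv_h, position = position),
            class = "work_task")
}

#' A work plan: ordered tasks, repetitions and prognosis uncertainty
#'
#' @param tasks list of [task()] objects.
#' @param repetitions number of identical cuttings the plan is repeated for
#'   (>= 1).
#' @param uncertainty_fraction symmetric fractional perturbation applied to
#'   totals for the max/min prognoses (default 0.038, i.e. 3.8%).
#' @param label optional scenario label.
#' @export
work_plan <- function(tasks, repetitions = 1L, uncertainty_fraction = 0.038,
                      label = NULL) {
  stopifnot(is.list(tasks), all(vapply(tasks, inherits, TRUE, "work_task")))
  if (repetitions < 1) stop("repetitions must be >= 1")
  if (uncertainty_fraction < 0 || uncertainty_fraction >= 1)
    stop("uncertainty_fraction must be in [0, 1)")
  structure(list(tasks = tasks, repetitions = as.integer(repetitions),
                 uncertainty_fraction = uncertainty_fraction,
                 label = label %||% "plan"),
            class = "work_plan")
}

#' Dose received during one task
#'
#' `dose_rate x duration / 60`, in mSv. Outputs are displayed at
#' 2 significant figures (the tables' style); full precision is returned.
#'
#' @param tsk a [task()] with its dose rate set.
#' @return task dose in mSv.
#' @export
task_dose <- function(tsk) {
  stopifnot(inherits(tsk, "work_task"))
  if (is.na(tsk$dose_rate_msv_h)) stop("task '", tsk$label, "' has no dose rate")
  tsk$dose_rate_msv_h * tsk$duration_min / 60
}

#' Summarize a work plan (one cutting)
#'
#' Totals over the task list plus max/min prognoses obtained by a symmetric
#' fractional perturbation of the totals; the per-task table carries the
#' running accumulated dose.
#'
#' @param plan a [work_plan()].
#' @param prognosis_mode apply the uncertainty band to `"both"` time and
#'   dose (default), `"time"` only, or `"dose"` only.
#' @return object of class `plan_summary` with `total_work_time_min`,
#'   `accumulated_dose_msv`, `max_/min_` variants, and `task_table`.
#' @export
summarize_plan <- function(plan, prognosis_mode = c("both", "time", "dose")) {
  stopifnot(inherits(plan, "work_plan"))
  prognosis_mode <- match.arg(prognosis_mode)
  doses <- vapply(plan$tasks, task_dose, numeric(1))
  durs <- vapply(plan$tasks, `[[`, numeric(1), "duration_min")
  tt <- data.frame(
    task = vapply(plan$tasks, `[[`, character(1), "label"),
    role = vapply(plan$tasks, `[[`, character(1), "role"),
    duration_min = durs,
    dose_rate_msv_h = vapply(plan$tasks, `[[`, numeric(1), "dose_rate_msv_h"),
    task_dose_msv = doses,
    accumulated_dose_msv = cumsum(doses),
    stringsAsFactors = FALSE)
  u <- plan$uncertainty_fraction
  ut <- if (prognosis_mode %in% c("both", "time")) u else 0
  ud <- if (prognosis_mode %in% c("both", "dose")) u else 0
  total_t <- sum(durs); total_d <- sum(doses)
  structure(list(label = plan$label,
                 total_work_time_min = total_t,
                 accumulated_dose_msv = total_d,
                 max_work_time_min = total_t * (1 + ut),
                 min_work_time_min = total_t * (1 - ut),
                 max_accumulated_dose_msv = total_d * (1 + ud),
                 min_accumulated_dose_msv = total_d * (1 - ud),
                 task_table = tt),
            class = "plan_summary")
}

#' @export
print.plan_summary <- function(x, ...) {
  cat(sprintf("<plan_summary> %s: %.1f min, %.2g mSv per cutting\n",
              x$label, x$total_work_time_min, x$accumulated_dose_msv))
  df <- x$task_table
  df$dose_rate_msv_h <- signif2(df$dose_rate_msv_h)
  df$task_dose_msv <- signif2(df$task_dose_msv)
  df$accumulated_dose_msv <- signif2(df$accumulated_dose_msv)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Collective time and dose for a repeated plan
#'
#' `collective_time = total_work_time x repetitions / 60` (man-h);
#' `collective_dose = accumulated_dose x repetitions` (man-mSv);
#' man-days at 8 h per man-day.
#'
#' @param plan a [work_plan()].
#' @return object of class `scenario_summary`.
#' @export
collective <- function(plan) {
  s <- summarize_plan(plan)
  ct <- s$total_work_time_min * plan$repetitions / 60
  structure(list(label = plan$label,
                 collective_time_man_h = ct,
                 collective_dose_man_msv = s$accumulated_dose_msv * plan$repetitions,
                 man_days = ct / 8,
                 repetitions = plan$repetitions),
            class = "scenario_summary")
}

#' Grand total over scenarios
#'
#' @param summaries list of [collective()] results.
#' @return list with `collective_time_man_h`, `man_days` (exact) and
#'   `man_days_display` (rounded to the nearest integer).
#' @export
grand_total <- function(summaries) {
  stopifnot(all(vapply(summaries, inherits, TRUE, "scenario_summary")))
  th <- sum(vapply(summaries, `[[`, numeric(1), "collective_time_man_h"))
  list(collective_time_man_h = th, man_days = th / 8,
       man_days_display = round(th / 8))
}

#' Check planned doses against an annual limit
#'
#' The default limit is 20 mSv per year averaged over five consecutive
#' years; the limit is inclusive (a planned dose exactly at the limit
#' passes).
#'
#' @param planned_msv named vector of per-worker planned annual doses (mSv).
#' @param limit_msv annual dose limit, > 0.
#' @param averaging_years averaging window, informational.
#' @return data.frame `worker, planned_msv, limit_msv, margin_msv, pass`.
#' @export
dose_limit_check <- function(planned_msv, limit_msv = 20, averaging_years = 5) {
  stopifnot_scalar_num(limit_msv, "limit_msv", positive = TRUE)
  workers <- names(planned_msv) %||% paste0("worker_", seq_along(planned_msv))
  out <- data.frame(worker = workers, planned_msv = as.numeric(planned_msv),
                    limit_msv = limit_msv,
                    margin_msv = limit_msv - as.numeric(planned_msv),
                    pass = as.numeric(planned_msv) <= limit_msv,
                    stringsAsFactors = FALSE)
  attr(out, "averaging_years") <- averaging_years
  out
}

#' Read / write work plans (JSON)
#'
#' The JSON schema mirrors the bundled fixture: a `plans` array of objects
#' with `label`, `repetitions`, `uncertainty_fraction` and a `tasks` array
#' (`label`, `role`, `duration_min`, `dose_rate_msv_h`).
#'
#' @param path file path.
#' @return named list of [work_plan()] objects.
#' @export
read_work_plans <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  plans <- j$plans
  out <- lapply(seq_len(nrow(plans)), function(i) {
    tk <- plans$tasks[[i]]
    work_plan(lapply(seq_len(nrow(tk)), function(k)
      task(tk$label[k], tk$role[k], tk$duration_min[k], tk$dose_rate_msv_h[k])),
      repetitions = plans$repetitions[i],
      uncertainty_fraction = plans$uncertainty_fraction[i],
      label = plans$label[i])
  })
  names(out) <- plans$label
  out
}

#' @rdname read_work_plans
#' @param plans named list of [work_plan()] objects.
#' @export
write_work_plans <- function(plans, path) {
  body <- list(plans = lapply(unname(plans), function(p) list(
    label = p$label, repetitions = p$repetitions,
    uncertainty_fraction = p$uncertainty_fraction,
    tasks = lapply(p$tasks, function(t) list(
      label = t$label, role = t$role, duration_min = t$duration_min,
      dose_rate_msv_h = t$dose_rate_msv_h)))))
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a plan summary as CSV mirroring the published table columns
#'
#' @param summary a [summarize_plan()] result.
#' @param path output file.
#' @export
write_plan_csv <- function(summary, path) {
  df <- summary$task_table
  df$dose_rate_msv_h <- signif2(df$dose_rate_msv_h)
  df$task_dose_msv <- signif2(df$task_dose_msv)
  df$accumulated_dose_msv <- signif2(df$accumulated_dose_msv)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
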