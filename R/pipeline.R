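# End-to-end orchestration: simulate or load tables, extract events, build
# the cohort, evaluate every tool, and emit the report bundle.

#' The three default tools
#'
#' Loads the shipped illustrative eRAT-style and QPaC-style rule sets and
#' the synthetic QCancer-style coefficient file.
#'
#' @return Named list of tool objects.
#' @export
default_tools <- function() {
  ext <- function(f) system.file("extdata", f, package = "panctriage",
                                 mustWork = TRUE)
  list(eRAT = load_ruleset(ext("ruleset_erat.yaml")),
       QPaC = load_ruleset(ext("ruleset_qpac.yaml")),
       QCancer = load_risk_model(ext("qcancer_synthetic.yaml")))
}

#' Pipeline run configuration
#'
#' Exactly one of `sim` (simulate on the fly) or `input_dir` (read tables
#' written by [write_tables()]) must be provided.
#'
#' @param out_dir Output directory for the report bundle.
#' @param sim Optional [sim_config()].
#' @param input_dir Optional directory of input tables.
#' @param lexicon A [symptom_lexicon()] (default the shipped lexicon).
#' @param feat A [feature_config()].
#' @param cohort A [cohort_config()].
#' @param tools Named list of tool objects (default [default_tools()]).
#' @param precovid Also run the pre-COVID sensitivity subset (default
#'   FALSE).
#' @param seed Seed recorded in provenance and forwarded to `sim` when that
#'   config has none.
#' @return Object of class `pc_run_config`.
#' @export
run_config <- function(out_dir, sim = NULL, input_dir = NULL,
                       lexicon = default_lexicon(),
                       feat = feature_config(), cohort = cohort_config(),
                       tools = default_tools(), precovid = FALSE,
                       seed = 1L) {
  if (is.null(sim) == is.null(input_dir)) {
    stop("provide exactly one of 'sim' or 'input_dir'", call. = FALSE)
  }
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "pc_sim_config"))
    if (is.null(sim$seed)) sim$seed <- seed
  }
  structure(list(out_dir = out_dir, sim = sim, input_dir = input_dir,
                 lexicon = lexicon, feat = feat, cohort = cohort,
                 tools = tools, precovid = precovid,
                 seed = as.integer(seed)),
            class = "pc_run_config")
}

#' Run the full validation pipeline
#'
#' Produces the report bundle in `config$out_dir`: `cohort_flow.json`
#' (exclusion-cascade counts), `table1.csv` (cohort description),
#' `prevalence.csv` (per-symptom presence by cancer status and
#' pre-diagnosis incidence), `per_symptom_ppv.csv`, `tool_confusion.csv`,
#' `tool_stats.csv` (the seven accuracy statistics per tool) and
#' `provenance.json`. Deterministic given the seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the computed objects (`tables`,
#'   `timelines`, `evaluations`, `stats`, paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pc_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  tables <- if (!is.null(config$sim)) generate_cohort_data(config$sim)
            else read_tables(config$input_dir)
  timelines <- build_timelines(tables, config$lexicon, config$feat,
                               config$cohort)
  if (isTRUE(config$precovid)) {
    timelines <- apply_precovid_filter(timelines, config$cohort)
  }

  flow <- attr(timelines, "flow")
  summ <- summarise_cohort(timelines, config$cohort)
  flow$cancers_12m <- summ$counts$cancer
  jsonlite::write_json(flow, file.path(config$out_dir, "cohort_flow.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  utils::write.csv(summ$table1, file.path(config$out_dir, "table1.csv"),
                   row.names = FALSE, na = "")
  prev <- prevalence_table(timelines, config$cohort)
  utils::write.csv(prev, file.path(config$out_dir, "prevalence.csv"),
                   row.names = FALSE, na = "")

  ppv_rows <- lapply(canonical_symptoms(), function(code) {
    st <- per_symptom_ppv(timelines, code, config$cohort)
    data.frame(symptom = code, n_presenters = attr(st, "n"),
               tp = attr(st, "tp"),
               ppv_pct = round(100 * st$estimate, 2),
               ci_low_pct = round(100 * st$ci_low, 2),
               ci_high_pct = round(100 * st$ci_high, 2),
               method = st$method, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, ppv_rows),
                   file.path(config$out_dir, "per_symptom_ppv.csv"),
                   row.names = FALSE, na = "")

  evaluations <- list()
  conf_rows <- list()
  stat_rows <- list()
  for (nm in names(config$tools)) {
    evals <- evaluate_cohort(timelines, config$tools[[nm]], config$cohort)
    evaluations[[nm]] <- evals
    cm <- confusion_from_evaluations(evals)
    conf_rows[[nm]] <- data.frame(tool = nm, tp = cm$tp, fp = cm$fp,
                                  fn = cm$fn, tn = cm$tn,
                                  n_eligible = sum(evals$eligible),
                                  stringsAsFactors = FALSE)
    stat_rows[[nm]] <- tool_stat_rows(nm, cm)
  }
  utils::write.csv(do.call(rbind, conf_rows),
                   file.path(config$out_dir, "tool_confusion.csv"),
                   row.names = FALSE)
  stats_df <- do.call(rbind, stat_rows)
  utils::write.csv(stats_df, file.path(config$out_dir, "tool_stats.csv"),
                   row.names = FALSE, na = "")

  prov_cfg <- file.path(config$out_dir, "run_config.yaml")
  yaml::write_yaml(list(
    mode = if (is.null(config$sim)) "tables" else "simulate",
    seed = config$seed,
    n_patients = if (is.null(config$sim)) NA else config$sim$n_patients,
    tools = names(config$tools)), prov_cfg)
  jsonlite::write_json(list(
    config_hash = unname(tools::md5sum(prov_cfg)),
    seed = config$seed,
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    package_version = as.character(utils::packageVersion("panctriage"))),
    file.path(config$out_dir, "provenance.json"),
    auto_unbox = TRUE, pretty = TRUE)

  invisible(list(tables = tables, timelines = timelines,
                 evaluations = evaluations, stats = stats_df,
                 flow = flow, out_dir = config$out_dir))
}

tool_stat_rows <- function(nm, cm) {
  lr <- likelihood_ratios(cm)
  mk <- function(stat_name, st, pct = TRUE) {
    f <- if (pct) function(v) round(100 * v, 2) else function(v) round(v, 2)
    data.frame(tool = nm, statistic = stat_name, estimate = f(st$estimate),
               ci_low = f(st$ci_low), ci_high = f(st$ci_high),
               method = st$method, stringsAsFactors = FALSE)
  }
  rbind(mk("sensitivity_pct", sensitivity(cm)),
        mk("specificity_pct", specificity(cm)),
        mk("ppv_pct", ppv(cm)),
        mk("npv_pct", npv(cm)),
        mk("lr_plus", lr$lr_plus, pct = FALSE),
        mk("lr_minus", lr$lr_minus, pct = FALSE),
        mk("accuracy_pct", accuracy(cm)))
}

# Outcome stratification used by the descriptive outputs: a patient counts
# as a cancer case when the C25 diagnosis falls within the follow-up window
# of their any-symptom index date (last event within the accumulation
# window after the first event).
timeline_outcome <- function(tl, config) {
  if (is.null(tl$diagnosis)) return(FALSE)
  first <- min(tl$events$event_date)
  win <- tl$events$event_date[tl$events$event_date <=
                                first + config$accumulation_window_days]
  index <- max(win)
  lag <- as.numeric(tl$diagnosis$date - index)
  lag >= 0 && lag <= config$followup_window_days
}

#' Cohort description summary
#'
#' Counts, medians and IQRs by cancer status (age at first presentation,
#' number of symptomatic presentations, sex split), the pre-diagnosis
#' presenter fraction, plus the group-comparison tests: Pearson chi-square
#' for sex (unknown-sex patients excluded) and Mann-Whitney U for the
#' continuous variables.
#'
#' @param timelines List of `pc_timeline`.
#' @param config A [cohort_config()].
#' @return List with `table1` (tidy data frame) and `counts`.
#' @export
summarise_cohort <- function(timelines, config = cohort_config()) {
  if (length(timelines) == 0) stop("no timelines to summarise",
                                   call. = FALSE)
  cancer <- vapply(timelines, timeline_outcome, logical(1), config = config)
  sex <- vapply(timelines, `[[`, "", "sex")
  age1 <- vapply(timelines, function(tl) {
    age_at(tl$birth_date, min(tl$events$event_date))
  }, numeric(1))
  nvisit <- vapply(timelines, function(tl) {
    length(unique(tl$events$event_date))
  }, numeric(1))

  prediag_presenter <- vapply(timelines, function(tl) {
    if (is.null(tl$diagnosis)) return(FALSE)
    any(tl$events$event_date >= tl$diagnosis$date - 365 &
          tl$events$event_date <= tl$diagnosis$date)
  }, logical(1))

  med_iqr <- function(x) {
    if (length(x) == 0) return("")
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    sprintf("%.0f (%.0f, %.0f)", q[2], q[1], q[3])
  }
  pct <- function(num, den) {
    if (den == 0) return("")
    sprintf("%d (%.1f%%)", num, 100 * num / den)
  }
  n <- length(timelines)
  nc <- sum(cancer)
  known <- sex != "unknown"
  p_sex <- if (nc > 0 && sum(known) > 0) {
    compare_proportions(sex[known & cancer] == "male",
                        sex[known & !cancer] == "male")$p_value
  } else NA_real_
  p_age <- if (nc > 0) {
    compare_distributions(age1[cancer], age1[!cancer])$p_value
  } else NA_real_
  p_nvisit <- if (nc > 0) {
    compare_distributions(nvisit[cancer], nvisit[!cancer])$p_value
  } else NA_real_

  note <- if (nc == 0) "cancer stratum empty; stratified cells omitted" else ""
  row <- function(metric, all, ca, nonca, p = NA_real_) {
    data.frame(metric = metric, all_patients = all, cancer = ca,
               non_cancer = nonca, p_value = p, stringsAsFactors = FALSE)
  }
  table1 <- rbind(
    row("n", as.character(n), as.character(nc), as.character(n - nc)),
    row("sex_male", pct(sum(sex == "male"), n),
        pct(sum(sex == "male" & cancer), nc),
        pct(sum(sex == "male" & !cancer), n - nc), p_sex),
    row("sex_female", pct(sum(sex == "female"), n),
        pct(sum(sex == "female" & cancer), nc),
        pct(sum(sex == "female" & !cancer), n - nc)),
    row("sex_unknown", pct(sum(sex == "unknown"), n),
        pct(sum(sex == "unknown" & cancer), nc),
        pct(sum(sex == "unknown" & !cancer), n - nc)),
    row("age_at_presentation", med_iqr(age1), med_iqr(age1[cancer]),
        med_iqr(age1[!cancer]), p_age),
    row("n_symptomatic_presentations", med_iqr(nvisit),
        med_iqr(nvisit[cancer]), med_iqr(nvisit[!cancer]), p_nvisit),
    row("prediagnosis_presenters", "",
        pct(sum(prediag_presenter & cancer), nc), "")
  )
  if (nzchar(note)) table1 <- rbind(table1, row("note", note, "", ""))
  list(table1 = table1,
       counts = list(n = n, cancer = nc, non_cancer = n - nc,
                     prediag_presenters = sum(prediag_presenter & cancer)))
}

prevalence_table <- function(timelines, config) {
  cancer <- vapply(timelines, timeline_outcome, logical(1), config = config)
  nc <- sum(cancer)
  nn <- sum(!cancer)
  presenters <- Filter(function(tl) {
    !is.null(tl$diagnosis) &&
      any(tl$events$event_date >= tl$diagnosis$date - 365 &
            tl$events$event_date <= tl$diagnosis$date)
  }, timelines[cancer])
  np <- length(presenters)
  rows <- lapply(canonical_symptoms(), function(code) {
    has <- vapply(timelines, function(tl) {
      code %in% tl$events$symptom_code
    }, logical(1))
    pre <- vapply(presenters, function(tl) {
      any(tl$events$symptom_code == code &
            tl$events$event_date >= tl$diagnosis$date - 365 &
            tl$events$event_date <= tl$diagnosis$date)
    }, logical(1))
    data.frame(
      symptom = code,
      n_cancer = sum(has & cancer),
      p_cancer = if (nc > 0) round(sum(has & cancer) / nc, 4) else NA,
      n_noncancer = sum(has & !cancer),
      p_noncancer = if (nn > 0) round(sum(has & !cancer) / nn, 4) else NA,
      n_prediag = sum(pre),
      p_prediag = if (np > 0) round(sum(pre) / np, 4) else NA,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
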