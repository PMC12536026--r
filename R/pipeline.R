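#' Pipeline run configuration
#'
#' Defaults encode the acquisition and analysis constants the pipeline is
#' built around: 2-s repetition time, 10 discarded volumes, a 0.01-0.1 Hz
#' passband, a +/-10 s lag grid with the coupling index read at +4 s,
#' 10,000 permutation draws and 1,000 calibration bootstrap repetitions.
#'
#' @param tr Repetition time, seconds.
#' @param n_discard Leading volumes dropped per signal.
#' @param passband Band edges in Hz.
#' @param max_lag,index_lag Correlogram range and index lag, seconds.
#' @param n_perm Permutation draws for the coupling null.
#' @param n_boot Bootstrap repetitions for calibration.
#' @param normality_alpha Shapiro-Wilk gate for test selection.
#' @param seed Master seed; stage seeds are derived from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(tr = 2, n_discard = 10, passband = c(0.01, 0.1),
                       max_lag = 10, index_lag = 4, n_perm = 10000,
                       n_boot = 1000, normality_alpha = 0.05, seed = 1L) {
  stopifnot(tr > 0, n_discard >= 0, passband[1] > 0,
            passband[1] < passband[2], passband[2] < 1 / (2 * tr),
            max_lag >= index_lag, n_perm >= 1, n_boot >= 1)
  structure(list(tr = tr, n_discard = as.integer(n_discard),
                 passband = passband, max_lag = max_lag,
                 index_lag = index_lag, n_perm = as.integer(n_perm),
                 n_boot = as.integer(n_boot),
                 normality_alpha = normality_alpha,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a subject marker table (CSV)
#'
#' @param table A subject marker data.frame.
#' @param path File path.
#' @return `read_subject_table` returns the data.frame;
#'   `write_subject_table` returns `path` invisibly.
#' @export
write_subject_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subject_table
#' @export
read_subject_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a two-signal TSV file
#'
#' Tab-separated columns `time_s`, `gbold`, `csf`, preceded by a comment
#' header recording `tr` and `t0` so the sampling grid round-trips.
#'
#' @param pair A list with `gbold` and `csf` [glym_ts()] elements on the
#'   same grid.
#' @param path File path.
#' @return `read_signal_tsv` returns such a pair; `write_signal_tsv`
#'   returns `path` invisibly.
#' @export
write_signal_tsv <- function(pair, path) {
  check_same_grid(pair$gbold, pair$csf)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tr=%.10g t0=%.10g", pair$gbold$tr, pair$gbold$t0),
             con)
  utils::write.table(
    data.frame(time_s = ts_times(pair$gbold),
               gbold = pair$gbold$values, csf = pair$csf$values),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_signal_tsv
#' @export
read_signal_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  m <- regmatches(header,
                  regexec("^# tr=([0-9.eE+-]+) t0=([0-9.eE+-]+)", header))[[1]]
  if (length(m) != 3L) stop("signal file lacks the '# tr=... t0=...' header: ",
                            path)
  tr <- as.numeric(m[2]); t0 <- as.numeric(m[3])
  d <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  need <- c("time_s", "gbold", "csf")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("signal file ", path, " lacks column(s): ",
                         paste(miss, collapse = ", "))
  list(gbold = glym_ts(d$gbold, tr = tr, t0 = t0),
       csf = glym_ts(d$csf, tr = tr, t0 = t0))
}

subject_table_schema <- list(
  required = c("subject_id", "group", "alps_index", "coupling_index",
               "cpv_ml", "tiv_ml", "cpv_fraction_pct"),
  numeric = c("age", "bmi", "education_years", "alsfrs_r", "duration_months",
              "progression_rate", "alps_index", "coupling_index", "cpv_ml",
              "tiv_ml", "cpv_fraction_pct")
)

#' Validate a subject marker table
#'
#' Schema, range, and internal-consistency checks on a subject table:
#' required columns, unique ids, recognized group labels, ALSFRS-R within
#' 0-48, positive durations and volumes, CPV smaller than TIV, and the
#' derived columns (`cpv_fraction_pct`, `progression_rate`) consistent with
#' their source columns to 1e-6.
#'
#' @param table A data.frame, or a path to a CSV readable by
#'   [read_subject_table()].
#' @return A data.frame `severity` (`"error"`/`"warning"`), `column`,
#'   `message`; zero rows when the table is clean.
#' @export
validate_subject_table <- function(table) {
  if (is.character(table)) table <- read_subject_table(table)
  issues <- list()
  note <- function(severity, column, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, column = column, message = message)
  }
  miss <- setdiff(subject_table_schema$required, names(table))
  for (m in miss) note("error", m, "required column is missing")
  if (!length(miss)) {
    if (anyDuplicated(table$subject_id)) {
      note("error", "subject_id", "subject ids are not unique")
    }
    bad_group <- setdiff(unique(table$group), c("ALS", "HC"))
    if (length(bad_group)) {
      note("error", "group",
           paste("unrecognized group label(s):",
                 paste(bad_group, collapse = ", ")))
    }
    num_cols <- intersect(subject_table_schema$numeric, names(table))
    for (cl in num_cols) {
      if (!is.numeric(table[[cl]])) note("error", cl, "column is not numeric")
    }
    rng_check <- function(col, ok, msg) {
      v <- table[[col]]
      if (is.numeric(v) && any(!ok(v[!is.na(v)]))) note("error", col, msg)
    }
    rng_check("alsfrs_r", function(v) v >= 0 & v <= 48,
              "ALSFRS-R outside [0, 48]")
    rng_check("duration_months", function(v) v > 0,
              "disease duration must be positive")
    rng_check("cpv_ml", function(v) v > 0, "CPV must be positive")
    rng_check("tiv_ml", function(v) v > 0, "TIV must be positive")
    if (is.numeric(table$cpv_ml) && is.numeric(table$tiv_ml)) {
      if (any(table$cpv_ml >= table$tiv_ml, na.rm = TRUE)) {
        note("error", "cpv_ml", "CPV must be smaller than TIV")
      }
      expect <- 100 * table$cpv_ml / table$tiv_ml
      off <- abs(table$cpv_fraction_pct - expect) > 1e-6
      if (any(off, na.rm = TRUE)) {
        note("error", "cpv_fraction_pct",
             "inconsistent with 100*cpv_ml/tiv_ml by more than 1e-6")
      }
    }
    if (all(c("progression_rate", "alsfrs_r", "duration_months") %in%
              names(table))) {
      i <- stats::complete.cases(table$progression_rate, table$alsfrs_r,
                                 table$duration_months)
      expect <- (48 - table$alsfrs_r[i]) / table$duration_months[i]
      if (any(abs(table$progression_rate[i] - expect) > 1e-6)) {
        note("error", "progression_rate",
             "inconsistent with (48 - alsfrs_r)/duration_months")
      }
    }
  }
  if (!length(issues)) {
    return(data.frame(severity = character(), column = character(),
                      message = character()))
  }
  do.call(rbind, issues)
}

# Default within-ALS correlation family: the nine marker-clinical pairs.
default_correlation_pairs <- function() {
  list(c("alps_index", "cpv_fraction_pct"),
       c("alps_index", "coupling_index"),
       c("alps_index", "progression_rate"),
       c("alps_index", "alsfrs_r"),
       c("coupling_index", "progression_rate"),
       c("coupling_index", "alsfrs_r"),
       c("cpv_fraction_pct", "progression_rate"),
       c("cpv_fraction_pct", "alsfrs_r"),
       c("alsfrs_r", "progression_rate"))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' End-to-end exercise of every stage on generated data: (1) a synthetic
#' marker table ([generate_marker_table()]) feeds the group comparisons,
#' the FDR-corrected ALS-group correlation family, the partial
#' ALPS-CPVfraction correlation given disease duration, per-marker ROC
#' analyses, the combined logistic nomogram, bootstrap calibration and the
#' decision curve; (2) a cohort of derivative-coupled signal pairs
#' ([generate_signal_cohort()]) feeds preprocessing, the per-subject
#' correlograms and the permutation null of the group-mean correlogram.
#' The marker table drives the statistics and diagnostics; the signal
#' pathway demonstrates how the coupling marker itself is measured.
#'
#' @param config A [run_config()].
#' @param cohort A [cohort_config()]; its seed defaults to the run seed.
#' @param signals A [signal_config()] template for the signal cohort;
#'   `n_signal_subjects` pairs are generated.
#' @param n_signal_subjects Number of signal-pair subjects (default
#'   `cohort$n_als + cohort$n_hc`).
#' @param out_dir Optional directory; when given, the stage outputs are
#'   written there (subject table CSV, comparisons CSV, correlations CSV,
#'   per-subject coupling CSV, group coupling JSON, ROC summary CSV, model
#'   + nomogram JSON, calibration CSV, DCA CSV).
#' @return A named list bundle with elements `subject_table`,
#'   `comparisons`, `correlations`, `partial_alps_cpv`, `coupling`
#'   (per-subject results), `group_correlogram`, `permutation`, `roc`
#'   (per-marker list), `model`, `nomogram`, `calibration`, `dca`,
#'   `config`.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL,
                         signals = NULL, n_signal_subjects = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max, 4)
  if (is.null(cohort)) cohort <- cohort_config(seed = stage_seeds[1])
  if (is.null(signals)) {
    signals <- signal_config(tr = config$tr, passband = config$passband,
                             seed = stage_seeds[2])
  }
  if (is.null(n_signal_subjects)) {
    n_signal_subjects <- cohort$n_als + cohort$n_hc
  }

  tab <- generate_marker_table(cohort)
  issues <- validate_subject_table(tab)
  if (any(issues$severity == "error")) {
    stop("generated subject table failed validation: ",
         paste(issues$message, collapse = "; "))
  }

  comparisons <- marker_comparisons(tab,
                                    normality_alpha = config$normality_alpha)
  als <- tab[tab$group == "ALS", ]
  correlations <- correlation_matrix(als, default_correlation_pairs())
  partial <- partial_correlation(als$alps_index, als$cpv_fraction_pct,
                                 als$duration_months)

  pairs <- generate_signal_cohort(n_signal_subjects, signals)
  coupling <- cohort_coupling(pairs, n_discard = config$n_discard,
                              low = config$passband[1],
                              high = config$passband[2],
                              max_lag = config$max_lag,
                              index_lag = config$index_lag)
  group_cc <- group_mean_correlogram(coupling$correlograms)
  perm <- permutation_test(coupling$prepped, max_lag = config$max_lag,
                           n_perm = config$n_perm, seed = stage_seeds[3])

  roc <- list(
    coupling_index = roc_analysis(tab$coupling_index, tab$group,
                                  direction = "less"),
    alps_index = roc_analysis(tab$alps_index, tab$group,
                              direction = "less"),
    cpv_fraction_pct = roc_analysis(tab$cpv_fraction_pct, tab$group,
                                    direction = "greater"))
  model <- fit_logistic(tab[c("coupling_index", "alps_index",
                              "cpv_fraction_pct")], tab$group)
  roc$combined <- roc_analysis(model$fitted, tab$group,
                               direction = "greater")
  nomogram <- build_nomogram(model)
  calibration <- calibration_bootstrap(model, n_boot = config$n_boot,
                                       seed = stage_seeds[4])
  dca <- decision_curve(model$fitted, tab$group)

  bundle <- list(subject_table = tab, comparisons = comparisons,
                 correlations = correlations, partial_alps_cpv = partial,
                 coupling = coupling$results,
                 group_correlogram = group_cc, permutation = perm,
                 roc = roc, model = model, nomogram = nomogram,
                 calibration = calibration, dca = dca, config = config)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

roc_summary_row <- function(name, r) {
  data.frame(marker = name, auc = r$auc, ci_low = r$ci95[1],
             ci_high = r$ci95[2], cutoff = r$cutoff,
             sensitivity = r$sens_at_cutoff, specificity = r$spec_at_cutoff,
             higher_is_positive = r$direction == "greater")
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_subject_table(bundle$subject_table, p("subject_table.csv"))
  utils::write.csv(bundle$comparisons, p("group_comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$correlations, p("als_correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$coupling, p("coupling_by_subject.csv"),
                   row.names = FALSE)
  perm <- bundle$permutation
  jsonlite::write_json(list(
    config = unclass(bundle$config),
    lags = perm$lags, mean_r = perm$observed, p = perm$p,
    band95_low = perm$band95[1, ], band95_high = perm$band95[2, ],
    n_perm = perm$n_perm, seed = perm$seed),
    p("group_coupling.json"), auto_unbox = TRUE, digits = NA)
  roc_tab <- do.call(rbind, Map(roc_summary_row, names(bundle$roc),
                                bundle$roc))
  utils::write.csv(roc_tab, p("roc_summary.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    intercept = bundle$model$intercept,
    coefficients = as.list(bundle$model$coefficients),
    points_per_lp = bundle$nomogram$points_per_lp,
    lp_at_zero_points = bundle$nomogram$lp_at_zero_points,
    prob_table = bundle$nomogram$prob_table),
    p("model_nomogram.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(bundle$calibration), p("calibration.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$dca), p("decision_curve.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
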