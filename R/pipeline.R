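#' Study configuration
#'
#' Collects every knob of the end-to-end workflow in one validated list.
#' Defaults are the study conditions the package models: a 19-channel 10-20
#' montage at 200 Hz, 6-minute recordings, 12 responsive and 9 non-responsive
#' subjects recorded pre and post intervention, K = 4 classes, 0.1-40 Hz
#' band-pass with 50 Hz notch, 2 s epochs rejected beyond +-150 uV, 30 ms
#' minimum segment duration, and a planted post-course increase of class-C
#' dwell (75 -> 90 ms) in the responsive arm only.
#'
#' @param mode `"synthetic"` (simulate the cohort) or `"files"` (read
#'   recordings listed in `files`).
#' @param n_re,n_nre synthetic group sizes (default 12 and 9).
#' @param duration_s recording length per session in seconds (default 360).
#' @param fs sampling rate in Hz (default 200).
#' @param mont montage (default 19-channel 10-20).
#' @param K number of microstate classes (4, 5 or 6; default 4).
#' @param snr synthetic signal-to-noise ratio (default 5).
#' @param effect planted responder effect: list with `class` (label) and
#'   `post_dwell_ms`; `NULL` for a null simulation.
#' @param notch,bandpass,epoch_s,reject_uv preprocessing settings.
#' @param n_restarts,peaks_per_subject clustering settings.
#' @param min_duration_ms segmentation smoothing floor.
#' @param alpha significance level (default 0.05).
#' @param seed master seed; every random stage derives from it.
#' @param files data.frame with columns `subject`, `session` (pre/post),
#'   `group` (RE/N-RE), `path` — required in `"files"` mode.
#' @return object of class `study_config`.
#' @export
study_config <- function(mode = c("synthetic", "files"),
                         n_re = 12, n_nre = 9, duration_s = 360, fs = 200,
                         mont = montage(), K = 4, snr = 5,
                         effect = list(class = "C", post_dwell_ms = 90),
                         notch = 50, bandpass = c(0.1, 40),
                         epoch_s = 2, reject_uv = 150,
                         n_restarts = 20, peaks_per_subject = 1000,
                         min_duration_ms = 30, alpha = 0.05,
                         seed = 1, files = NULL) {
  mode <- match.arg(mode)
  if (mode == "files") {
    if (is.null(files)) stop("files mode needs a files table")
    need <- c("subject", "session", "group", "path")
    if (!all(need %in% names(files))) {
      stop("files table needs columns: ", paste(need, collapse = ", "))
    }
    if (!all(file.exists(files$path))) stop("missing recording file(s)")
  }
  if (!K %in% 2:6) stop("K must be in 2..6")
  structure(as.list(environment()), class = "study_config")
}

#' Simulate a pre/post cohort of recordings
#'
#' All subjects share one set of ground-truth templates (the canonical A-D
#' maps on the configured montage). Responsive subjects' post-course
#' recordings get the configured class dwell effect; everything else is
#' exchangeable between sessions and groups.
#'
#' @param config `study_config` (synthetic mode).
#' @return list of records, each `list(subject, session, group, rec, truth)`.
#' @export
simulate_cohort <- function(config) {
  templates <- canonical_templates(config$mont, config$K)
  base_dwell <- if (config$K == 4) c(85, 85, 75, 95) else rep(80, config$K)
  groups <- c(rep("RE", config$n_re), rep("N-RE", config$n_nre))
  out <- list()
  i <- 0L
  for (s in seq_along(groups)) {
    for (session in c("pre", "post")) {
      i <- i + 1L
      dwell <- base_dwell
      if (!is.null(config$effect) && groups[s] == "RE" && session == "post") {
        k <- match(config$effect$class, LETTERS[seq_len(config$K)])
        if (is.na(k)) stop("effect class not among the model classes")
        dwell[k] <- config$effect$post_dwell_ms
      }
      truth <- ground_truth(templates, mean_dwell_ms = dwell, snr = config$snr)
      sim <- synthesize_eeg(truth, duration_s = config$duration_s, fs = config$fs,
                            seed = config$seed + 97L * i, mont = config$mont)
      out[[i]] <- list(subject = sprintf("S%02d", s), session = session,
                       group = groups[s], rec = sim$rec, truth = sim$truth)
    }
  }
  out
}

#' Run the full microstate study workflow
#'
#' Simulates or loads all recordings, preprocesses each (notch, band-pass,
#' epoch rejection, average reference), derives one set of prototype maps
#' from the pooled GFP peaks of every recording (both sessions, both groups —
#' so pre/post differences can never come from different template sets),
#' back-fits and smooths each recording, extracts temporal parameters and
#' transition syntax, and compares post against pre within each group
#' (two-level repeated-measures ANOVA per class and parameter, FDR within
#' each parameter family; paired t per directed transition pair, FDR over
#' the K(K-1) pairs).
#'
#' @param config `study_config`.
#' @return object of class `study_report`: `params` (per-recording tidy
#'   parameter table), `table2` (group x class x parameter pre/post summary
#'   with F and FDR-adjusted p), `transitions` (directed-pair pre/post
#'   summary with adjusted p), `model`, `gev` (pooled-peak clustering GEV),
#'   `subject_gev` (per-recording total GEV), and `provenance`.
#' @export
run_study <- function(config) {
  records <- if (config$mode == "synthetic") {
    simulate_cohort(config)
  } else {
    lapply(seq_len(nrow(config$files)), function(i) {
      f <- config$files[i, ]
      list(subject = as.character(f$subject), session = as.character(f$session),
           group = as.character(f$group),
           rec = read_recording(f$path, mont = config$mont, fs = config$fs),
           truth = NULL)
    })
  }
  prepped <- lapply(records, function(r) {
    preprocess(r$rec, notch = config$notch, bandpass = config$bandpass,
               epoch_s = config$epoch_s, reject_uv = config$reject_uv)
  })
  agg <- aggregate_group_prototypes(lapply(prepped, `[[`, "rec"),
                                    K = config$K,
                                    peaks_per_subject = config$peaks_per_subject,
                                    seed = config$seed,
                                    n_restarts = config$n_restarts)
  model <- agg$model

  params <- list(); trans <- list(); subject_gev <- numeric(length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    seg <- backfit(model, prepped[[i]]$rec, epoch_starts = prepped[[i]]$epoch_starts)
    seg <- smooth_segmentation(seg, config$min_duration_ms)
    tp <- temporal_parameters(seg)
    gev <- global_explained_variance(model, prepped[[i]]$rec, seg)
    subject_gev[i] <- gev$total
    params[[i]] <- data.frame(subject = r$subject, session = r$session,
                              group = r$group, tp,
                              gev = unname(gev$per_class),
                              stringsAsFactors = FALSE)
    tm <- transition_syntax(seg)
    pr <- symmetric_pair_rates(tm)
    trans[[i]] <- data.frame(subject = r$subject, session = r$session,
                             group = r$group, pr, stringsAsFactors = FALSE)
  }
  params <- do.call(rbind, params)
  trans <- do.call(rbind, trans)

  report <- structure(list(
    params = params,
    table2 = summarize_parameters(params, config$alpha),
    transitions = summarize_transitions(trans, config$alpha),
    model = model,
    gev = agg$gev,
    subject_gev = subject_gev,
    provenance = list(seed = config$seed, K = config$K, mode = config$mode,
                      n_recordings = length(records),
                      package_version = as.character(utils::packageVersion("eegmicrostates")))
  ), class = "study_report")
  report
}

# Table-2-shaped pre/post comparison: per group, class and parameter, paired
# RM-ANOVA across subjects with FDR within each (group, parameter) family.
summarize_parameters <- function(params, alpha) {
  families <- expand.grid(group = unique(params$group),
                          parameter = c("duration_ms", "occurrence_per_s", "coverage"),
                          stringsAsFactors = FALSE)
  out <- list()
  for (f in seq_len(nrow(families))) {
    g <- families$group[f]; pname <- families$parameter[f]
    sub <- params[params$group == g, ]
    classes <- unique(sub$class)
    rows <- lapply(classes, function(k) {
      wide <- merge(sub[sub$session == "pre" & sub$class == k, c("subject", pname)],
                    sub[sub$session == "post" & sub$class == k, c("subject", pname)],
                    by = "subject", suffixes = c("_pre", "_post"))
      pre <- wide[[paste0(pname, "_pre")]]; post <- wide[[paste0(pname, "_post")]]
      st <- rm_anova_two_level(pre, post)
      data.frame(group = g, class = k, parameter = pname,
                 pre_mean = mean(pre), pre_sd = stats::sd(pre),
                 post_mean = mean(post), post_sd = stats::sd(post),
                 F = st$statistic, p = st$p, stringsAsFactors = FALSE)
    })
    fam <- do.call(rbind, rows)
    fam$p_adj <- fdr_bh(fam$p)
    out[[f]] <- fam
  }
  res <- do.call(rbind, out)
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  res
}

# Figure-5-shaped transition comparison: per group and directed pair, paired
# t across subjects with FDR over all K(K-1) pairs in the group.
summarize_transitions <- function(trans, alpha) {
  out <- list()
  for (g in unique(trans$group)) {
    sub <- trans[trans$group == g, ]
    pairs <- unique(sub[, c("from", "to")])
    rows <- lapply(seq_len(nrow(pairs)), function(i) {
      fr <- pairs$from[i]; to <- pairs$to[i]
      sel <- sub$from == fr & sub$to == to
      wide <- merge(sub[sel & sub$session == "pre", c("subject", "prob")],
                    sub[sel & sub$session == "post", c("subject", "prob")],
                    by = "subject", suffixes = c("_pre", "_post"))
      pre <- wide$prob_pre; post <- wide$prob_post
      st <- tryCatch(paired_t(pre, post),
                     error = function(e) stat_result("paired t", NA_real_, NA_real_, NA_real_))
      data.frame(group = g, from = fr, to = to,
                 pre_mean = mean(pre), post_mean = mean(post),
                 t = st$statistic, p = st$p, stringsAsFactors = FALSE)
    })
    fam <- do.call(rbind, rows)
    fam$p_adj <- fdr_bh(fam$p)
    fam$significant <- !is.na(fam$p_adj) & fam$p_adj < alpha
    out[[g]] <- fam
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cohort demographics and clinical outcome report
#'
#' Group means with SD for age and days since onset, the between-group pooled
#' t-tests (non-responsive minus responsive, the reporting convention for
#' this cohort), the responder count, and the paired t on CRS-R totals before
#' (T0) versus after (T2) the stimulation course over all patients. With a
#' single-group cohort the between-group tests are omitted with a notice.
#'
#' @param cohort cohort data.frame as returned by [cohort_fixture()].
#' @return object of class `cohort_report`.
#' @export
report_cohort <- function(cohort) {
  grp <- classify_responders(cohort)
  re <- cohort[grp == "RE", ]; nre <- cohort[grp == "N-RE", ]
  out <- list(
    n = nrow(cohort), n_re = nrow(re), n_nre = nrow(nre),
    re_age = c(mean = mean(re$age), sd = stats::sd(re$age)),
    nre_age = c(mean = mean(nre$age), sd = stats::sd(nre$age)),
    re_course = c(mean = mean(re$course_days), sd = stats::sd(re$course_days)),
    nre_course = c(mean = mean(nre$course_days), sd = stats::sd(nre$course_days)),
    crsr_t0_vs_t2 = paired_t(cohort$crsr_t0, cohort$crsr_t2),
    notice = NULL
  )
  if (nrow(re) >= 2 && nrow(nre) >= 2) {
    out$age_test <- two_sample_t_pooled(nre$age, re$age)
    out$course_test <- two_sample_t_pooled(nre$course_days, re$course_days)
    out$sex_test <- mann_whitney(as.integer(factor(nre$sex, c("F", "M"))),
                                 as.integer(factor(re$sex, c("F", "M"))))
  } else {
    out$notice <- "single-group cohort: between-group tests omitted"
  }
  structure(out, class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort: %d patients (%d RE, %d N-RE)\n", x$n, x$n_re, x$n_nre))
  cat(sprintf("  age (y):    RE %.2f +- %.2f, N-RE %.2f +- %.2f\n",
              x$re_age["mean"], x$re_age["sd"], x$nre_age["mean"], x$nre_age["sd"]))
  cat(sprintf("  course (d): RE %.2f +- %.2f, N-RE %.2f +- %.2f\n",
              x$re_course["mean"], x$re_course["sd"],
              x$nre_course["mean"], x$nre_course["sd"]))
  if (!is.null(x$notice)) {
    cat("  ", x$notice, "\n", sep = "")
  } else {
    cat(sprintf("  age:    t = %.3f, p = %.3f\n", x$age_test$statistic, x$age_test$p))
    cat(sprintf("  course: t = %.3f, p = %.3f\n", x$course_test$statistic, x$course_test$p))
    cat(sprintf("  sex:    z = %.3f, p = %.3f\n", x$sex_test$z, x$sex_test$p))
  }
  cat(sprintf("  CRS-R T0 vs T2 (paired): t = %.3f, p = %.3f\n",
              x$crsr_t0_vs_t2$statistic, x$crsr_t0_vs_t2$p))
  invisible(x)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Microstate study report (K = %d, %d recordings, seed %d)\n",
              x$provenance$K, x$provenance$n_recordings, x$provenance$seed))
  cat(sprintf("  pooled-peak clustering GEV: %.3f; mean per-recording GEV: %.3f\n",
              x$gev, mean(x$subject_gev)))
  sig <- x$table2[x$table2$significant, ]
  if (nrow(sig) > 0) {
    cat("  significant pre/post parameter changes (FDR):\n")
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("    %s class %s %s: %.2f -> %.2f (F = %.2f, p_adj = %.4f)\n",
                  sig$group[i], sig$class[i], sig$parameter[i],
                  sig$pre_mean[i], sig$post_mean[i], sig$F[i], sig$p_adj[i]))
    }
  } else cat("  no significant pre/post parameter changes after FDR\n")
  sigt <- x$transitions[x$transitions$significant, ]
  if (nrow(sigt) > 0) {
    cat("  significant transition changes (FDR):\n")
    for (i in seq_len(nrow(sigt))) {
      cat(sprintf("    %s %s->%s: %.3f -> %.3f (p_adj = %.4f)\n",
                  sigt$group[i], sigt$from[i], sigt$to[i],
                  sigt$pre_mean[i], sigt$post_mean[i], sigt$p_adj[i]))
    }
  } else cat("  no significant transition changes after FDR\n")
  invisible(x)
}

#' Write the study report tables to a directory
#'
#' Emits `parameters.csv` (per-recording tidy table), `table2.csv`,
#' `transitions.csv`, `model_maps.csv` plus a JSON sidecar with labels and
#' provenance.
#'
#' @param report `study_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$params, file.path(dir, "parameters.csv"), row.names = FALSE)
  utils::write.csv(report$table2, file.path(dir, "table2.csv"), row.names = FALSE)
  utils::write.csv(report$transitions, file.path(dir, "transitions.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$model$maps), file.path(dir, "model_maps.csv"),
                   row.names = TRUE)
  jsonlite::write_json(list(labels = report$model$labels, K = report$model$K,
                            gev = report$gev, provenance = report$provenance),
                       file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
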