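#' Configuration of one experimental session
#'
#' Session 1 screens three combined-stimulus dB ratios with 2 min baseline and
#' 3 min stimulation; session 2 compares the selected combination against
#' SHAM, beat-only and natural-sound-only with 2 min baseline, 10 min
#' stimulation and a 2 min post-stimulus rest.
#'
#' @param session 1 or 2.
#' @param conditions Condition labels the cohort must contain.
#' @param baseline,stimulation,post Epoch durations, seconds.
#' @return A `session_config` list.
#' @export
session_config <- function(session = 1,
                           conditions = if (session == 1)
                             c("CS1", "CS2", "CS3")
                           else c("SHAM", "BB", "AT", "CS"),
                           baseline = 120,
                           stimulation = if (session == 1) 180 else 600,
                           post = if (session == 1) 0 else 120) {
  stopifnot(session %in% c(1, 2), baseline > 0, stimulation > 0, post >= 0)
  if (session == 2 && post <= 0)
    stop("session 2 requires a post-stimulus resting epoch")
  structure(list(session = session, conditions = conditions,
                 timing = epoch_spec(baseline, stimulation, post)),
            class = "session_config")
}

# per-subject, per-condition spectral summaries shared by both sessions
cohort_spectra <- function(cohort, conditions, preprocess = TRUE,
                           with_post = FALSE, ...) {
  missing <- setdiff(conditions, cohort$conditions)
  if (length(missing))
    stop("cohort is missing conditions: ", paste(missing, collapse = ", "))
  res <- list()
  for (s in seq_len(cohort$n)) {
    for (cond in conditions) {
      rec <- cohort$subjects[[s]][[cond]]
      if (preprocess && rec$fs > 250) rec <- preprocess_recording(rec)
      tb_base <- band_power_table(rec, "baseline", ...)
      tb_stim <- band_power_table(rec, "stimulation", ...)
      chg <- power_change(tb_stim, tb_base)
      reg <- region_power_table(chg)
      entry <- list(
        subject = s, condition = cond,
        band_change = stats::aggregate(power ~ band, data = chg, FUN = mean),
        region_theta = reg[reg$band == "theta", ],
        peak = peak_at_target(rec, ...)
      )
      if (with_post) {
        tb_post <- band_power_table(rec, "post", ...)
        entry$theta_prepost <- tibble::tibble(
          subject = s, condition = cond,
          channel = tb_base$channel[tb_base$band == "theta"],
          pre = tb_base$power[tb_base$band == "theta"],
          post = tb_post$power[tb_post$band == "theta"])
        entry$li <- tibble::tibble(
          subject = s, condition = cond,
          pre = alpha_laterality(rec, "baseline", ...)$LI,
          post = alpha_laterality(rec, "post", ...)$LI)
      }
      res[[length(res) + 1L]] <- entry
    }
  }
  res
}

collect <- function(spectra, what) {
  do.call(rbind, lapply(spectra, function(e) {
    x <- e[[what]]
    tibble::tibble(subject = e$subject, condition = e$condition,
                   tibble::as_tibble(x))
  }))
}

paired_row <- function(vals, family) {
  r <- paired_t(vals)
  tibble::tibble(mean = r$mean, sd = r$sd, df = r$df, t = r$statistic,
                 p = r$p, p_adj = bonferroni(r$p, family), d = r$effect_size)
}

# condition x key summary of per-subject change values
change_stat_table <- function(df, key) {
  fams <- length(unique(df[[key]]))
  out <- list()
  for (cond in unique(df$condition)) {
    for (k in unique(df[[key]])) {
      vals <- df$power[df$condition == cond & df[[key]] == k]
      row <- paired_row(vals, fams)
      tb <- tibble::tibble(condition = cond, key = k, row)
      names(tb)[2] <- key
      out[[length(out) + 1L]] <- tb
    }
  }
  do.call(rbind, out)
}

# one-way ANOVA across conditions within each level of `key`, with
# Bonferroni-corrected pairwise paired-t post hocs
condition_anova_table <- function(df, key, value = "power",
                                  repeated = FALSE) {
  conds <- unique(df$condition)
  m_posthoc <- choose(length(conds), 2)
  out <- list(); posthoc <- list()
  for (k in unique(df[[key]])) {
    sub <- df[df[[key]] == k, ]
    groups <- lapply(conds, function(cc)
      sub[[value]][sub$condition == cc][order(sub$subject[sub$condition == cc])])
    names(groups) <- conds
    a <- one_way_anova(groups, repeated = repeated)
    tb <- tibble::tibble(key = k, df1 = a$df[["df1"]], df2 = a$df[["df2"]],
                         F = a$statistic, p = a$p, eta_p2 = a$effect_size)
    names(tb)[1] <- key
    out[[length(out) + 1L]] <- tb
    for (i in seq_len(length(conds) - 1)) {
      for (j in seq.int(i + 1, length(conds))) {
        r <- paired_row(groups[[i]] - groups[[j]], m_posthoc)
        tb <- tibble::tibble(key = k,
                             contrast = paste(conds[i], "vs", conds[j]), r)
        names(tb)[1] <- key
        posthoc[[length(posthoc) + 1L]] <- tb
      }
    }
  }
  list(anova = do.call(rbind, out), posthoc = do.call(rbind, posthoc))
}

brums_change_table <- function(responses, conditions,
                               mapping = brums_default_mapping()) {
  scored <- score_brums_table(responses, mapping)
  out <- list(); deltas <- list()
  for (cond in conditions) {
    pre <- scored[scored$condition == cond & scored$timepoint == "pre", ]
    post <- scored[scored$condition == cond & scored$timepoint == "post", ]
    pre <- pre[order(pre$subject), ]; post <- post[order(post$subject), ]
    for (f in brums_factors()) {
      vals <- post[[f]] - pre[[f]]
      out[[length(out) + 1L]] <- tibble::tibble(
        condition = cond, factor = f, paired_row(vals, length(brums_factors())))
      deltas[[length(deltas) + 1L]] <- tibble::tibble(
        subject = pre$subject, condition = cond, factor = f, power = vals)
    }
  }
  list(table = do.call(rbind, out), deltas = do.call(rbind, deltas))
}

# session-1 selection rule (a reconstruction, see Details of run_session1):
# per-subject winner by midline target-frequency peak, majority vote across
# subjects, ties broken by the mean calmness change, else indeterminate
select_condition <- function(peaks, calmness = NULL) {
  conds <- unique(peaks$condition)
  votes <- stats::setNames(numeric(length(conds)), conds)
  for (s in unique(peaks$subject)) {
    v <- peaks$peak[peaks$subject == s][match(conds, peaks$condition[peaks$subject == s])]
    mx <- max(v)
    if (sum(v == mx) == 1) {  # strict per-subject winner only
      w <- conds[which.max(v)]
      votes[w] <- votes[w] + 1
    }
  }
  if (all(votes == 0))
    return(list(selected = NA_character_, votes = votes, indeterminate = TRUE,
                rule = "reconstructed: midline peak vote, calmness tie-break"))
  top <- names(votes)[votes == max(votes)]
  tie_broken <- FALSE
  if (length(top) > 1) {
    if (is.null(calmness))
      return(list(selected = NA_character_, votes = votes,
                  indeterminate = TRUE,
                  rule = "reconstructed: midline peak vote, calmness tie-break"))
    cm <- vapply(top, function(cc)
      mean(calmness$power[calmness$condition == cc]), numeric(1))
    if (sum(cm == max(cm)) > 1)
      return(list(selected = NA_character_, votes = votes,
                  indeterminate = TRUE,
                  rule = "reconstructed: midline peak vote, calmness tie-break"))
    top <- top[which.max(cm)]
    tie_broken <- TRUE
  }
  list(selected = top, votes = votes, indeterminate = FALSE,
       tie_broken = tie_broken,
       rule = "reconstructed: midline peak vote, calmness tie-break")
}

#' Run the session-1 screening analysis
#'
#' For each combined-stimulus ratio: per-band power change across all
#' channels, regional theta change over the seven regions, across-condition
#' ANOVAs with paired post hocs, BRUMS-32 score changes, and the selection of
#' the ratio to carry into session 2. The codified selection rule -- the
#' condition winning the most per-subject midline target-frequency peaks,
#' ties broken by the calmness change -- is a reconstruction of the original
#' subject-level decision and is labeled as such in the output.
#'
#' @param cohort A [simulate_cohort()] result (or equivalent) holding the
#'   CS1/CS2/CS3 recordings.
#' @param brums Optional BRUMS-32 response table (see [simulate_brums()]).
#' @param config A [session_config()] (session 1).
#' @param preprocess Run [preprocess_recording()] on each recording first
#'   when its sampling rate exceeds 250 Hz.
#' @param ... Welch parameters passed down ([welch_psd()]).
#' @return List of class `session1_result`: `band_table`, `region_table`,
#'   `region_anova`, `region_posthoc`, `peaks`, `brums_table`, `selection`.
#' @export
run_session1 <- function(cohort, brums = NULL, config = session_config(1),
                         preprocess = TRUE, ...) {
  stopifnot(inherits(config, "session_config"), config$session == 1)
  sp <- cohort_spectra(cohort, config$conditions, preprocess = preprocess, ...)
  band_changes <- collect(sp, "band_change")
  names(band_changes)[names(band_changes) == "power"] <- "power"
  region_theta <- collect(sp, "region_theta")
  peaks <- do.call(rbind, lapply(sp, function(e)
    tibble::tibble(subject = e$subject, condition = e$condition,
                   peak = e$peak)))
  anv <- condition_anova_table(region_theta, "region")
  brums_out <- NULL; calmness <- NULL
  if (!is.null(brums)) {
    b <- brums_change_table(brums, config$conditions)
    brums_out <- b$table
    calmness <- b$deltas[b$deltas$factor == "calmness", ]
  }
  structure(list(
    band_table = change_stat_table(band_changes, "band"),
    region_table = change_stat_table(region_theta, "region"),
    region_anova = anv$anova,
    region_posthoc = anv$posthoc,
    peaks = peaks,
    brums_table = brums_out,
    selection = select_condition(peaks, calmness)
  ), class = "session1_result")
}

#' Run the session-2 comparison analysis
#'
#' Compares the selected combined stimulus against SHAM, beat-only and
#' natural-sound-only: per-band and regional theta changes during
#' stimulation, across-condition ANOVAs, the channel-by-phase two-way ANOVA
#' on resting theta before vs after stimulation, per-channel paired tests
#' with Bonferroni correction over the 19 channels, the frontal alpha
#' laterality index before vs after, and BRUMS-32 changes. Every statistics
#' row carries the statistic, df, raw and adjusted p, and an effect size.
#'
#' @inheritParams run_session1
#' @param config A [session_config()] (session 2; must include a post epoch).
#' @return List of class `session2_result`: `band_table`, `region_table`,
#'   `region_anova`, `region_posthoc`, `two_way`, `channel_tests`,
#'   `li_table`, `brums_table`, `peaks`.
#' @export
run_session2 <- function(cohort, brums = NULL, config = session_config(2),
                         preprocess = TRUE, ...) {
  stopifnot(inherits(config, "session_config"), config$session == 2)
  sp <- cohort_spectra(cohort, config$conditions, preprocess = preprocess,
                       with_post = TRUE, ...)
  band_changes <- collect(sp, "band_change")
  region_theta <- collect(sp, "region_theta")
  prepost <- do.call(rbind, lapply(sp, `[[`, "theta_prepost"))
  li <- do.call(rbind, lapply(sp, `[[`, "li"))
  peaks <- do.call(rbind, lapply(sp, function(e)
    tibble::tibble(subject = e$subject, condition = e$condition,
                   peak = e$peak)))
  anv <- condition_anova_table(region_theta, "region")

  # Table-7-style channel x stimulation two-way ANOVA, one per condition
  two_way <- list(); chan_tests <- list()
  n_chan <- length(unique(prepost$channel))
  for (cond in config$conditions) {
    sub <- prepost[prepost$condition == cond, ]
    long <- tibble::tibble(
      power = c(sub$pre, sub$post),
      channel = rep(sub$channel, 2),
      phase = rep(c("pre", "post"), each = nrow(sub)),
      subject = rep(sub$subject, 2))
    tw <- two_way_anova(long)
    for (src in names(tw)) {
      two_way[[length(two_way) + 1L]] <- tibble::tibble(
        condition = cond,
        source = c(channel = "Channel", stimulation = "Stimulation",
                   interaction = "Channel x stimulation")[[src]],
        df1 = tw[[src]]$df[["df1"]], df2 = tw[[src]]$df[["df2"]],
        F = tw[[src]]$statistic, p = tw[[src]]$p,
        eta_p2 = tw[[src]]$effect_size)
    }
    for (ch in unique(sub$channel)) {
      d <- sub$post[sub$channel == ch] - sub$pre[sub$channel == ch]
      chan_tests[[length(chan_tests) + 1L]] <- tibble::tibble(
        condition = cond, channel = ch, paired_row(d, n_chan))
    }
  }
  chan_tests <- do.call(rbind, chan_tests)
  chan_tests$significant <- chan_tests$p_adj < 0.05

  li_rows <- lapply(config$conditions, function(cond) {
    d <- li[li$condition == cond, ]
    tibble::tibble(condition = cond, li_pre = mean(d$pre),
                   li_post = mean(d$post),
                   paired_row(d$post - d$pre, length(config$conditions)))
  })

  brums_out <- NULL
  if (!is.null(brums)) brums_out <- brums_change_table(brums, config$conditions)$table

  structure(list(
    band_table = change_stat_table(band_changes, "band"),
    region_table = change_stat_table(region_theta, "region"),
    region_anova = anv$anova,
    region_posthoc = anv$posthoc,
    two_way = do.call(rbind, two_way),
    channel_tests = chan_tests,
    li_table = do.call(rbind, li_rows),
    brums_table = brums_out,
    peaks = peaks
  ), class = "session2_result")
}
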