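# Study orchestration: ingest -> dedup -> standardize -> select -> device-PT
# merge -> events -> contingency (overall / SOC / subgroups / yearly) ->
# statistics -> thresholds -> ranking, with every screening count logged and
# all output surfaces written as CSV.

#' Build a study configuration
#'
#' @param targets character vector of canonical ingredients to analyze.
#' @param windows named list of `c(from, to)` quarter labels per target (a
#'   target absent from the list uses the whole extract). Each drug's
#'   background (`c`/`d` cells) is restricted to the same quarters as its own
#'   extraction window.
#' @param roles role codes selecting a target report; default `"PS"`.
#' @param synonym_dict a [synonym_dict()] or path to one.
#' @param pt_soc_map a [pt_soc_map()] or path to one.
#' @param exclude_from_ranking events removed before top-k ranking; defaults
#'   to the merged device-use PT plus indication/disease terms.
#' @param top_k rows in the ranked PT table (default 10).
#' @param yates Yates-corrected chi-square (default TRUE).
#' @param continuity +0.5 smoothing of zero cells for ROR/PRR (default FALSE).
#' @param bcpnn_method `"approx"` (closed forms) or `"posterior"`.
#' @param priors a [bcpnn_priors()].
#' @param timescan_mode `"per_year"` or `"cumulative"`.
#' @param subgroups case fields for subgroup tables.
#' @param out_dir optional output directory for CSVs.
#' @return object of class `study_config`.
#' @export
study_config <- function(targets,
                         windows = list(),
                         roles = "PS",
                         synonym_dict = default_synonym_dict(),
                         pt_soc_map = NULL,
                         exclude_from_ranking = c("Device use issue",
                                                  "Asthma",
                                                  "Chronic obstructive pulmonary disease",
                                                  "Drug ineffective",
                                                  "Condition aggravated"),
                         top_k = 10,
                         yates = TRUE,
                         continuity = FALSE,
                         bcpnn_method = "approx",
                         priors = bcpnn_priors(),
                         timescan_mode = "per_year",
                         subgroups = c("sex", "age_bin", "country"),
                         out_dir = NULL) {
  if (is.character(synonym_dict)) synonym_dict <- load_synonym_dict(synonym_dict)
  if (is.character(pt_soc_map)) pt_soc_map <- load_pt_soc_map(pt_soc_map)
  for (w in windows) {
    stopifnot(length(w) == 2L, all(grepl("^\\d{4}Q[1-4]$", w)))
    if (w[1] > w[2]) stop("malformed quarter window: ", paste(w, collapse = "-"))
  }
  structure(list(targets = targets, windows = windows, roles = roles,
                 synonym_dict = synonym_dict, pt_soc_map = pt_soc_map,
                 exclude_from_ranking = exclude_from_ranking, top_k = top_k,
                 yates = yates, continuity = continuity,
                 bcpnn_method = bcpnn_method, priors = priors,
                 timescan_mode = timescan_mode, subgroups = subgroups,
                 out_dir = out_dir),
            class = "study_config")
}

#' Quarterly report counts for a target drug
#'
#' @param cases deduplicated case records.
#' @param target_caseids caseids of the drug's reports.
#' @return `data.table(quarter, count, percent)`; `percent` is of the drug's
#'   total reports, half-up to 2 decimals.
#' @export
quarterly_counts <- function(cases, target_caseids) {
  cs <- data.table::as.data.table(cases)[caseid %in% target_caseids]
  out <- cs[!is.na(quarter), .(count = .N), by = quarter]
  data.table::setorder(out, quarter)
  out[, percent := pt_percent(count, sum(count))]
  out[]
}

#' Demographic summary blocks (sex, age, reporter, country, year)
#'
#' Counts and percents of a drug's reports by sex, age bin, reporter
#' occupation, reporting country (top 5 by count, rest pooled as `"Other"`,
#' ties broken lexicographically) and receipt year. Percents are of the
#' drug's total reports, half-up to 2 decimals; each block's counts sum to
#' the total.
#'
#' @param cases deduplicated case records.
#' @param target_caseids caseids to summarize (default: all cases).
#' @return `data.table(block, category, count, percent)`.
#' @export
demographics_table <- function(cases, target_caseids = NULL) {
  cs <- data.table::as.data.table(cases)
  if (!is.null(target_caseids)) cs <- cs[caseid %in% target_caseids]
  total <- nrow(cs)
  blk <- function(block, v) {
    d <- data.table::data.table(category = as.character(v))
    d <- d[, .(count = .N), by = category]
    d[, `:=`(block = block, percent = if (total > 0) pt_percent(count, total) else 0)]
    d
  }
  sex_lab <- c(F = "Female", M = "Male", UNK = "Unknown")
  rep_lab <- c(CN = "Consumer", MD = "Physician", PH = "Pharmacist",
               OT = "Other health-professional", UNK = "Unknown")
  country <- cs$country
  tab <- sort(table(country), decreasing = TRUE)
  top5 <- names(tab)[order(-as.integer(tab), names(tab))][seq_len(min(5L, length(tab)))]
  country[!country %in% top5] <- "Other"
  out <- data.table::rbindlist(list(
    blk("sex", sex_lab[cs$sex]),
    blk("age", cs$age_bin),
    blk("reporter", rep_lab[cs$reporter]),
    blk("country", country),
    blk("year", cs$year)))
  data.table::setcolorder(out, c("block", "category", "count", "percent"))
  data.table::setorder(out, block, -count, category)
  out[]
}

.fwrite_if <- function(dt, dir, name) {
  if (!is.null(dir)) data.table::fwrite(dt, file.path(dir, name))
}

#' Run the full disproportionality study
#'
#' Executes the complete screening and analysis flow on a FAERS-style
#' extract, for each configured target drug: deduplication, drug-name
#' standardization, target-report selection, device-PT merge, event building,
#' 2x2 tabulation at PT and SOC level (overall, per subgroup, per year for
#' ranked PTs), the three disproportionality statistics with thresholds, and
#' IC-ranked top-k selection. Every screening count is recorded; outputs are
#' written as CSVs when `out_dir` is set, with fully specified ordering so
#' identical inputs give byte-identical files.
#'
#' @param config a [study_config()].
#' @param data list with `demo`, `drug`, `reac` tables (e.g. from
#'   [generate_faers()] or [read_faers_extract()]).
#' @param input_dir alternatively, a directory of quarterly files.
#' @return invisibly, a list with `cases`, `screening_flow`, and per-target
#'   lists (`quarterly`, `demographics`, `pt_signals`, `soc_signals`,
#'   `ranked`, `subgroup_signals`, `timescan`, `target_caseids`).
#' @export
run_study <- function(config, data = NULL, input_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(data)) {
    if (is.null(input_dir)) stop("provide data or input_dir")
    data <- read_faers_extract(input_dir)
  }
  if (is.null(config$pt_soc_map)) stop("study_config needs a pt_soc_map")
  dir <- config$out_dir
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(stage_name, drug, count)
    data.table::data.table(stage = stage_name, drug = drug, count = count)
  flow <- list(stage("raw_demo_rows", "all", nrow(data$demo)))

  cases <- deduplicate_cases(data$demo)
  flow <- c(flow, list(stage("deduplicated_cases", "all", nrow(cases))))
  pv_log("deduplicated %d raw rows to %d cases", nrow(data$demo), nrow(cases))

  drug_std <- standardize_drugs(data$drug, config$synonym_dict)
  drug_std <- join_retained(drug_std, cases)
  reac <- merge_device_pts(data$reac)
  events_all <- build_events(reac, cases, config$pt_soc_map)

  # reports naming more than one target (logged, counted for each drug)
  tgt_sets <- lapply(config$targets, function(tg)
    select_target_reports(drug_std, tg, config$roles))
  names(tgt_sets) <- config$targets
  if (length(config$targets) > 1L) {
    ov <- Reduce(intersect, tgt_sets)
    if (length(ov)) pv_log("%d report(s) list more than one target drug", length(ov))
  }

  res <- list()
  for (tg in config$targets) {
    w <- config$windows[[tg]]
    cs <- if (is.null(w)) cases else {
      qs <- quarter_seq(w[1], w[2])
      cases[quarter %in% qs]
    }
    flow <- c(flow, list(stage("window_cases", tg, nrow(cs))))
    tgt <- intersect(tgt_sets[[tg]], cs$caseid)
    flow <- c(flow, list(stage("target_reports", tg, length(tgt))))
    ev <- events_all[caseid %in% cs$caseid]
    n_pairs <- nrow(ev[caseid %in% tgt])
    flow <- c(flow, list(stage("target_ae_pairs", tg, n_pairs)))
    pv_log("%s: %d reports, %d AE pairs", tg, length(tgt), n_pairs)

    sig <- function(level, stratum = NULL) {
      tab <- tabulate_events(ev, cs, tgt, level = level, stratum = stratum)
      st <- signal_table(tab, priors = config$priors, yates = config$yates,
                         continuity = config$continuity,
                         bcpnn_method = config$bcpnn_method)
      data.table::setorderv(st, c("level", "ic", "event"), order = c(1L, -1L, 1L))
      st
    }
    pt_sig <- sig("pt")
    soc_sig <- sig("soc")
    ranked <- rank_by_ic(pt_sig, k = config$top_k,
                         exclude = config$exclude_from_ranking,
                         require_all_three = TRUE)
    sub <- data.table::rbindlist(lapply(config$subgroups, function(f) {
      vals <- unique(cs[[f]])
      vals <- sort(as.character(vals[!is.na(vals)]))
      data.table::rbindlist(lapply(vals, function(vv)
        sig("pt", stratum = setNames(list(vv), f))))
    }))
    scan <- data.table::rbindlist(lapply(ranked$event, function(p) {
      ys <- yearly_series(ev, cs, tgt, p, mode = config$timescan_mode)
      if (nrow(ys) == 0L) return(NULL)
      st <- signal_table(ys, priors = config$priors, yates = config$yates,
                         continuity = config$continuity,
                         bcpnn_method = config$bcpnn_method)
      st
    }), fill = TRUE)

    qc <- quarterly_counts(cs, tgt)
    dem <- demographics_table(cs, tgt)
    res[[tg]] <- list(target_caseids = tgt, quarterly = qc, demographics = dem,
                      pt_signals = pt_sig, soc_signals = soc_sig, ranked = ranked,
                      subgroup_signals = sub, timescan = scan)
  }

  screening <- data.table::rbindlist(flow)
  if (!is.null(dir)) {
    .fwrite_if(screening, dir, "screening_flow.csv")
    for (tg in config$targets) {
      safe <- gsub("[^A-Za-z0-9]+", "_", tg)
      r <- res[[tg]]
      .fwrite_if(r$quarterly, dir, sprintf("quarterly_counts_%s.csv", safe))
      .fwrite_if(r$demographics, dir, sprintf("demographics_%s.csv", safe))
      .fwrite_if(r$pt_signals, dir, sprintf("pt_signals_%s.csv", safe))
      .fwrite_if(r$soc_signals, dir, sprintf("soc_signals_%s.csv", safe))
      .fwrite_if(r$ranked, dir, sprintf("ranked_pt_%s.csv", safe))
      .fwrite_if(r$subgroup_signals, dir, sprintf("subgroup_signals_%s.csv", safe))
      .fwrite_if(r$timescan, dir, sprintf("timescan_%s.csv", safe))
    }
  }
  invisible(c(list(cases = cases, screening_flow = screening), res))
}
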