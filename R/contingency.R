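# 2x2 contingency construction for drug-event pairs. The counting unit
# throughout is the report x event pair (each PT once per report): the
# denominators of a spontaneous-report disproportionality table are "AEs",
# not reports.

.device_pts <- c("device use issue",
                 "wrong technique in product usage process",
                 "product use issue")

#' Merge device-use Preferred Terms
#'
#' Relabels the PTs "Device use issue", "Wrong technique in product usage
#' process" and "Product use issue" (case-insensitive) to the single PT
#' `"Device use issue"`, then re-deduplicates per report so a report listing
#' two of the three yields one event.
#'
#' @param reac_rows a REAC `data.table` with columns `primaryid`, `pt`.
#' @return the relabeled, per-report-unique rows.
#' @export
merge_device_pts <- function(reac_rows) {
  dt <- data.table::as.data.table(reac_rows)
  stopifnot(all(c("primaryid", "pt") %in% names(dt)))
  pt_merged <- trimws(dt$pt)
  pt_merged[tolower(pt_merged) %in% .device_pts] <- "Device use issue"
  dt <- data.table::copy(dt)[, pt := pt_merged]
  dt[!duplicated(dt[, .(primaryid, key = toupper(pt))])]
}

#' Build event records (one row per report-PT pair)
#'
#' Joins reactions to the retained case versions, deduplicates `(caseid, pt)`
#' case-insensitively, and attaches the SOC from the PT map (`"UNMAPPED"` for
#' unknown PTs). Empty PTs are dropped.
#'
#' @param reac_rows a REAC `data.table` (after [merge_device_pts()] if the
#'   device merge is wanted).
#' @param cases output of [deduplicate_cases()].
#' @param map a [pt_soc_map()].
#' @return `data.table` with columns `caseid`, `pt`, `soc`.
#' @export
build_events <- function(reac_rows, cases, map) {
  dt <- join_retained(reac_rows, cases)
  dt <- dt[!is.na(pt) & nzchar(trimws(pt))]
  dt[, pt := trimws(pt)]
  dt <- dt[!duplicated(dt[, .(caseid, key = toupper(pt))])]
  dt[, soc := lookup_soc(map, pt)]
  dt[, .(caseid, pt, soc)]
}

.stratum_label <- function(stratum) {
  if (is.null(stratum) || length(stratum) == 0L) return("overall")
  paste(sprintf("%s=%s", names(stratum), vapply(stratum, paste, "", collapse = "|")),
        collapse = ";")
}

.filter_stratum <- function(cases, stratum) {
  if (is.null(stratum) || length(stratum) == 0L) return(cases)
  bad <- setdiff(names(stratum), names(cases))
  if (length(bad)) stop("unknown stratum field(s): ", paste(bad, collapse = ", "))
  keep <- rep(TRUE, nrow(cases))
  for (f in names(stratum)) {
    v <- cases[[f]]
    if (is.factor(v)) v <- as.character(v)
    keep <- keep & v %in% stratum[[f]]
  }
  cases[keep]
}

#' Tabulate 2x2 contingency tables for every event
#'
#' For each event `e` in the (optionally stratified) extract:
#' `a` = target-report pairs with `e`, `a+b` = all target pairs,
#' `a+c` = all pairs with `e`, `N` = all pairs. At SOC level each report-PT
#' pair contributes to its SOC (a report with two PTs in one SOC contributes
#' two SOC pairs), which keeps the PT-to-SOC sum conservation exact.
#'
#' @param events output of [build_events()].
#' @param cases output of [deduplicate_cases()] (the case universe; supplies
#'   stratum fields).
#' @param target_caseids caseids of the target-drug reports.
#' @param level `"pt"` or `"soc"`.
#' @param stratum optional named list filtering case fields, e.g.
#'   `list(sex = "F")` or `list(age_bin = "66-79", year = 2022)`.
#' @return `data.table` with columns `event`, `level`, `stratum`, `a`, `b`,
#'   `c`, `d`, `N`, one row per event observed in the stratum (empty if the
#'   stratum is empty).
#' @export
tabulate_events <- function(events, cases, target_caseids,
                            level = c("pt", "soc"), stratum = NULL) {
  level <- match.arg(level)
  stopifnot(all(c("caseid", "pt", "soc") %in% names(events)))
  cs <- .filter_stratum(data.table::as.data.table(cases), stratum)
  ev <- data.table::as.data.table(events)[caseid %in% cs$caseid]
  lab <- .stratum_label(stratum)
  empty <- data.table::data.table(event = character(0), level = character(0),
                                  stratum = character(0), a = integer(0), b = integer(0),
                                  c = integer(0), d = integer(0), N = integer(0))
  if (nrow(ev) == 0L) return(empty)
  ev[, event := if (level == "pt") pt else soc]
  ev[, is_target := caseid %in% target_caseids]
  N <- nrow(ev)
  n_target <- sum(ev$is_target)
  out <- ev[, .(a = sum(is_target), ac = .N), by = event]
  out[, `:=`(level = level, stratum = lab,
             b = n_target - a, c = ac - a)]
  out[, d := N - a - b - c]
  out[, `:=`(N = N, ac = NULL)]
  data.table::setcolorder(out, c("event", "level", "stratum", "a", "b", "c", "d", "N"))
  data.table::setorder(out, -a, event)
  out[]
}

#' Per-year (or cumulative) contingency series for one PT
#'
#' Builds one 2x2 table per calendar year in which the target drug has at
#' least one pair with the PT; the series is emitted only when at least two
#' years qualify (a one-year signal cannot show a trend). In cumulative mode
#' the table for year `y` pools all years `<= y`.
#'
#' @inheritParams tabulate_events
#' @param pt the Preferred Term to scan (case-insensitive).
#' @param mode `"per_year"` (default) or `"cumulative"`.
#' @return `data.table` with a `year` column plus the [tabulate_events()]
#'   columns; zero rows if fewer than two years qualify.
#' @export
yearly_series <- function(events, cases, target_caseids, pt,
                          mode = c("per_year", "cumulative")) {
  mode <- match.arg(mode)
  cs <- data.table::as.data.table(cases)
  ev <- data.table::as.data.table(events)
  pt_key <- toupper(trimws(pt))
  tgt_years <- sort(unique(cs[caseid %in% target_caseids][
    ev[toupper(pt) == pt_key], on = "caseid", nomatch = NULL]$year))
  tgt_years <- tgt_years[!is.na(tgt_years)]
  if (length(tgt_years) < 2L) {
    return(data.table::data.table(year = integer(0), event = character(0),
                                  level = character(0), stratum = character(0),
                                  a = integer(0), b = integer(0), c = integer(0),
                                  d = integer(0), N = integer(0)))
  }
  res <- lapply(tgt_years, function(y) {
    yrs <- if (mode == "cumulative") min(cs$year, na.rm = TRUE):y else y
    tab <- tabulate_events(ev, cs, target_caseids, level = "pt",
                           stratum = list(year = yrs))
    row <- tab[toupper(event) == toupper(pt)]
    if (nrow(row)) row[, year := y]
    row
  })
  out <- data.table::rbindlist(res, use.names = TRUE, fill = TRUE)
  out[, stratum := if (mode == "cumulative") sprintf("years<=%d", year) else sprintf("year=%d", year)]
  data.table::setcolorder(out, c("year", "event", "level", "stratum",
                                 "a", "b", "c", "d", "N"))
  out[]
}
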