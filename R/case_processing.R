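# Case-level screening: deduplication by caseid, drug-name standardization,
# target-report selection. Mirrors the screening flow of a spontaneous-report
# disproportionality study.

.age_bin_levels <- c("<18", "18-39", "40-65", "66-79", ">=80", "unknown")

#' Assign age bins
#'
#' Bins used by the demographic table: `[0,18)`, `[18,40)`, `[40,66)`,
#' `[66,80)`, `[80,Inf)`; missing or negative ages go to `"unknown"`.
#' The `40-65`/`66-79` labels follow pharmacovigilance reporting convention;
#' the partition boundaries are 40, 66 and 80 so every age has exactly one
#' bin.
#'
#' @param age_years numeric vector of ages in years (NA allowed).
#' @return factor with levels `<18`, `18-39`, `40-65`, `66-79`, `>=80`,
#'   `unknown`.
#' @examples
#' assign_age_bin(c(17.9, 66, NA))
#' @export
assign_age_bin <- function(age_years) {
  neg <- !is.na(age_years) & age_years < 0
  if (any(neg)) {
    pv_log("assign_age_bin: %d negative age(s) set to unknown", sum(neg))
    age_years[neg] <- NA_real_
  }
  out <- cut(age_years, breaks = c(0, 18, 40, 66, 80, Inf),
             labels = .age_bin_levels[1:5], right = FALSE)
  out <- factor(out, levels = .age_bin_levels)
  out[is.na(out)] <- "unknown"
  out
}

#' Deduplicate cases, keeping the latest report version
#'
#' FAERS re-submits updated case versions under the same `caseid`; only the
#' latest version is analyzed. Among rows sharing a `caseid` the retained row
#' maximizes `(fda_dt, caseversion, primaryid)` lexicographically (missing
#' `fda_dt` sorts lowest; `primaryid` compared as a character string for
#' determinism).
#'
#' @param demo_rows a DEMO `data.table` as returned by [read_faers_table()]
#'   (or the generator), with columns `primaryid`, `caseid`, `caseversion`,
#'   `fda_dt`, `sex`, `age_years`, `reporter`, `country`.
#' @return a `data.table` of case records, one row per `caseid`, with columns
#'   `caseid`, `primaryid`, `caseversion`, `fda_dt`, `year`, `quarter`, `sex`,
#'   `age_years`, `age_bin`, `reporter`, `country`, and attributes `n_input` /
#'   `n_dropped`.
#' @export
deduplicate_cases <- function(demo_rows) {
  dt <- data.table::as.data.table(demo_rows)
  if (!all(c("age_years", "reporter", "country") %in% names(dt)))
    dt <- normalize_demo(dt)
  need <- c("primaryid", "caseid", "caseversion", "fda_dt", "sex",
            "age_years", "reporter", "country")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("demo_rows lack column(s): ", paste(miss, collapse = ", "))
  n_in <- nrow(dt)
  ver <- dt$caseversion
  ver[is.na(ver)] <- -1L
  ord <- order(dt$caseid,
               data.table::fifelse(is.na(dt$fda_dt), as.Date("0001-01-01"), dt$fda_dt),
               ver, as.character(dt$primaryid))
  dt <- dt[ord]
  keep <- !duplicated(dt$caseid, fromLast = TRUE)  # last = max within caseid
  out <- dt[keep, .(caseid, primaryid, caseversion, fda_dt, sex, age_years,
                    reporter, country)]
  out[, `:=`(year = as.integer(format(fda_dt, "%Y")),
             quarter = date_to_quarter(fda_dt),
             age_bin = assign_age_bin(age_years))]
  data.table::setcolorder(out, c("caseid", "primaryid", "caseversion", "fda_dt",
                                 "year", "quarter", "sex", "age_years", "age_bin",
                                 "reporter", "country"))
  data.table::setattr(out, "n_input", n_in)
  data.table::setattr(out, "n_dropped", n_in - nrow(out))
  out[]
}

#' Standardize free-text drug names against a synonym dictionary
#'
#' Each drug mention is labeled with the canonical ingredient of the first
#' dictionary pattern that matches its name (case-insensitive, surrounding
#' whitespace ignored); unmatched names become `"OTHER"`.
#'
#' @param drug_rows a DRUG `data.table` with columns `primaryid`, `drugname`,
#'   `role_cod`.
#' @param dict a [synonym_dict()].
#' @return the input with a `canonical_ingredient` column added.
#' @export
standardize_drugs <- function(drug_rows, dict) {
  stopifnot(inherits(dict, "synonym_dict"), nrow(dict) > 0)
  dt <- data.table::as.data.table(drug_rows)
  nm <- toupper(trimws(dt$drugname))
  ing <- rep(NA_character_, length(nm))
  for (i in seq_len(nrow(dict))) {
    open <- is.na(ing)
    if (!any(open)) break
    p <- dict$pattern[i]
    hit <- if (dict$is_regex[i]) {
      grepl(p, nm[open], ignore.case = TRUE, perl = TRUE)
    } else {
      grepl(toupper(p), nm[open], fixed = TRUE)
    }
    ing[open][hit] <- dict$ingredient[i]
  }
  ing[is.na(ing)] <- "OTHER"
  dt[, canonical_ingredient := ing]
  dt[]
}

#' Select reports mentioning a target ingredient in given roles
#'
#' @param assignments a `data.table` with columns `caseid`,
#'   `canonical_ingredient` and `role_cod` (see [standardize_drugs()]; join
#'   `caseid` from the deduplicated cases first, e.g. via [join_retained()]).
#' @param target canonical ingredient to select.
#' @param roles non-empty subset of `c("PS","SS","C","I")`; default `"PS"`
#'   (primary suspect only).
#' @return sorted character vector of caseids having at least one matching
#'   assignment.
#' @export
select_target_reports <- function(assignments, target, roles = "PS") {
  if (length(roles) == 0L) stop("roles must be non-empty")
  bad <- setdiff(roles, c("PS", "SS", "C", "I"))
  if (length(bad)) stop("unknown role code(s): ", paste(bad, collapse = ", "))
  dt <- data.table::as.data.table(assignments)
  stopifnot(all(c("caseid", "canonical_ingredient", "role_cod") %in% names(dt)))
  sort(unique(as.character(
    dt[canonical_ingredient == target & role_cod %in% roles, caseid])))
}

#' Restrict child-table rows to retained case versions
#'
#' Joins DRUG or REAC rows to the deduplicated cases on `primaryid`, dropping
#' rows that belong to superseded case versions (or to no known case) and
#' attaching `caseid`. The dropped-row count is logged and stored in the
#' `n_dropped` attribute.
#'
#' @param rows a `data.table` with a `primaryid` column.
#' @param cases output of [deduplicate_cases()].
#' @return `rows` restricted to retained primaryids, with `caseid` attached.
#' @export
join_retained <- function(rows, cases) {
  dt <- data.table::as.data.table(rows)
  stopifnot("primaryid" %in% names(dt))
  if ("caseid" %in% names(dt)) dt <- dt[, setdiff(names(dt), "caseid"), with = FALSE]
  idx <- cases[, .(primaryid, caseid)]
  out <- idx[dt, on = "primaryid", nomatch = NULL]
  dropped <- nrow(dt) - nrow(out)
  if (dropped > 0) pv_log("join_retained: dropped %d row(s) from superseded/unknown versions", dropped)
  data.table::setattr(out, "n_dropped", dropped)
  out[]
}
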