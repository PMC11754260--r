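# FAERS quarterly ASCII dialect: "$"-delimited, header line, no quoting.
# Parsing is header-driven (column order never matters); unparseable field
# values become NA and are tallied, never fatal.

.faers_schemas <- list(
  DEMO = c("primaryid", "caseid", "caseversion", "fda_dt", "sex",
           "age", "age_cod", "occp_cod", "occr_country"),
  DRUG = c("primaryid", "drugname", "role_cod"),
  REAC = c("primaryid", "pt")
)

#' Column names of a FAERS table schema
#'
#' @param schema one of `"DEMO"`, `"DRUG"`, `"REAC"`.
#' @return character vector of required column names.
#' @export
faers_schema <- function(schema = c("DEMO", "DRUG", "REAC")) {
  .faers_schemas[[match.arg(schema)]]
}

# UTF-8 with per-file latin-1 fallback (real dumps mix encodings)
.read_lines_fallback <- function(path) {
  x <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (any(!validEnc(x))) x <- iconv(readLines(path, warn = FALSE), from = "latin1", to = "UTF-8")
  x
}

.age_factor <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52, DY = 1 / 365.25)

#' Read one FAERS-dialect ASCII table
#'
#' Reads a `$`-delimited table with a header line and returns the columns the
#' schema requires, located by header name so column order is irrelevant.
#' Values that fail to parse (dates, ages, versions) become `NA` and are
#' counted in the `missing_tally` attribute rather than aborting the read.
#'
#' For `DEMO`, derived columns are added at read time: `fda_dt` parsed to
#' `Date` (8-digit `YYYYMMDD` required), `age_years` converted from the
#' `age`/`age_cod` pair (DEC x10, YR x1, MON /12, WK /52, DY /365.25; unknown
#' code or missing age gives `NA`), `sex` normalized to `F`/`M`/`UNK`,
#' `reporter` from `occp_cod` (`CN`, `MD`, `PH`, `OT`; blank `UNK`, any other
#' non-blank code `OT`), and `country` from `occr_country` (blank
#' `"Unknown"`).
#'
#' @param path file path.
#' @param schema one of `"DEMO"`, `"DRUG"`, `"REAC"`.
#' @return a `data.table` with attributes `n_rows` (data lines parsed) and
#'   `missing_tally` (named integer vector of NA counts per parsed field).
#' @export
read_faers_table <- function(path, schema = c("DEMO", "DRUG", "REAC")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- .read_lines_fallback(path)
  if (length(lines) == 0L) stop("empty file (no header line): ", path)
  header <- tolower(trimws(strsplit(lines[[1L]], "$", fixed = TRUE)[[1L]]))
  need <- .faers_schemas[[schema]]
  miss <- setdiff(need, header)
  if (length(miss)) stop(sprintf("%s header lacks required column(s): %s",
                                 schema, paste(miss, collapse = ", ")))
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) {
    dt <- data.table::setDT(lapply(need, function(x) character(0)))
    data.table::setnames(dt, need)
  } else {
    parts <- data.table::tstrsplit(body, "$", fixed = TRUE)
    # short rows: pad missing trailing fields
    if (length(parts) < length(header)) {
      parts <- c(parts, rep(list(rep(NA_character_, length(body))),
                            length(header) - length(parts)))
    }
    dt <- data.table::setDT(parts[seq_along(header)])
    data.table::setnames(dt, header)
    dt <- dt[, need, with = FALSE]
    for (j in need) data.table::set(dt, j = j, value = trimws(dt[[j]]))
  }
  tally <- integer(0)
  if (schema == "DEMO") {
    dt <- normalize_demo(dt)
    tally <- attr(dt, "missing_tally")
  } else if (schema == "REAC") {
    tally["pt"] <- sum(is.na(dt$pt) | dt$pt == "")
  } else {
    tally["drugname"] <- sum(is.na(dt$drugname) | dt$drugname == "")
    role <- toupper(dt$role_cod)
    role[!role %in% c("PS", "SS", "C", "I")] <- NA_character_
    tally["role_cod"] <- sum(is.na(role))
    dt[, role_cod := role]
  }
  data.table::setattr(dt, "n_rows", length(body))
  data.table::setattr(dt, "missing_tally", tally)
  dt[]
}

#' Normalize a raw DEMO table
#'
#' Derives the analysis columns from the raw DEMO fields: `fda_dt` parsed to
#' `Date` (8-digit `YYYYMMDD`; anything else is missing), `caseversion` to
#' integer, `age_years` from `age`/`age_cod` (DEC x10, YR x1, MON /12,
#' WK /52, DY /365.25), `sex` to `F`/`M`/`UNK`, `reporter` from `occp_cod`
#' (blank gives `UNK`, unrecognized non-blank codes `OT`) and `country` from
#' `occr_country` (blank gives `"Unknown"`). Called by [read_faers_table()]
#' and, when the derived columns are absent, by [deduplicate_cases()], so
#' in-memory extracts from the generator need no file round trip.
#'
#' @param dt a `data.table` with the raw DEMO schema columns.
#' @return the table with derived columns, plus a `missing_tally` attribute.
#' @export
normalize_demo <- function(dt) {
  dt <- data.table::as.data.table(dt)
  tally <- integer(0)
  if (!inherits(dt$fda_dt, "Date")) {
    raw_dt <- as.character(dt$fda_dt)
    ok <- !is.na(raw_dt) & grepl("^\\d{8}$", raw_dt)
    fda <- as.Date(rep(NA_character_, nrow(dt)))
    if (any(ok)) fda[ok] <- as.Date(raw_dt[ok], format = "%Y%m%d")
    dt[, fda_dt := fda]
  }
  tally["fda_dt"] <- sum(is.na(dt$fda_dt))
  ver <- suppressWarnings(as.integer(dt$caseversion))
  tally["caseversion"] <- sum(is.na(ver))
  age_num <- suppressWarnings(as.numeric(dt$age))
  age_years <- age_num * unname(.age_factor[toupper(as.character(dt$age_cod))])
  tally["age"] <- sum(is.na(age_years))
  sex_norm <- toupper(as.character(dt$sex))
  sex_norm[!sex_norm %in% c("F", "M")] <- "UNK"
  occ <- toupper(as.character(dt$occp_cod))
  reporter <- ifelse(occ %in% c("CN", "MD", "PH", "OT"), occ,
                     ifelse(is.na(occ) | occ == "", "UNK", "OT"))
  country <- as.character(dt$occr_country)
  country[is.na(country) | country == ""] <- "Unknown"
  # note: `:=` right-hand sides see columns first, so normalized vectors must
  # not share a column's name (sex_norm, ver)
  dt[, `:=`(caseversion = ver, age_years = age_years, sex = sex_norm,
            reporter = reporter, country = country)]
  data.table::setattr(dt, "missing_tally", tally)
  dt[]
}

#' Write a FAERS-dialect ASCII table
#'
#' Writes the schema columns `$`-delimited with a header line. The dialect has
#' no quoting, so any embedded `$` in a character field is replaced by a space
#' (logged). `NA` is written as the empty field. Dates are written `YYYYMMDD`.
#'
#' @param rows a data.frame/data.table containing at least the schema columns.
#' @param path output file path.
#' @param schema one of `"DEMO"`, `"DRUG"`, `"REAC"`.
#' @return `path`, invisibly.
#' @export
write_faers_table <- function(rows, path, schema = c("DEMO", "DRUG", "REAC")) {
  schema <- match.arg(schema)
  need <- .faers_schemas[[schema]]
  rows <- data.table::as.data.table(rows)
  miss <- setdiff(need, names(rows))
  if (length(miss)) stop("rows lack schema column(s): ", paste(miss, collapse = ", "))
  out <- rows[, need, with = FALSE]
  n_san <- 0L
  cols <- lapply(out, function(v) {
    if (inherits(v, "Date")) v <- format(v, "%Y%m%d")
    v <- as.character(v)
    bad <- grepl("$", v, fixed = TRUE)
    n_san <<- n_san + sum(bad, na.rm = TRUE)
    v[bad & !is.na(v)] <- gsub("$", " ", v[bad & !is.na(v)], fixed = TRUE)
    v[is.na(v)] <- ""
    v
  })
  if (n_san > 0L) pv_log("write_faers_table: sanitized %d embedded delimiter(s) in %s", n_san, basename(path))
  lines <- c(paste(need, collapse = "$"),
             do.call(paste, c(cols, sep = "$")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Load a PT to SOC mapping table
#'
#' Two-column delimited text (tab, comma, or `$`; auto-detected from the
#' header line) with a header row: PT then SOC. Lookup is case-insensitive on
#' PT. Duplicate PT rows are allowed only if they agree on the SOC;
#' conflicting duplicates are an error naming the PTs.
#'
#' @param path file path.
#' @return an object of class `pt_soc_map`.
#' @export
load_pt_soc_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- .read_lines_fallback(path)
  sep <- .detect_sep(lines[[1L]])
  dt <- data.table::setDT(data.table::tstrsplit(lines[-1L], sep, fixed = TRUE)[1:2])
  data.table::setnames(dt, c("pt", "soc"))
  dt <- dt[!is.na(pt) & nzchar(trimws(pt))]
  pt_soc_map(trimws(dt$pt), trimws(dt$soc))
}

.detect_sep <- function(header) {
  for (s in c("\t", "$", ",")) if (grepl(s, header, fixed = TRUE)) return(s)
  stop("cannot detect delimiter in header: ", header)
}

#' Construct a PT to SOC map from vectors
#'
#' @param pt character vector of Preferred Terms.
#' @param soc character vector of System Organ Classes, same length.
#' @return an object of class `pt_soc_map`; lookups of unmapped PTs yield the
#'   sentinel `"UNMAPPED"`.
#' @export
pt_soc_map <- function(pt, soc) {
  stopifnot(length(pt) == length(soc))
  key <- toupper(trimws(pt))
  soc <- trimws(soc)
  n_soc <- tapply(soc, key, function(s) length(unique(s)))
  conflicts <- names(n_soc)[n_soc > 1L]
  if (length(conflicts))
    stop("conflicting SOC for PT(s): ", paste(conflicts, collapse = ", "))
  keep <- !duplicated(key)
  structure(list(map = setNames(soc[keep], key[keep])), class = "pt_soc_map")
}

#' Look up SOCs for PTs
#'
#' @param map a `pt_soc_map`.
#' @param pt character vector of PTs (case-insensitive).
#' @return character vector of SOCs, `"UNMAPPED"` where the PT is unknown.
#' @export
lookup_soc <- function(map, pt) {
  stopifnot(inherits(map, "pt_soc_map"))
  out <- unname(map$map[toupper(trimws(pt))])
  out[is.na(out)] <- "UNMAPPED"
  out
}

#' @export
print.pt_soc_map <- function(x, ...) {
  cat(sprintf("<pt_soc_map: %d PTs, %d SOCs>\n",
              length(x$map), length(unique(x$map))))
  invisible(x)
}

#' Load a drug-name synonym dictionary
#'
#' Two-column delimited text with header: `pattern`, `ingredient`. A pattern
#' is matched case-insensitively against the verbatim drug name; it is treated
#' as a regular expression when it starts with `^` or ends with `$`, and as a
#' plain substring otherwise. Patterns are tried in declaration order and the
#' first match wins.
#'
#' @param path file path.
#' @return an object of class `synonym_dict`.
#' @export
load_synonym_dict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- .read_lines_fallback(path)
  sep <- .detect_sep(lines[[1L]])
  dt <- data.table::setDT(data.table::tstrsplit(lines[-1L], sep, fixed = TRUE)[1:2])
  data.table::setnames(dt, c("pattern", "ingredient"))
  synonym_dict(trimws(dt$pattern), trimws(dt$ingredient))
}

#' Construct a synonym dictionary from vectors
#'
#' @param pattern character vector of substring or anchored-regex patterns.
#' @param ingredient canonical ingredient each pattern maps to.
#' @return an object of class `synonym_dict`.
#' @export
synonym_dict <- function(pattern, ingredient) {
  stopifnot(length(pattern) == length(ingredient), length(pattern) > 0)
  if (any(!nzchar(pattern))) stop("empty pattern in synonym dictionary")
  structure(
    data.table::data.table(pattern = pattern, ingredient = ingredient,
                           is_regex = startsWith(pattern, "^") | endsWith(pattern, "$")),
    class = c("synonym_dict", "data.table", "data.frame"))
}
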