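# Shared fixtures, built in code. The default synthetic world is generated
# once per test run and memoised; hand-built micro-fixtures are constructed
# inline where a test needs exact, enumerable counts.

.fx <- new.env(parent = emptyenv())

# memoised default synthetic extract (n = 5000 keeps the whole suite fast;
# statistical acceptance tests build their own larger worlds)
default_fixture <- function(n = 5000, seed = 42) {
  key <- sprintf("fx_%d_%d", n, seed)
  if (is.null(.fx[[key]])) {
    cfg <- synthetic_config(n_cases = n, seed = seed)
    .fx[[key]] <- generate_faers(cfg)
  }
  .fx[[key]]
}

fixture_map <- function(cfg = NULL) {
  v <- if (is.null(cfg)) default_pt_vocabulary() else cfg$pt_vocabulary
  pt_soc_map(v$pt, v$soc)
}

# minimal DEMO rows builder (raw file-dialect fields)
demo_rows <- function(primaryid, caseid, caseversion, fda_dt,
                      sex = "F", age = "60", age_cod = "YR",
                      occp_cod = "MD", occr_country = "US") {
  data.table::data.table(primaryid = as.character(primaryid),
                         caseid = as.character(caseid),
                         caseversion = as.integer(caseversion),
                         fda_dt = fda_dt, sex = sex, age = age,
                         age_cod = age_cod, occp_cod = occp_cod,
                         occr_country = occr_country)
}

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

# exact inclusion probabilities for sequential weighted sampling without
# replacement of K items, by enumeration of ordered draws -- the independent
# oracle for expected_table (feasible only for small vocabularies)
incl_exact_K <- function(w, K) {
  m <- length(w)
  probs <- numeric(m)
  rec <- function(remaining, chosen, p) {
    if (length(chosen) == K) {
      probs[chosen] <<- probs[chosen] + p
      return(invisible())
    }
    for (i in remaining) {
      rec(setdiff(remaining, i), c(chosen, i), p * w[i] / sum(w[remaining]))
    }
  }
  rec(seq_len(m), integer(0), 1)
  probs
}

incl_exact <- function(w, lambda, kmax) {
  pk <- dpois(seq_len(kmax), lambda)
  pk <- pk / sum(pk)
  rowSums(vapply(seq_len(kmax), function(K) incl_exact_K(w, K) * pk[K],
                 numeric(length(w))))
}
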