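# Small in-code fixtures shared across test files.

# two-type toy registry: D1/D2 are HADs, anything else is not
toy_registry <- function() {
  reg <- tibble::tibble(
    drug_code = c("D1", "D2"),
    drug_name = c("Digoxin", "Morphine"),
    had_group = c("general", "narcotic_psychotropic"),
    had_type = c("CVS", "CNS")
  )
  class(reg) <- c("had_registry", class(reg))
  reg
}

# build a visit tibble directly from per-visit code/drug lists
toy_visits <- function(icd10, drugs, gender = NULL, age = NULL) {
  n <- length(icd10)
  tibble::tibble(
    txn = sprintf("T%03d", seq_len(n)),
    gender = if (is.null(gender)) rep("female", n) else gender,
    age = if (is.null(age)) rep(50L, n) else age,
    icd10 = icd10,
    drugs = drugs,
    total_drugs = lengths(drugs),
    no_icd10 = lengths(icd10) == 0
  )
}

# visits with a single ICD10 code each and Bernoulli(p) HAD use, for
# prevalence-estimator checks
bernoulli_visits <- function(n, code, p, seed) {
  withr::with_seed(seed, {
    had <- stats::runif(n) < p
    toy_visits(
      icd10 = rep(list(code), n),
      drugs = lapply(had, function(h) if (h) c("D1", "N1") else "N1")
    )
  })
}
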