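# Seeded synthetic prescription-data generator.
#
# Emulates the statistical structure the screening protocol exploits: each
# diagnosis code carries an association probability pi (the chance a visit
# with that principal diagnosis receives a high-alert drug), visits mix in
# comorbidities and non-HAD co-prescriptions, and errors can be planted with
# ground truth — unrelated HAD prescriptions (mismatches), follow-up visits
# of high-association diagnoses issued without HAD (stage mixing), and
# heavy multi-drug accumulation.

#' Build a generator configuration
#'
#' All probabilities are fractions in `[0, 1]`. The association profile
#' assigns each synthetic ICD10 code its probability `pi` of HAD use when it
#' is the visit's principal diagnosis: `"spectrum"` spreads `pi` evenly over
#' `[0, 0.98]`; `"separated"` draws a high group (`prop_high` of codes) from
#' `high_range` and the rest from `low_range`, the well-separated setting in
#' which planted errors are detectable.
#'
#' @param n_visits Number of visits to generate.
#' @param setting `"OPD"` or `"IPD"` (a tag carried through to reports).
#' @param n_icd10 Number of distinct synthetic ICD10 codes.
#' @param zipf_exponent Power-law exponent of the code frequency
#'   distribution (visit counts per code follow rank^-exponent).
#' @param pi_profile `"spectrum"` or `"separated"`; ignored when `pi` is
#'   given.
#' @param pi Optional explicit association map: a numeric vector of
#'   probabilities, one per ICD10 code (recycled names `ICD_001`, ...;
#'   overrides `n_icd10` when named or when its length differs).
#' @param prop_high,high_range,low_range Parameters of the `"separated"`
#'   profile.
#' @param comorbidity_mean Poisson mean of per-visit extra ICD10 codes.
#' @param nonhad_drug_mean Poisson mean of per-visit non-HAD prescriptions
#'   (every visit receives at least one drug).
#' @param mismatch_rate Probability that an eligible visit (non-HAD
#'   indicated, all its codes below `unrelated_bound`) receives a random
#'   high-alert drug — a planted prescription error.
#' @param stage_mixing Probability that a high-association
#'   (`pi >= 0.5`) visit is a follow-up issued without HAD, emulating
#'   multi-stage treatment.
#' @param unrelated_bound Codes with `pi` below this bound count as
#'   unrelated to HAD use (default 0.1); planted mismatches only occur on
#'   visits all of whose codes are unrelated.
#' @param use_real_names Use the packaged drug registry instead of synthetic
#'   drug tokens, for readable demos.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A validated list of class `had_generator_config`.
#' @export
generator_config <- function(n_visits = 5000,
                             setting = c("OPD", "IPD"),
                             n_icd10 = 60,
                             zipf_exponent = 1.1,
                             pi_profile = c("spectrum", "separated"),
                             pi = NULL,
                             prop_high = 0.3,
                             high_range = c(0.8, 0.98),
                             low_range = c(0, 0.1),
                             comorbidity_mean = 0.8,
                             nonhad_drug_mean = 2,
                             mismatch_rate = 0,
                             stage_mixing = 0,
                             unrelated_bound = 0.1,
                             use_real_names = FALSE,
                             seed = 1) {
  config <- list(
    n_visits = as.integer(n_visits), setting = match.arg(setting),
    n_icd10 = if (is.null(pi)) as.integer(n_icd10) else length(pi),
    zipf_exponent = zipf_exponent,
    pi_profile = match.arg(pi_profile), pi = pi, prop_high = prop_high,
    high_range = high_range, low_range = low_range,
    comorbidity_mean = comorbidity_mean, nonhad_drug_mean = nonhad_drug_mean,
    mismatch_rate = mismatch_rate, stage_mixing = stage_mixing,
    unrelated_bound = unrelated_bound, use_real_names = use_real_names,
    seed = as.integer(seed)
  )
  validate_generator_config(config)
  structure(config, class = "had_generator_config")
}

validate_generator_config <- function(config) {
  check_prob <- function(name) {
    v <- config[[name]]
    if (any(v < 0 | v > 1)) abort(sprintf("`%s` must lie in [0, 1].", name))
  }
  if (config$n_visits < 1) abort("`n_visits` must be at least 1.")
  if (config$n_icd10 < 2) abort("`n_icd10` must be at least 2.")
  if (!is.null(config$pi)) check_prob("pi")
  for (f in c("prop_high", "high_range", "low_range", "mismatch_rate",
              "stage_mixing", "unrelated_bound")) check_prob(f)
  if (config$comorbidity_mean < 0) abort("`comorbidity_mean` must be >= 0.")
  if (config$nonhad_drug_mean < 0) abort("`nonhad_drug_mean` must be >= 0.")
  invisible(config)
}

#' Named generator scenario presets
#'
#' * `"clean"` — the calibration scenario: no planted errors, no stage
#'   mixing, no comorbidities, association spectrum spanning 0–0.98; the
#'   per-ICD10 prevalence estimator recovers `pi` within binomial error.
#' * `"mismatch_rich"` — separated associations (high group at 0.8–0.98,
#'   low group at 0–0.1) with a 1% planted-mismatch rate: the end-to-end
#'   screening benchmark.
#' * `"eacip"` — 30% of high-association visits are follow-ups issued
#'   without HAD, with heavier comorbidity mixing (complex diagnosis
#'   relationships).
#' * `"eamu"` — heavy non-HAD co-prescription (4 or more drug types are
#'   common), the multi-drug accumulation scenario.
#'
#' @param name Preset name.
#' @param ... Overrides passed to [generator_config()] (e.g. `n_visits`,
#'   `seed`).
#' @return A `had_generator_config`.
#' @export
#' @examples
#' scenario_preset("clean", n_visits = 100)$mismatch_rate
scenario_preset <- function(name, ...) {
  presets <- list(
    clean = list(pi_profile = "spectrum", mismatch_rate = 0,
                 stage_mixing = 0, comorbidity_mean = 0, n_visits = 20000L),
    mismatch_rich = list(pi_profile = "separated", mismatch_rate = 0.01,
                         stage_mixing = 0, comorbidity_mean = 0.8,
                         n_visits = 20000L),
    eacip = list(pi_profile = "spectrum", stage_mixing = 0.3,
                 comorbidity_mean = 1.5, mismatch_rate = 0),
    eamu = list(pi_profile = "spectrum", nonhad_drug_mean = 4.5,
                comorbidity_mean = 0.8, mismatch_rate = 0)
  )
  if (!name %in% names(presets)) {
    abort(sprintf("Unknown preset '%s'; available: %s.", name,
                  paste(names(presets), collapse = ", ")))
  }
  args <- modifyList(presets[[name]], list(...))
  do.call(generator_config, args)
}

#' @rdname scenario_preset
#' @export
scenario_presets <- function() c("clean", "mismatch_rich", "eacip", "eamu")

# internal: synthetic drug registry, 4 drugs per HAD type
synthetic_registry <- function() {
  group_of <- c(ANS = "general", BIG = "general", CVS = "general",
                CNS = "narcotic_psychotropic", END = "general",
                Tumor = "iv_cytotoxic")
  reg <- purrr::map(had_types(), function(tt) {
    tibble::tibble(
      drug_code = sprintf("HAD_%s_%02d", toupper(tt), 1:4),
      drug_name = sprintf("%s drug %d", tt, 1:4),
      had_group = group_of[[tt]],
      had_type = tt
    )
  }) |> purrr::list_rbind()
  class(reg) <- c("had_registry", class(reg))
  reg
}

#' Generate a synthetic prescription dataset
#'
#' Draws visits under the configured association structure and returns the
#' prescription table (the exact dialect [read_prescriptions()] reads), the
#' drug registry in force, and per-visit ground truth including every
#' planted error.
#'
#' Each visit has a principal diagnosis drawn from a power-law code
#' distribution; HAD use is Bernoulli in the principal code's association
#' probability `pi`; prescribed HAD drugs follow the principal code's type
#' mixture (one dominant pharmacological type per code); non-HAD drugs and
#' comorbid codes are added per the configured means; prescription rows
#' recycle the visit's codes, principal first, so a visit with fewer
#' prescriptions than diagnoses drops surplus comorbidities from both the
#' emitted rows and the ground truth.
#'
#' @param config A `had_generator_config` (see [generator_config()],
#'   [scenario_preset()]).
#' @return A list of class `had_simulation`: `prescriptions` (tibble),
#'   `registry` (`had_registry`), `ground_truth` (tibble with `txn`,
#'   `principal_icd10`, `pi_principal`, `intended_had`, `intended_types`
#'   list-column, `follow_up`, `planted_mismatch`, `planted_drug`, `icd10`
#'   list-column), `pi` (named per-code association vector) and `config`.
#' @export
simulate_prescriptions <- function(config) {
  stopifnot(inherits(config, "had_generator_config"))
  validate_generator_config(config)
  registry <- if (config$use_real_names) default_registry() else synthetic_registry()
  nonhad_codes <- sprintf("NH_%03d", 1:30)
  withr::with_seed(config$seed, {
    n <- config$n_visits
    codes <- sprintf("ICD_%03d", seq_len(config$n_icd10))
    pi <- if (!is.null(config$pi)) {
      unname(config$pi)
    } else switch(config$pi_profile,
      spectrum = sample(seq(0, 0.98, length.out = config$n_icd10)),
      separated = {
        n_high <- max(1L, round(config$prop_high * config$n_icd10))
        v <- c(runif(n_high, config$high_range[1], config$high_range[2]),
               runif(config$n_icd10 - n_high, config$low_range[1],
                     config$low_range[2]))
        sample(v)
      })
    names(pi) <- codes
    # one dominant pharmacological type per code, mixture weight 0.8
    dominant_type <- sample(had_types(), config$n_icd10, replace = TRUE)
    freq <- seq_len(config$n_icd10)^(-config$zipf_exponent)

    principal <- sample(codes, n, replace = TRUE, prob = freq)
    n_com <- rpois(n, config$comorbidity_mean)
    comorbid <- purrr::map2(principal, n_com, function(p, k) {
      if (k == 0) character() else
        unique(sample(setdiff(codes, p), min(k, config$n_icd10 - 1L)))
    })
    pi_principal <- pi[principal]
    intended_had <- runif(n) < pi_principal
    follow_up <- intended_had & pi_principal >= 0.5 &
      runif(n) < config$stage_mixing
    intended_had[follow_up] <- FALSE

    # HAD drugs for intended-HAD visits: 1 or occasionally 2 distinct types
    # drawn from the principal code's type mixture
    drugs_by_type <- split(registry$drug_code, registry$had_type)
    type_mix <- function(code) {
      w <- rep(0.2 / 5, 6)
      w[match(dominant_type[match(code, codes)], had_types())] <- 0.8
      w
    }
    n_types <- 1L + rbinom(n, 1L, 0.15)
    had_drugs <- purrr::pmap(list(principal, intended_had, n_types),
      function(p, ih, k) {
        if (!ih) return(character())
        tts <- sample(had_types(), k, replace = FALSE, prob = type_mix(p))
        vapply(tts, function(tt) sample(drugs_by_type[[tt]], 1), character(1),
               USE.NAMES = FALSE)
      })
    intended_types <- purrr::map(had_drugs, function(d) {
      tt <- unique(had_type_of(d, registry)); tt[!is.na(tt)]
    })

    n_nonhad <- rpois(n, config$nonhad_drug_mean) + as.integer(!intended_had)
    nonhad_drugs <- purrr::map(n_nonhad, function(k) {
      if (k == 0) character() else sample(nonhad_codes, k, replace = TRUE)
    })

    # planted mismatches: an unrelated HAD on a visit with no supporting code
    all_low <- purrr::map2_lgl(principal, comorbid, function(p, cm) {
      all(pi[c(p, cm)] < config$unrelated_bound)
    })
    eligible <- !intended_had & all_low
    planted <- eligible & runif(n) < config$mismatch_rate
    planted_drug <- ifelse(planted,
                           sample(registry$drug_code, n, replace = TRUE),
                           NA_character_)

    gender <- sample(c("male", "female"), n, replace = TRUE,
                     prob = c(0.45, 0.55))
    age <- pmin(pmax(round(rnorm(n, 48, 15)), 0L), 100L)
    txn <- sprintf("V%06d", seq_len(n))

    rows <- purrr::pmap(
      list(txn, gender, age, principal, comorbid, had_drugs, nonhad_drugs,
           planted_drug),
      function(tx, g, a, p, cm, hd, nh, pd) {
        drugs <- c(hd, if (!is.na(pd)) pd, nh)
        if (length(drugs) == 0) drugs <- sample(nonhad_codes, 1)
        icd <- rep(c(p, cm), length.out = length(drugs))
        tibble::tibble(txn = tx, gender = g, age = a, icd10 = icd,
                       drug_code = drugs)
      })
    prescriptions <- purrr::list_rbind(rows) |>
      dplyr::mutate(drug_name = dplyr::coalesce(
        registry$drug_name[match(.data$drug_code, registry$drug_code)],
        .data$drug_code))
    kept_icd10 <- prescriptions |>
      dplyr::group_by(.data$txn) |>
      dplyr::summarise(icd10 = list(unique(.data$icd10)), .groups = "drop")
    ground_truth <- tibble::tibble(
      txn = txn, principal_icd10 = principal,
      pi_principal = unname(pi_principal),
      intended_had = intended_had, intended_types = intended_types,
      follow_up = follow_up, planted_mismatch = planted,
      planted_drug = planted_drug
    ) |>
      dplyr::left_join(kept_icd10, by = "txn")
    structure(
      list(prescriptions = prescriptions, registry = registry,
           ground_truth = ground_truth, pi = pi, config = config),
      class = "had_simulation"
    )
  })
}

#' @export
print.had_simulation <- function(x, ...) {
  cat(sprintf(
    "<had_simulation> %d visits, %d prescriptions, %d planted mismatch(es) [%s, seed %d]\n",
    nrow(x$ground_truth), nrow(x$prescriptions),
    sum(x$ground_truth$planted_mismatch), x$config$setting, x$config$seed))
  invisible(x)
}

#' Write a simulation to disk
#'
#' Emits the prescription CSV in the dialect [read_prescriptions()] reads,
#' the registry CSV, and the ground truth as a JSON side-car.
#'
#' @param sim A `had_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_prescriptions(sim$prescriptions, file.path(dir, "prescriptions.csv"))
  readr::write_csv(tibble::as_tibble(sim$registry),
                   file.path(dir, "registry.csv"))
  gt <- sim$ground_truth
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = FALSE, digits = NA, na = "null")
  invisible(dir)
}
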