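#' Run the end-to-end sCT comparison experiment on a phantom cohort
#'
#' For every case and every requested method this generates an sCT,
#' computes HU mean error / mean absolute error (whole body, bone, soft
#' tissue), recalculates the plan dose on CT and sCT with a frozen
#' normalization (identical "monitor units"), and evaluates the ICRU-point
#' and DVH percentage dose differences plus 3D gamma at the three standard
#' criteria (3%/2 mm, 2%/2 mm, 1%/1 mm). Atlas and cGAN methods use
#' leave-one-out within the cohort. Fully deterministic given the cohort
#' and config.
#'
#' @param cohort list of `phantom_case` objects (e.g. from
#'   [generate_cohort()]).
#' @param methods subset of `"bulk"`, `"tissue_class"`, `"atlas"`,
#'   `"cgan"`, `"identity"` (`"identity"` copies the CT: the pipeline null).
#' @param beams a [beam_config()] (isocenter defaults per case to its
#'   reference point).
#' @param cal a [density_calibration()].
#' @param gamma_criteria_list list of [gamma_criteria()] evaluated per sCT.
#' @param override_gas apply [override_bowel_gas()] to CT and sCT before
#'   dose calculation.
#' @param cgan_cfg a [cgan_config()] for the `"cgan"` method.
#' @param lwv a [lwv_params()] for the `"atlas"` method.
#' @param out_dir optional directory: writes `metrics.csv`, `summary.csv`
#'   and `manifest.json`.
#' @return List: `metrics` (long per-case data.frame), `summary`
#'   (cohort summary via [summarize_cohort()]), `manifest`.
#' @export
run_experiment <- function(cohort,
                           methods = c("bulk", "tissue_class"),
                           beams = beam_config(),
                           cal = density_calibration(),
                           gamma_criteria_list = standard_gamma_ladder(),
                           override_gas = TRUE,
                           cgan_cfg = cgan_config(),
                           lwv = lwv_params(),
                           out_dir = NULL) {
  methods <- match.arg(methods, c("bulk", "tissue_class", "atlas", "cgan",
                                  "identity"), several.ok = TRUE)
  rows <- list()
  failures <- character(0)
  cgan_models <- if ("cgan" %in% methods)
    train_cgan_loo(cohort, cgan_cfg) else NULL
  for (ci in seq_along(cohort)) {
    case <- cohort[[ci]]
    group <- case$spec$sex_variant %||% "all"
    ct_ref <- prepare_reference_ct(case, override_gas)
    dose_ct <- case_dose(ct_ref, case, beams, cal, scale = NULL)
    for (method in methods) {
      res <- tryCatch(
        evaluate_method(case, ci, cohort, method, ct_ref, dose_ct, beams,
                        cal, gamma_criteria_list, override_gas,
                        cgan_models, lwv),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures <- c(failures,
                      sprintf("case %d method %s: %s", ci, method,
                              conditionMessage(res)))
        next
      }
      res$case <- ci
      res$group <- group
      res$method <- method
      rows[[length(rows) + 1]] <- res
    }
  }
  metrics <- do.call(rbind, rows)
  summary <- summarize_cohort(metrics, "all")
  manifest <- list(n_cases = length(cohort), methods = methods,
                   seeds = vapply(cohort, function(c) c$seed, integer(1)),
                   beams = unclass(beams),
                   gamma = lapply(gamma_criteria_list, unclass),
                   override_gas = override_gas, failures = failures)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(metrics, file.path(out_dir, "metrics.csv"),
              row.names = FALSE)
    write.csv(summary, file.path(out_dir, "summary.csv"),
              row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  if (length(failures) > 0)
    warning(sprintf("%d case/method run(s) failed; see manifest$failures",
                    length(failures)))
  list(metrics = metrics, summary = summary, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The three standard gamma criteria (3%/2 mm, 2%/2 mm, 1%/1 mm)
#' @param ... overrides passed to every [gamma_criteria()] call.
#' @return List of three `gamma_criteria`.
#' @export
standard_gamma_ladder <- function(...) {
  list(gamma_criteria(dose_diff_pct = 3, dta_mm = 2, ...),
       gamma_criteria(dose_diff_pct = 2, dta_mm = 2, ...),
       gamma_criteria(dose_diff_pct = 1, dta_mm = 1, ...))
}

prepare_reference_ct <- function(case, override_gas) {
  ct <- case$ct
  if (override_gas) ct <- override_bowel_gas(ct, case$masks$body)
  ct
}

case_dose <- function(ct_hu, case, beams, cal, scale = NULL) {
  if (is.null(beams$isocenter)) beams$isocenter <- case$reference_point
  red <- hu_to_red(ct_hu, cal)
  calculate_dose(red, case$masks$body, beams, case$masks$ptv, scale = scale)
}

generate_method_sct <- function(case, ci, cohort, method, cgan_models,
                                cal, lwv) {
  masks <- case$masks
  switch(method,
    identity = case$ct,
    bulk = {
      body <- segment_body(case$mri$in_phase)
      assign_bulk_density(body, masks$bone & body, bulk_density_values(),
                          cal, geometry = case$ct)
    },
    tissue_class = {
      body <- segment_body(case$mri$in_phase)
      fat <- segment_fat(case$mri, body) & !masks$bone
      assign_tissue_class(body, masks$bone & body, fat,
                          tissue_class_values(), cal, geometry = case$ct)
    },
    atlas = {
      multi_atlas_sct(case, cohort[-ci], params = lwv)$sct
    },
    cgan = {
      predict_sct(cgan_models[[ci]], case$mri$in_phase, masks$body)
    })
}

# leave-one-out cGAN training: one model per held-out case
train_cgan_loo <- function(cohort, cfg) {
  lapply(seq_along(cohort), function(ci) {
    train <- cohort[-ci]
    stacks <- lapply(train, function(c)
      preprocess_pair(c$ct, c$mri$in_phase, c$masks$body, cfg))
    pairs <- list(mri = do.call(abind3, lapply(stacks, `[[`, "mri")),
                  ct = do.call(abind3, lapply(stacks, `[[`, "ct")),
                  meta = stacks[[1]]$meta)
    train_cgan(pairs, cfg)
  })
}

abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n <- sum(vapply(parts, function(p) dim(p)[3], numeric(1)))
  out <- array(0, c(d[1], d[2], n))
  at <- 0
  for (p in parts) {
    out[, , at + seq_len(dim(p)[3])] <- p
    at <- at + dim(p)[3]
  }
  out
}

evaluate_method <- function(case, ci, cohort, method, ct_ref, dose_ct,
                            beams, cal, crits, override_gas, cgan_models,
                            lwv) {
  sct <- generate_method_sct(case, ci, cohort, method, cgan_models, cal,
                             lwv)
  # the same override is applied to CT and every sCT before dose comparison
  if (override_gas) sct <- override_bowel_gas(sct, case$masks$body)
  body <- case$masks$body; bone <- case$masks$bone
  soft <- body & !bone
  rows <- list()
  add <- function(family, metric, value)
    rows[[length(rows) + 1]] <<- data.frame(family = family,
                                            metric = metric, value = value)
  for (rg in list(list("whole_body", body), list("bone", bone),
                  list("soft_tissue", soft))) {
    # compare against the same (gas-overridden) reference used for dose
    he <- hu_error(sct, ct_ref, rg[[2]], region_name = rg[[1]])
    add("hu", paste0("me_", rg[[1]]), he$me)
    add("hu", paste0("mae_", rg[[1]]), he$mae)
  }
  dose_sct <- case_dose(sct, case, beams, cal,
                        scale = attr(dose_ct, "scale"))
  icru_ct <- dose_at_point(dose_ct, case$reference_point)
  icru_sct <- dose_at_point(dose_sct, case$reference_point)
  add("dd", "icru_point", percent_dose_difference(icru_sct, icru_ct))
  dvh_structs <- list(ptv = case$masks$ptv, oar_bladder = case$masks$bladder)
  per_struct <- vapply(names(dvh_structs), function(nm) {
    m_ct <- dvh_metrics(dose_ct, dvh_structs[[nm]], case$prescription_dose)
    m_sct <- dvh_metrics(dose_sct, dvh_structs[[nm]],
                         case$prescription_dose)
    percent_dose_difference(m_sct[c("D98", "D50", "D2")],
                            m_ct[c("D98", "D50", "D2")])$average
  }, numeric(1))
  add("dd", "dvh_average", mean(per_struct))
  for (cr in crits) {
    g <- gamma_3d(dose_ct, dose_sct, body, cr)
    tag <- sprintf("%g_%g", cr$dose_diff_pct, cr$dta_mm)
    add("gamma", paste0("pass_", tag), g$pass_rate)
    add("gamma", paste0("mean_gamma_", tag), g$mean_gamma)
  }
  do.call(rbind, rows)
}
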