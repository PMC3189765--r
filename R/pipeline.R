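#' Study configuration
#'
#' A single flat configuration for the full modelling workflow.  Defaults
#' equal the conventional settings of a lattice-field QSAR study: 2.0 A
#' spacing, attenuation 0.3, 30 kcal/mol truncation, minimum sigma 1.0,
#' pharmacophore tolerance 0.25 A with 4-16 features and 50/7 conformers.
#'
#' @param sdf_path structure file (SDF); NULL when molecules are passed to
#'   [run_study()] directly
#' @param activity_path activity CSV; NULL when passed directly
#' @param scaffold_pattern substructure query of the shared scaffold; NULL
#'   skips the alignment stage (input treated as pre-aligned)
#' @param template_id alignment template compound; NULL picks the compound
#'   with the highest training activity
#' @param endpoint `"I"` or `"II"`
#' @param field_set `"comfa"`, `"comsia"` or `"both"`
#' @param spacing,margin lattice construction (A)
#' @param attenuation,truncation,dielectric probe settings, see
#'   [probe_spec()]
#' @param sigma_min column filtering threshold
#' @param scheme block scaling scheme
#' @param c_max largest PLS component count scanned by LOO
#' @param use_clogp include the calculated logP as an extra descriptor
#' @param contour_favored,contour_disfavored contour quantile levels
#' @param pharm_top_n actives entering the pharmacophore search (0 skips)
#' @param pharm pharmacophore parameters, see [pharm_params()]
#' @param seed study seed
#' @param out_dir output directory for the report and contour files (NULL:
#'   nothing written)
#' @return object of class `study_config`
#' @export
study_config <- function(sdf_path = NULL, activity_path = NULL,
                         scaffold_pattern = NULL, template_id = NULL,
                         endpoint = c("I", "II"),
                         field_set = c("comfa", "comsia", "both"),
                         spacing = 2.0, margin = 4.0,
                         attenuation = 0.3, truncation = 30,
                         dielectric = "distance",
                         sigma_min = 1.0,
                         scheme = c("comfa_std", "none"),
                         c_max = 8L, use_clogp = TRUE,
                         contour_favored = 0.80, contour_disfavored = 0.20,
                         pharm_top_n = 0L, pharm = pharm_params(),
                         seed = 1L, out_dir = NULL) {
  structure(list(sdf_path = sdf_path, activity_path = activity_path,
                 scaffold_pattern = scaffold_pattern, template_id = template_id,
                 endpoint = match.arg(endpoint),
                 field_set = match.arg(field_set),
                 spacing = spacing, margin = margin,
                 attenuation = attenuation, truncation = truncation,
                 dielectric = dielectric, sigma_min = sigma_min,
                 scheme = match.arg(scheme), c_max = as.integer(c_max),
                 use_clogp = use_clogp,
                 contour_favored = contour_favored,
                 contour_disfavored = contour_disfavored,
                 pharm_top_n = as.integer(pharm_top_n), pharm = pharm,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "study_config")
}

#' Load a study configuration from a YAML file
#'
#' Keys mirror the arguments of [study_config()]; pharmacophore parameters
#' live under a `pharm:` mapping.
#'
#' @param path YAML file
#' @return a `study_config`
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  pp <- if (!is.null(raw$pharm)) do.call(pharm_params, raw$pharm) else pharm_params()
  raw$pharm <- NULL
  args <- raw[names(raw) %in% names(formals(study_config))]
  args$pharm <- pp
  do.call(study_config, args)
}

#' Run the full 3D-QSAR study
#'
#' Stages: load (or accept) structures and activities; align onto the
#' template scaffold; evaluate the requested fields on a shared lattice;
#' assemble, filter and scale descriptors; scan component counts by
#' leave-one-out cross-validation; refit at the optimal count and report
#' the fit statistics, the external test-set prediction, per-field
#' contributions and per-compound predictions; extract stdev*coeff
#' contours; and, when requested, search the most active training
#' compounds for a common-feature pharmacophore.
#'
#' @param config a [study_config()]
#' @param molecules optional pre-loaded [molecule_set()] (overrides
#'   `sdf_path`)
#' @param activities optional pre-loaded activity data frame (overrides
#'   `activity_path`)
#' @return object of class `study_report` (a list; see the report fields)
#' @export
run_study <- function(config, molecules = NULL, activities = NULL) {
  stopifnot(inherits(config, "study_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE))
  }
  mols <- stage("input", {
    m <- if (!is.null(molecules)) molecules
         else read_molecules(config$sdf_path, "sdf")
    prepare_molecules(m)
  })
  acts <- stage("input", {
    a <- if (!is.null(activities)) activities
         else read_activities(config$activity_path)
    a <- a[a$endpoint == config$endpoint, ]
    if (nrow(a) == 0L) stop(sprintf("no activities for endpoint %s",
                                    config$endpoint))
    miss <- setdiff(a$compound_id, names(mols))
    if (length(miss)) stop(sprintf("no structure for compound(s): %s",
                                   paste(miss, collapse = ", ")))
    miss2 <- setdiff(names(mols), a$compound_id)
    if (length(miss2)) stop(sprintf("no activity for compound(s): %s",
                                    paste(miss2, collapse = ", ")))
    a
  })
  train_ids <- acts$compound_id[acts$set_label == "train"]
  test_ids <- acts$compound_id[acts$set_label == "test"]
  y <- stats::setNames(acts$pic50, acts$compound_id)
  aligned_rmsd <- NULL
  if (!is.null(config$scaffold_pattern)) {
    al <- stage("alignment", {
      tid <- config$template_id
      if (is.null(tid)) tid <- train_ids[which.max(y[train_ids])]
      align_series(mols, tid, config$scaffold_pattern)
    })
    mols <- al$molecules
    aligned_rmsd <- al$rmsd
  }
  probe <- probe_spec(attenuation = config$attenuation,
                      truncation = config$truncation,
                      dielectric = config$dielectric)
  fieldkinds <- switch(config$field_set, comfa = "comfa", comsia = "comsia",
                       both = c("comfa", "comsia"))
  fb <- stage("fields", {
    lattice <- build_lattice(mols, spacing = config$spacing,
                             margin = config$margin)
    compute_fields(mols, lattice, probe, fields = fieldkinds)
  })
  dm <- stage("descriptors", {
    extras <- if (config$use_clogp)
      data.frame(ClogP = vapply(mols, function(m) m$properties$ClogP,
                                numeric(1)),
                 row.names = names(mols))
    else NULL
    assemble_descriptors(fb, extras = extras, sigma_min = config$sigma_min,
                         train_ids = train_ids)
  })
  loo <- stage("loo", loo_validate(dm, y, c_max = config$c_max,
                                   train_ids = train_ids,
                                   scheme = config$scheme))
  model <- stage("fit", fit_qsar(dm, y, ncomp = loo$opn,
                                 train_ids = train_ids,
                                 scheme = config$scheme))
  summ <- model_summary(model)
  pred_all <- predict(model, dm)
  ext <- if (length(test_ids) >= 2L)
    r2_pred(y[test_ids], pred_all[test_ids], mean(y[train_ids]))
  else NA_real_
  contours <- stage("contour", {
    out <- list()
    for (f in setdiff(unique(dm$col_field), "extra")) {
      cs <- tryCatch(contour_set(model, f, config$contour_favored,
                                 config$contour_disfavored),
                     error = function(e) NULL)
      if (!is.null(cs)) out[[f]] <- cs
    }
    out
  })
  pharm_models <- list()
  if (config$pharm_top_n > 0L) {
    pharm_models <- stage("pharmacophore", {
      top <- train_ids[order(-y[train_ids])][seq_len(min(config$pharm_top_n,
                                                         length(train_ids)))]
      sub <- mols[top]
      sub <- molecule_set(lapply(sub, generate_conformers,
                                 params = config$pharm))
      disco_search(sub, reference_id = top[1L], params = config$pharm)
    })
  }
  report <- structure(list(
    endpoint = config$endpoint, field_set = config$field_set,
    n_train = length(train_ids), n_test = length(test_ids),
    q2 = loo$q2[loo$opn], sep = loo$sep[loo$opn], opn = loo$opn,
    q2_by_component = loo$q2,
    r2_ncv = summ$r2_ncv, see = summ$see, f_stat = summ$f_stat,
    r2_pred = ext,
    field_fractions = as.list(field_fractions(model)),
    predictions = data.frame(compound_id = names(pred_all),
                             observed = as.numeric(y[names(pred_all)]),
                             predicted = as.numeric(pred_all),
                             set_label = ifelse(names(pred_all) %in% test_ids,
                                                "test", "train")),
    alignment_rmsd = aligned_rmsd,
    pharmacophore = lapply(pharm_models, function(m)
      list(size = m$size, hits = m$hits, score = m$score,
           tolerance = m$tolerance, dmean = m$dmean,
           kinds = m$features$kind)),
    seed = config$seed,
    model = model, contours = contours, pharm_models = pharm_models,
    lattice = dm$lattice),
    class = "study_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(.report_json(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10)
    for (f in names(contours))
      export_contours(contours[[f]],
                      file.path(config$out_dir, paste0("contour_", f, ".cube")),
                      "cube")
    writeLines(report_table(report), file.path(config$out_dir, "table.txt"))
  }
  report
}

.report_json <- function(report) {
  keep <- c("endpoint", "field_set", "n_train", "n_test", "q2", "sep", "opn",
            "q2_by_component", "r2_ncv", "see", "f_stat", "r2_pred",
            "field_fractions", "predictions", "pharmacophore", "seed")
  out <- unclass(report)[keep]
  out$f_stat <- if (is.finite(out$f_stat)) out$f_stat else "Inf"
  out
}

#' @export
print.study_report <- function(x, ...) {
  cat(paste(report_table(x), collapse = "\n"), "\n")
  invisible(x)
}

#' Format a study report as a summary table
#'
#' Plain-text table with the conventional row labels of a lattice-field
#' QSAR summary: Q2, R2_ncv, SEE, F, R2_pre, SEP, OPN and the per-field
#' contribution rows.  Missing optional rows are omitted.
#'
#' @param report a [run_study()] report
#' @return character vector of lines
#' @export
report_table <- function(report) {
  fmt <- function(label, v, digits = 3)
    sprintf("%-14s %s", label, formatC(v, digits = digits, format = "f"))
  lines <- c(sprintf("PLS statistics (%s, endpoint %s; n = %d train / %d test)",
                     report$field_set, report$endpoint,
                     report$n_train, report$n_test),
             fmt("Q2", report$q2),
             fmt("R2_ncv", report$r2_ncv),
             fmt("SEE", report$see),
             fmt("F", report$f_stat))
  if (!is.na(report$r2_pred)) lines <- c(lines, fmt("R2_pre", report$r2_pred))
  lines <- c(lines, fmt("SEP", report$sep),
             sprintf("%-14s %d", "OPN", report$opn), "Contribution")
  fr <- report$field_fractions
  for (nm in names(fr)) lines <- c(lines, fmt(paste0("  ", nm), fr[[nm]]))
  lines
}
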