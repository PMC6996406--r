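#' Pipeline run configuration
#'
#' Collects the end-to-end run parameters. Defaults follow the method's
#' stated constants: score cutoff 30, reporter tolerance 0.05 Da, five
#' replicate experiments, ratio histogram bin width 0.05, frequency
#' index requirement equal to the number of experiments, alpha 0.05,
#' average linkage.
#'
#' @param sim a [sim_config()] describing the synthetic study to
#'   generate, or `NULL` when `jpf_paths` supplies real quantitation
#'   tables.
#' @param jpf_paths optional character vector of per-experiment `.jpf`
#'   files to analyse instead of simulating.
#' @param out_dir output directory for all stage files.
#' @param score_cutoff identification score cutoff (strict, default 30).
#' @param tolerance reporter mass tolerance in Da (default 0.05;
#'   recorded for the spectrum path).
#' @param bin_width ratio histogram bin width (default 0.05).
#' @param n_required required frequency index; `NULL` means the number
#'   of experiments.
#' @param alpha significance level for enrichment retention.
#' @param linkage clustering linkage (default `"average"`).
#' @param null_mean,null_sd optional fixed (calibrated) Gaussian null
#'   parameters for tier classification; `NULL` (default) classifies
#'   against the null fitted to this run's ratio distribution.
#' @param correction optional 4x4 isotope correction matrix applied
#'   during quantitation.
#' @param seed run seed; overrides `sim$seed` when simulating.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(sim = sim_config(), jpf_paths = NULL,
                       out_dir = tempfile("itraqr_run_"),
                       score_cutoff = 30, tolerance = 0.05,
                       bin_width = 0.05, n_required = NULL,
                       alpha = 0.05, linkage = "average",
                       null_mean = NULL, null_sd = NULL,
                       correction = NULL, seed = NULL) {
  if (is.null(sim) && is.null(jpf_paths))
    stop("either a simulation config or jpf_paths must be given")
  if (!is.null(sim) && !is.null(seed)) sim$seed <- as.integer(seed)
  if (xor(is.null(null_mean), is.null(null_sd)))
    stop("null_mean and null_sd must be given together")
  structure(list(sim = sim, jpf_paths = jpf_paths, out_dir = out_dir,
                 score_cutoff = score_cutoff, tolerance = tolerance,
                 bin_width = bin_width, n_required = n_required,
                 alpha = alpha, linkage = linkage,
                 null_mean = null_mean, null_sd = null_sd,
                 correction = correction,
                 seed = if (!is.null(sim)) sim$seed else seed),
            class = "run_config")
}

#' Read a flat key-value run configuration file
#'
#' Accepts a flat YAML mapping whose keys match the arguments of
#' [run_config()] and [sim_config()] (simulation keys may be prefixed
#' `sim_`). A `conditions` entry may be a comma-separated string.
#'
#' @param path YAML config file.
#' @param ... overrides applied after the file is read (CLI flags win).
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  over <- list(...)
  raw[names(over)] <- over
  split_csv <- function(x)
    if (is.character(x) && length(x) == 1L && grepl(",", x))
      trimws(strsplit(x, ",")[[1]]) else x
  sim_keys <- names(formals(sim_config))
  sim_args <- raw[intersect(names(raw), sim_keys)]
  pre <- raw[startsWith(names(raw), "sim_")]
  names(pre) <- sub("^sim_", "", names(pre))
  sim_args[names(pre)] <- pre
  if (!is.null(sim_args$conditions))
    sim_args$conditions <- split_csv(sim_args$conditions)
  run_keys <- setdiff(names(formals(run_config)), "sim")
  run_args <- raw[intersect(names(raw), run_keys)]
  if ("seed" %in% names(raw)) sim_args$seed <- raw$seed
  run_args$sim <- do.call(sim_config, sim_args)
  do.call(run_config, run_args)
}

.stage_row <- function(stage, rows_in, rows_out, note = "") {
  data.frame(stage = stage, rows_in = rows_in, rows_out = rows_out,
             note = note, stringsAsFactors = FALSE)
}

#' Run the full quantitation pipeline
#'
#' Executes simulate (or load) -> quantify -> filter -> catalogue ->
#' aggregate -> fit/classify -> enrich -> cluster, writing every stage's
#' output under `cfg$out_dir` and returning a run manifest with
#' per-stage row counts and output checksums. Identical configuration
#' and seed reproduce byte-identical outputs. Degenerate cascades (for
#' example a score cutoff that removes everything) finish with a warning
#' and a valid manifest rather than an error.
#'
#' @param cfg a [run_config()].
#' @return An object of class `"run_manifest"`: list with `stages`
#'   (stage, rows_in, rows_out, note), `files` (path, md5), `fit`
#'   (the `ratio_null` or `NULL`), `thresholds`, `out_dir`, `config`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  files <- character(0)
  put <- function(name) files <<- c(files, file.path(cfg$out_dir, name))

  # --- stage 1: simulate or load quantitation tables ---------------------
  truth <- NULL
  if (!is.null(cfg$sim)) {
    sim <- simulate_study(cfg$sim)
    truth <- sim$truth
    write_ground_truth(truth, file.path(cfg$out_dir, "ground_truth.tsv"))
    put("ground_truth.tsv")
    jpf <- vector("list", cfg$sim$n_experiments)
    n_psm <- 0L
    for (i in seq_len(cfg$sim$n_experiments)) {
      psm <- sim$psms[[i]]
      n_psm <- n_psm + nrow(psm)
      write_psm_table(psm, file.path(cfg$out_dir,
                                     sprintf("psm_exp%d.tsv", i)))
      put(sprintf("psm_exp%d.tsv", i))
      jpf[[i]] <- quantify_psms(psm,
                                reference_condition =
                                  cfg$sim$reference_condition,
                                correction = cfg$correction)
      write_jpf(jpf[[i]], file.path(cfg$out_dir,
                                    sprintf("quant_exp%d.jpf", i)))
      put(sprintf("quant_exp%d.jpf", i))
    }
    stages <- c(stages, list(.stage_row("simulate", cfg$sim$n_proteins,
                                        n_psm, "proteins in, PSMs out")))
    stages <- c(stages, list(.stage_row("quantify", n_psm,
                                        sum(vapply(jpf, nrow, 0L)))))
  } else {
    jpf <- lapply(cfg$jpf_paths, read_jpf)
    stages <- c(stages, list(.stage_row("load", length(cfg$jpf_paths),
                                        sum(vapply(jpf, nrow, 0L)),
                                        "files in, records out")))
  }

  # --- stage 2: CiR-C filter, catalogue, aggregate -----------------------
  filtered <- lapply(jpf, filter_peptides, score_cutoff = cfg$score_cutoff)
  rep_tot <- Reduce(`+`, lapply(filtered, attr, "filter_report"))
  stages <- c(stages, list(.stage_row(
    "filter", rep_tot[["input"]], rep_tot[["retained"]],
    sprintf("low_score %d, null_ratio %d, flagged %d",
            rep_tot[["low_score"]], rep_tot[["null_ratio"]],
            rep_tot[["flagged"]]))))
  if (rep_tot[["retained"]] == 0L) {
    warning("no peptides survive filtering; downstream stages skipped")
    return(.finish_manifest(cfg, stages, files, NULL, NULL, truth))
  }
  cat_all <- build_catalogue(filtered,
                             n_experiments = if (!is.null(cfg$sim))
                               cfg$sim$n_experiments else length(jpf))
  n_req <- if (is.null(cfg$n_required)) cat_all$n_experiments else
    cfg$n_required
  cat_top <- suppressWarnings(select_top_frequency(cat_all, n_req))
  stages <- c(stages, list(.stage_row("catalogue", nrow(cat_all$entries),
                                      nrow(cat_top$entries),
                                      sprintf("frequency index >= %d",
                                              n_req))))
  if (nrow(cat_top$entries) == 0L) {
    warning("empty top-frequency catalogue; downstream stages skipped")
    return(.finish_manifest(cfg, stages, files, NULL, NULL, truth))
  }
  quant <- aggregate_protein_ratios(cat_top)
  write_protein_catalogue(quant, file.path(cfg$out_dir,
                                           "protein_quant.tsv"))
  put("protein_quant.tsv")
  stages <- c(stages, list(.stage_row("aggregate",
                                      nrow(cat_top$observations),
                                      nrow(quant$overall))))

  # --- stage 3: Gaussian null and sigma tiers ----------------------------
  ratios <- quant$overall$ratio
  fit <- tryCatch(fit_ratio_null(ratios, bin_width = cfg$bin_width),
                  error = function(e) e)
  if (inherits(fit, "error")) {
    if (is.null(cfg$null_mean))
      stop("Gaussian null fit failed and no calibrated null given: ",
           conditionMessage(fit))
    fit <- NULL
  } else {
    write_fit_report(fit, file.path(cfg$out_dir, "fit_report.tsv"))
    put("fit_report.tsv")
  }
  th <- if (!is.null(cfg$null_mean))
    tier_thresholds(cfg$null_mean, sd = cfg$null_sd)
  else tier_thresholds(fit)
  classification <- classify_protein_quant(quant, th)
  utils::write.table(classification,
                     file.path(cfg$out_dir, "classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  put("classification.tsv")
  stages <- c(stages, list(.stage_row(
    "classify", nrow(quant$overall), nrow(classification),
    sprintf("null mean %.4f sd %.4f (%s)", attr(th, "mean"),
            attr(th, "sd"),
            if (is.null(cfg$null_mean)) "fitted" else "calibrated"))))

  # --- stage 4: over-representation of impacted protein classes ----------
  if (!is.null(truth)) {
    impacted <- unique(classification$accession[
      classification$tier != "none"])
    prot <- truth$proteins
    sizes <- .synthetic_class_sizes()
    obs <- table(factor(prot$protein_class[prot$protein_id %in% impacted],
                        levels = names(sizes)))
    classes <- data.frame(class_id = names(sizes),
                          reference_count = as.integer(sizes),
                          observed = as.integer(obs),
                          stringsAsFactors = FALSE)
    enr <- enrichment_test(classes, reference_total = sum(sizes),
                           input_size = max(1L, length(impacted)),
                           alpha = cfg$alpha)
    write_enrichment_table(enr, file.path(cfg$out_dir, "enrichment.tsv"))
    put("enrichment.tsv")
    stages <- c(stages, list(.stage_row("enrich", nrow(classes),
                                        sum(enr$retained),
                                        "classes in, retained out")))
  }

  # --- stage 5: hierarchical clustering ----------------------------------
  m <- ratio_matrix(quant)
  if (nrow(m) >= 2L) {
    cl <- cluster_ratio_matrix(m, linkage = cfg$linkage)
    write_ordered_matrix(cl, file.path(cfg$out_dir,
                                       "ratio_matrix_ordered.tsv"))
    put("ratio_matrix_ordered.tsv")
    write_dendrogram_newick(cl, file.path(cfg$out_dir,
                                          "dendrogram.newick"))
    put("dendrogram.newick")
    stages <- c(stages, list(.stage_row("cluster", nrow(m), nrow(m),
                                        paste(cfg$linkage, "linkage"))))
  }
  .finish_manifest(cfg, stages, files, fit, th, truth,
                   classification = classification)
}

.finish_manifest <- function(cfg, stages, files, fit, th, truth,
                             classification = NULL) {
  stages <- do.call(rbind, stages)
  md5 <- tools::md5sum(files)
  manifest <- structure(list(
    stages = stages,
    files = data.frame(path = basename(files), md5 = unname(md5),
                       stringsAsFactors = FALSE),
    fit = fit, thresholds = th, classification = classification,
    out_dir = cfg$out_dir,
    seed = cfg$seed
  ), class = "run_manifest")
  json <- list(seed = if (is.null(cfg$seed)) NA else cfg$seed,
               stages = stages,
               files = manifest$files)
  jsonlite::write_json(json, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run (seed ", x$seed, ") -> ", x$out_dir, "\n\n", sep = "")
  print(x$stages, row.names = FALSE)
  cat("\nOutputs:\n")
  print(x$files, row.names = FALSE)
  if (!is.null(x$fit)) {
    cat("\n")
    print(x$fit)
  }
  invisible(x)
}
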