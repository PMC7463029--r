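#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run: cohort size and family
#' structure, target heritability of the latent haemodynamic traits, SNP
#' panel size and missingness, QC thresholds, fluid constants, and stage
#' toggles. The configuration round-trips losslessly through
#' [write_run_config()] / [read_run_config()].
#'
#' @param n_families Number of families.
#' @param h2 Target narrow-sense heritability of the latent lumen-radius
#'   and peak-velocity traits.
#' @param seed Master seed; all stage seeds derive from it.
#' @param m_snps SNP panel size.
#' @param missing_rate Genotype missingness rate.
#' @param structure `cohort_structure()` settings (list form accepted).
#' @param thresholds `qc_thresholds()` settings (list form accepted).
#' @param rho,mu Fluid constants (kg/m^3, N.s/m^2).
#' @param turbulence_threshold Reynolds number reported as the turbulent
#'   fraction cut-off.
#' @param stages Named logical vector toggling `flow`, `adjust`,
#'   `genetics` and `gwas`.
#' @param gwas_trait Trait scanned by the mixed-model association stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_families = 108, h2 = 0.4, seed = 1,
                       m_snps = 2000, missing_rate = 0.01,
                       structure = cohort_structure(),
                       thresholds = qc_thresholds(),
                       rho = 1050, mu = 3e-3,
                       turbulence_threshold = 4000,
                       stages = c(flow = TRUE, adjust = TRUE,
                                  genetics = TRUE, gwas = TRUE),
                       gwas_trait = "re_pm") {
  if (!inherits(structure, "cohort_structure")) {
    structure <- do.call(cohort_structure, structure)
  }
  if (!inherits(thresholds, "qc_thresholds")) {
    thresholds <- do.call(qc_thresholds, thresholds)
  }
  stopifnot(h2 >= 0, h2 <= 1, n_families >= 1, m_snps >= 1)
  structure(list(n_families = n_families, h2 = h2, seed = seed,
                 m_snps = m_snps, missing_rate = missing_rate,
                 structure = structure, thresholds = thresholds,
                 rho = rho, mu = mu,
                 turbulence_threshold = turbulence_threshold,
                 stages = stages, gwas_trait = gwas_trait),
            class = "run_config")
}

#' Serialise / parse a run configuration
#'
#' @param config A [run_config()].
#' @param path JSON file path.
#' @return `write_run_config` invisibly returns `path`;
#'   `read_run_config` returns the reconstructed `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  plain <- lapply(config, function(x) if (is.list(x)) unclass(x) else x)
  # named vectors must survive as JSON objects, not bare arrays
  plain$structure$p_phenotyped <- as.list(plain$structure$p_phenotyped)
  plain$stages <- as.list(plain$stages)
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  plain <- jsonlite::read_json(path, simplifyVector = TRUE)
  drop_empty <- function(x) {
    x[vapply(x, length, 0L) > 0]  # JSON null round-trips as empty
  }
  plain$structure$p_phenotyped <- unlist(plain$structure$p_phenotyped)
  plain$structure <- do.call(cohort_structure,
                             drop_empty(as.list(plain$structure)))
  plain$thresholds <- do.call(qc_thresholds,
                              drop_empty(as.list(plain$thresholds)))
  plain$stages <- unlist(plain$stages)
  do.call(run_config, plain)
}

#' Simulate a full synthetic cohort
#'
#' Generates the pedigree, kinship matrix, covariates, SNP panel,
#' gene-dropped genotypes and two latent heritable haemodynamic traits --
#' lumen radius (mm) and peak systolic centreline velocity (m/s) -- each
#' with the configured polygenic fraction plus covariate effects (sex,
#' age, BMI, hypertension) so that the downstream stepwise adjustment has
#' true signal to find.
#'
#' @param config A [run_config()].
#' @return A list: `ped`, `kinship`, `covariates`, `panel`, `genotypes`,
#'   `radius_mm`, `peak_velocity` (named vectors over all individuals).
#' @export
simulate_cohort <- function(config = run_config()) {
  seeds <- derive_seeds(config$seed, 6)
  ped <- simulate_pedigrees(config$n_families, config$structure, seeds[1])
  kin <- kinship_matrix(ped)
  cov <- simulate_covariates(ped, seeds[2])
  panel <- simulate_snp_panel(config$m_snps, seed = seeds[3])
  g <- simulate_genotypes(ped, panel, config$missing_rate, seeds[4])
  # latent heritable traits on the measurement scale; intercepts calibrated
  # against the nominal covariate means so the cohort averages sit near
  # radius 15.5 mm (D ~ 0.031 m) and peak velocity 0.79 m/s
  t_r <- simulate_trait(ped, kin, trait_spec(config$h2, 1), seed = seeds[5])
  t_v <- simulate_trait(ped, kin, trait_spec(config$h2, 1), seed = seeds[6])
  b_r <- c(male = 0.9, age = 0.025, bmi = 0.05, hypertension = 0.5)
  b_v <- c(male = 0.05, age = -0.003, bmi = 0.004)
  nominal <- c(male = 0.49, age = 47, bmi = 25.88, hypertension = 0.39)
  int_r <- 15.5 - sum(b_r * nominal[names(b_r)])
  int_v <- 0.79 - sum(b_v * nominal[names(b_v)])
  Xr <- as.matrix(cov[, names(b_r)])
  Xv <- as.matrix(cov[, names(b_v)])
  radius <- int_r + drop(Xr %*% b_r) + 1.2 * t_r
  vel <- int_v + drop(Xv %*% b_v) + 0.09 * t_v
  radius <- pmin(pmax(radius, 8), 19)
  vel <- pmin(pmax(vel, 0.2, na.rm = TRUE), 1.6)
  names(radius) <- names(vel) <- ped$id
  list(ped = ped, kinship = kin, covariates = cov, panel = panel,
       genotypes = g, radius_mm = radius, peak_velocity = vel)
}

derive_seeds <- function(seed, k) {
  # numeric arithmetic avoids 32-bit overflow before the modulus
  as.integer((as.numeric(seed) * 1103 + 7919 * seq_len(k)) %% 2147483111)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the stages in order: cohort simulation, per-subject velocity
#' cines and flow metrics, stepwise covariate adjustment with
#' standardisation and 3-SD exclusion, genotype QC, pedigree-based
#' heritability (ML variance components on the kinship matrix), SNP-based
#' heritability (AI-REML on the GRM) and a mixed-model association scan.
#' Produces a per-trait summary with one row per (trait, method) holding
#' the p-value, the heritability estimate in percent, and the sample size
#' after adjustment -- the shape of a cohort heritability table.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, the cohort table, metric
#'   table, summary and a run manifest (config, seed, package version) are
#'   written there, each atomically (write to a temporary name, then
#'   rename).
#' @return A list of class `pipeline_result`: `summary` (data frame),
#'   `metrics`, `adjusted`, `qc`, `fits`, `assoc`, `frac_turbulent`,
#'   `config`, `log`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  log <- list()
  say <- function(...) log[[length(log) + 1L]] <<- sprintf(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  say("seed %d, %d families, target h2 %.2f", config$seed,
      config$n_families, config$h2)
  sim <- stage("simulate", simulate_cohort(config))
  ped <- sim$ped
  pheno_ids <- ped$id[ped$phenotyped]
  say("cohort: %d individuals, %d phenotyped, %d SNPs",
      nrow(ped), length(pheno_ids), nrow(sim$genotypes))
  constants <- fluid_constants(config$rho, config$mu)

  metrics <- NULL
  frac_turb <- NA_real_
  if (isTRUE(config$stages[["flow"]])) {
    cine_seeds <- derive_seeds(config$seed + 17L, length(pheno_ids))
    rows <- vector("list", length(pheno_ids))
    for (i in seq_along(pheno_ids)) {
      id <- pheno_ids[i]
      prof <- flow_profile(radius_mm = sim$radius_mm[[id]],
                           peak_velocity = sim$peak_velocity[[id]])
      cine <- simulate_flow_series(prof, seed = cine_seeds[i])
      m <- flow_metrics(cine, constants)
      rows[[i]] <- data.frame(id = id, csa = m$csa, d = m$d,
                              u_pm = m$u_pm, u_max = m$u_max,
                              re_pm = m$re_pm, re_max = m$re_max,
                              stringsAsFactors = FALSE)
    }
    metrics <- do.call(rbind, rows)
    frac_turb <- mean(metrics$re_pm > config$turbulence_threshold)
    say("flow metrics: mean U_pm %.3f m/s, mean D %.4f m, %.0f%% with Re_pm > %d",
        mean(metrics$u_pm), mean(metrics$d), 100 * frac_turb,
        config$turbulence_threshold)
  }

  trait_names <- c("csa", "d", "u_pm", "u_max", "re_pm", "re_max")
  adjusted <- list()
  if (isTRUE(config$stages[["adjust"]]) && !is.null(metrics)) {
    cv <- sim$covariates[match(metrics$id, sim$covariates$id), ]
    candidates <- data.frame(age = cv$age, age2 = cv$age2, sex = cv$male,
                             bmi = cv$bmi, sbp = cv$sbp,
                             hypertension = cv$hypertension)
    for (tr in trait_names) {
      model <- stage("adjust", stepwise_select(metrics[[tr]], candidates))
      adj <- adjust_standardize(metrics[[tr]], model)
      z <- adj$z
      z[adj$excluded] <- NA
      names(z) <- metrics$id
      adjusted[[tr]] <- list(model = model, adjusted = adj, z = z)
      say("adjust %s: covariates [%s], n retained %d", tr,
          paste(model$covariates, collapse = ", "), adj$n_retained)
    }
  }

  qc <- NULL
  fits <- list()
  assoc <- NULL
  summary_rows <- list()
  if (isTRUE(config$stages[["genetics"]])) {
    geno_ids <- ped$id[ped$genotyped]
    g_in <- sim$genotypes[, geno_ids, drop = FALSE]
    qc <- stage("qc", run_qc(g_in, ped, config$thresholds))
    say("QC: %d/%d SNPs and %d/%d genotyped individuals retained",
        length(qc$kept_snps), nrow(g_in), length(qc$kept_samples),
        ncol(g_in))
    grm <- stage("grm", compute_grm(qc$g))
    fam_of <- setNames(ped$family, ped$id)
    for (tr in names(adjusted)) {
      z <- adjusted[[tr]]$z
      z_ped <- z[!is.na(z)]
      fit_ped <- stage("pedigree_h2",
                       fit_polygenic(z_ped, sim$kinship,
                                     family = fam_of[names(z_ped)]))
      z_snp <- z_ped[names(z_ped) %in% qc$kept_samples]
      fit_snp <- stage("snp_h2", suppressWarnings(ai_reml(z_snp, grm)))
      fits[[tr]] <- list(pedigree = fit_ped, snp = fit_snp)
      summary_rows[[tr]] <- data.frame(
        trait = tr,
        method = c("pedigree-ML", "SNP-GREML"),
        p_value = c(fit_ped$p_value, fit_snp$p_value),
        h2_pct = 100 * c(fit_ped$h2, fit_snp$h2),
        n = c(fit_ped$n, fit_snp$n))
      say("h2 %s: pedigree %.0f%% (P=%.3g, n=%d), SNP %.0f%% (P=%.3g, n=%d)",
          tr, 100 * fit_ped$h2, fit_ped$p_value, fit_ped$n,
          100 * fit_snp$h2, fit_snp$p_value, fit_snp$n)
    }
    if (isTRUE(config$stages[["gwas"]]) &&
        config$gwas_trait %in% names(adjusted)) {
      z <- adjusted[[config$gwas_trait]]$z
      z_snp <- z[!is.na(z)]
      z_snp <- z_snp[names(z_snp) %in% qc$kept_samples]
      assoc <- stage("gwas",
                     mlma_scan(z_snp, qc$g, grm,
                               fit = fits[[config$gwas_trait]]$snp))
      say("MLMA %s: lambda_GC %.3f, %d genome-wide hits",
          config$gwas_trait, attr(assoc, "lambda_gc"),
          sum(assoc$genome_wide, na.rm = TRUE))
    }
  }
  summary <- if (length(summary_rows)) {
    out <- do.call(rbind, summary_rows)
    rownames(out) <- NULL
    out
  } else NULL

  result <- structure(list(summary = summary, metrics = metrics,
                           adjusted = adjusted, qc = qc, fits = fits,
                           assoc = assoc, frac_turbulent = frac_turb,
                           config = config, log = unlist(log)),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, sim, out_dir)
  result
}

write_pipeline_result <- function(result, sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  atomically <- function(path, writer) {
    tmp <- paste0(path, ".tmp")
    writer(tmp)
    file.rename(tmp, path)
  }
  atomically(file.path(out_dir, "cohort.tsv"), function(p) {
    write_cohort_table(sim$ped, sim$covariates, p)
  })
  if (!is.null(result$metrics)) {
    atomically(file.path(out_dir, "metrics.tsv"), function(p) {
      write_metric_table(result$metrics, p)
    })
  }
  if (!is.null(result$summary)) {
    atomically(file.path(out_dir, "summary.tsv"), function(p) {
      write.table(result$summary, p, quote = FALSE, sep = "\t",
                  row.names = FALSE)
    })
  }
  manifest <- list(seed = result$config$seed,
                   config = lapply(unclass(result$config),
                                   function(x) if (is.list(x)) unclass(x) else x),
                   package_version = as.character(utils::packageVersion("aortaflow")),
                   log = result$log)
  atomically(file.path(out_dir, "manifest.json"), function(p) {
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA)
  })
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  for (line in x$log) cat(" ", line, "\n")
  invisible(x)
}
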