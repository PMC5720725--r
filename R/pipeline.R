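# Configuration-driven orchestration of the full pipeline:
# synth -> align -> register -> fit -> sweep -> cej -> landmarks ->
# measure -> stats, with logging, JSON/CSV artifacts and a reproducible
# seed. Inputs are never mutated; all outputs live under the run
# directory.

#' Pipeline configuration
#'
#' @param out_dir output directory for all artifacts.
#' @param manifest optional CSV path (columns id, group, whole_mesh,
#'   enamel_mesh); when `NULL` a synthetic population is generated.
#' @param seed integer seed for all randomness.
#' @param synth list of [population_spec()] arguments for the synth stage.
#' @param align list: `icp_iter`, `icp_tol`, `global_init`.
#' @param register list: `alpha`, `lambda0`, `decay`, `tol`, `max_iter`,
#'   `delta` (`NULL` = per-target default).
#' @param pca list: `use_material`, `epsilon`, `cumulative_target`.
#' @param sweep_levels sigma levels for PC sweeps.
#' @param alphas list: `anova`, `regression`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, manifest = NULL, seed = 1L,
                            synth = list(n = 6L, cv = 0.05, noise = 0.02,
                                         scale_cv = 0.05, crown_root_cv = 0),
                            align = list(icp_iter = 50L, icp_tol = 1e-9,
                                         global_init = FALSE),
                            register = list(alpha = 0.5, lambda0 = 0.5,
                                            decay = 0.9, tol = 1e-4,
                                            max_iter = 200L, delta = NULL),
                            pca = list(use_material = TRUE, epsilon = 1e-8,
                                       cumulative_target = 0.95),
                            sweep_levels = -3:3,
                            alphas = list(anova = 0.05, regression = 0.01)) {
  stopifnot(register$tol >= 0, align$icp_tol > 0,
            pca$cumulative_target > 0, pca$cumulative_target <= 1)
  structure(list(out_dir = out_dir, manifest = manifest,
                 seed = as.integer(seed), synth = synth, align = align,
                 register = register, pca = pca,
                 sweep_levels = sweep_levels, alphas = alphas),
            class = "pipeline_config")
}

PIPELINE_STAGES <- c("synth", "align", "register", "fit", "sweep", "cej",
                     "landmarks", "measure", "stats")

log_line <- function(con, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  writeLines(msg, con)
}

#' Run the pipeline
#'
#' Executes stages in order up to `through` and writes per-stage
#' artifacts plus a log under the output directory. Reruns with the
#' same configuration and inputs reproduce identical numerical outputs.
#'
#' @param config a `pipeline_config`.
#' @param through last stage to execute (default `"stats"` = all).
#' @return run report: list with `stages` (completed stage names),
#'   `artifacts` (paths) and key results (`model`, `cohort`,
#'   `measurements`, `stats`).
#' @export
run_pipeline <- function(config, through = "stats") {
  stopifnot(inherits(config, "pipeline_config"))
  through <- match.arg(through, PIPELINE_STAGES)
  last <- match(through, PIPELINE_STAGES)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(config$out_dir, "pipeline.log"), "a")
  on.exit(close(logf))
  set.seed(config$seed)
  done <- character()
  art <- character()
  results <- list()
  t_stage <- function(name, expr) {
    t0 <- proc.time()[3]
    val <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s (completed: %s; artifacts: %s)",
                   name, conditionMessage(e),
                   paste(done, collapse = ", "),
                   paste(art, collapse = ", ")), call. = FALSE))
    log_line(logf, "stage %s done in %.2fs", name, proc.time()[3] - t0)
    done <<- c(done, name)
    val
  }

  # -- synth / load ----------------------------------------------------------
  specimens <- t_stage("synth", {
    if (!is.null(config$manifest)) {
      man <- utils::read.csv(config$manifest, stringsAsFactors = FALSE)
      lapply(seq_len(nrow(man)), function(i) {
        mesh <- load_mesh(man$whole_mesh[i])
        enamel <- if (!is.na(man$enamel_mesh[i]) && nzchar(man$enamel_mesh[i]))
          load_mesh(man$enamel_mesh[i]) else NULL
        list(id = man$id[i], group = man$group[i], mesh = mesh,
             enamel = enamel)
      })
    } else {
      sargs <- config$synth
      sargs$seed <- config$seed
      spec <- do.call(population_spec, sargs)
      pop <- generate_population(spec)
      sd_dir <- file.path(config$out_dir, "synth")
      dir.create(sd_dir, showWarnings = FALSE)
      rows <- lapply(pop, function(sp) {
        p <- file.path(sd_dir, paste0(sp$id, ".ply"))
        write_mesh(sp$mesh, p)
        data.frame(id = sp$id, group = sp$group, whole_mesh = p,
                   enamel_mesh = "", t(unlist(sp$params[MM_PARAMS])))
      })
      man_path <- file.path(sd_dir, "manifest.csv")
      utils::write.csv(do.call(rbind, rows), man_path, row.names = FALSE)
      art <- c(art, man_path)
      pop
    }
  })
  if (last == 1L) return(list(stages = done, artifacts = art, results = results))

  baseline <- specimens[[1]]$mesh
  baseline$material <- NULL

  # -- align -----------------------------------------------------------------
  t_stage("align", {
    al_dir <- file.path(config$out_dir, "align")
    dir.create(al_dir, showWarnings = FALSE)
    for (sp in specimens) {
      al <- align_chain(baseline, sp$mesh,
                        max_iter = config$align$icp_iter,
                        tol = config$align$icp_tol,
                        global_init = isTRUE(config$align$global_init))
      side <- file.path(al_dir, paste0(sp$id, "_transform.json"))
      jsonlite::write_json(list(matrix = as_homogeneous(al$transform),
                                scale = al$scale, rms = al$rms),
                           side, digits = NA)
      art <- c(art, side)
    }
    invisible(NULL)
  })
  if (last == 2L) return(list(stages = done, artifacts = art, results = results))

  # -- register --------------------------------------------------------------
  cohort <- t_stage("register", {
    co <- two_pass_register(specimens, baseline,
                            alpha = config$register$alpha,
                            lambda0 = config$register$lambda0,
                            decay = config$register$decay,
                            tol = config$register$tol,
                            max_iter = config$register$max_iter,
                            delta = config$register$delta,
                            icp_iter = config$align$icp_iter,
                            global_init = isTRUE(config$align$global_init))
    rg_dir <- file.path(config$out_dir, "registered")
    dir.create(rg_dir, showWarnings = FALSE)
    utils::write.csv(as.data.frame(co$faces),
                     file.path(rg_dir, "faces.csv"), row.names = FALSE)
    for (i in seq_along(co$vectors))
      write_mesh(shape_to_mesh(co$vectors[[i]], co$faces),
                 file.path(rg_dir, paste0(co$ids[i], "_registered.ply")))
    write_mesh(shape_to_mesh(compute_mean_shape(co), co$faces),
               file.path(rg_dir, "mean_shape.ply"))
    co
  })
  results$cohort <- cohort
  if (last == 3L) return(list(stages = done, artifacts = art, results = results))

  # -- fit -------------------------------------------------------------------
  model <- t_stage("fit", {
    m <- fit_model(cohort, use_material = config$pca$use_material,
                   epsilon = config$pca$epsilon)
    save_model(m, file.path(config$out_dir, "model.json"))
    utils::write.csv(variance_report(m),
                     file.path(config$out_dir, "variance.csv"),
                     row.names = FALSE)
    m
  })
  results$model <- model
  results$c <- choose_c(model, config$pca$cumulative_target)
  if (last == 4L) return(list(stages = done, artifacts = art, results = results))

  # -- sweep -----------------------------------------------------------------
  sweeps <- t_stage("sweep", {
    sw <- do.call(rbind, lapply(seq_len(results$c), function(pc)
      measure_sweep(model, cohort$faces, pc, levels = config$sweep_levels)))
    utils::write.csv(sw, file.path(config$out_dir, "sweeps.csv"),
                     row.names = FALSE)
    sw
  })
  results$sweeps <- sweeps
  if (last == 5L) return(list(stages = done, artifacts = art, results = results))

  # -- cej / landmarks / measure ---------------------------------------------
  mats <- t_stage("cej", {
    mp <- lapply(seq_along(cohort$vectors), function(i) {
      mesh <- shape_to_mesh(cohort$vectors[[i]], cohort$faces)
      material_pipeline(mesh)
    })
    cej_json <- file.path(config$out_dir, "cej_loops.json")
    jsonlite::write_json(lapply(mp, function(m) m$cej$loops), cej_json)
    art <- c(art, cej_json)
    mp
  })
  if (last == 6L) return(list(stages = done, artifacts = art, results = results))

  lms <- t_stage("landmarks", {
    lm_list <- lapply(seq_along(cohort$vectors), function(i) {
      mesh <- shape_to_mesh(cohort$vectors[[i]], cohort$faces)
      detect_landmarks(mesh, mats[[i]]$node_material, mats[[i]]$cej)
    })
    rows <- do.call(rbind, lapply(seq_along(lm_list), function(i) {
      p <- lm_list[[i]]$points
      data.frame(id = cohort$ids[i], landmark = rownames(p),
                 x = p[, 1], y = p[, 2], z = p[, 3],
                 vertex = lm_list[[i]]$vertex)
    }))
    utils::write.csv(rows, file.path(config$out_dir, "landmarks.csv"),
                     row.names = FALSE)
    lm_list
  })
  if (last == 7L) return(list(stages = done, artifacts = art, results = results))

  measurements <- t_stage("measure", {
    rows <- do.call(rbind, lapply(seq_along(lms), function(i) {
      mesh <- shape_to_mesh(cohort$vectors[[i]], cohort$faces)
      rec <- measure(lms[[i]], mesh)
      df <- as.data.frame(as.list(as.numeric(rec)))
      names(df) <- MEASUREMENT_NAMES
      cbind(data.frame(id = cohort$ids[i],
                       group = if (is.null(cohort$groups)) NA
                               else cohort$groups[i]),
            df)
    }))
    utils::write.csv(rows, file.path(config$out_dir, "measurements.csv"),
                     row.names = FALSE)
    rows
  })
  results$measurements <- measurements
  if (last == 8L) return(list(stages = done, artifacts = art, results = results))

  results$stats <- t_stage("stats", {
    reg <- pc_measurement_regressions(sweeps, alpha = config$alphas$regression)
    utils::write.csv(reg, file.path(config$out_dir, "regressions.csv"),
                     row.names = FALSE)
    an <- NULL
    if (!is.null(cohort$groups) && length(unique(cohort$groups)) >= 2L) {
      sc <- cohort_scores(model, cohort)
      npc <- min(results$c, ncol(sc))
      an <- compare_groups_all(sc[, seq_len(npc), drop = FALSE],
                               cohort$groups, alpha = config$alphas$anova)
      jsonlite::write_json(
        lapply(an, function(a) a[c("F", "p", "group_means")]),
        file.path(config$out_dir, "anova.json"), digits = NA)
    }
    list(regressions = reg, anova = an)
  })
  list(stages = done, artifacts = art, results = results)
}

#' Command-line entry point
#'
#' Subcommands: `synth`, `align`, `register`, `fit`, `sweep`, `cej`,
#' `landmarks`, `measure`, `stats`, `all` -- each runs the pipeline up
#' to (and including) that stage. Usage:
#' `toothssm <subcommand> --config config.json [--out DIR] [--seed N]`.
#' The JSON config holds [pipeline_config()] fields.
#'
#' @param args character vector of command-line arguments.
#' @return the run report, invisibly.
#' @export
ssm_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L)
    stop("usage: toothssm <stage|all> [--config FILE] [--out DIR] [--seed N]",
         call. = FALSE)
  sub <- args[1]
  if (!sub %in% c(PIPELINE_STAGES, "all"))
    stop(sprintf("unknown subcommand '%s'", sub), call. = FALSE)
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else default
  }
  cfg_path <- opt("--config")
  fields <- if (!is.null(cfg_path))
    jsonlite::read_json(cfg_path, simplifyVector = TRUE) else list()
  out <- opt("--out", fields$out_dir %||% "toothssm_run")
  seed <- as.integer(opt("--seed", fields$seed %||% 1L))
  fields$out_dir <- out
  fields$seed <- seed
  keep <- intersect(names(fields), names(formals(pipeline_config)))
  config <- do.call(pipeline_config, fields[keep])
  through <- if (sub == "all") "stats" else sub
  report <- run_pipeline(config, through = through)
  cat(sprintf("completed %d stage(s): %s\n", length(report$stages),
              paste(report$stages, collapse = ", ")))
  invisible(report)
}
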