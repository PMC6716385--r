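#' Validate a pipeline configuration file
#'
#' Reads a JSON or YAML pipeline configuration and validates it, reporting
#' every violation at once rather than stopping at the first. The
#' configuration drives [run_pipeline()] and has the shape:
#'
#' ```yaml
#' seed: 1
#' out_dir: results/
#' protocol: {G: 2, n_chains: 3, n_iter: 3000, n_burnin: 1000}
#' block_map: {Fish: nominal, Rescue: "ad hoc"}
#' drop_unknown_pairs: false
#' categories:
#'   Fish:    {n_participants: 60, n_archival: 250, n_items: 24}
#'   Rescue:  {n_participants: 60, n_archival: 254, n_items: 20}
#' ```
#'
#' Each entry of `categories` holds [sim_config()] overrides for that
#' category's synthetic study; alternatively a category may specify
#' `new_csv` / `archival_csv` paths to existing response files. Unknown
#' top-level keys produce a warning, not an error.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return a validated configuration list of class `pipeline_config`
#'   (invisibly errors with the full violation list otherwise).
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("seed", "out_dir", "protocol", "block_map", "categories",
             "drop_unknown_pairs")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    warning("ignoring unknown config key(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  errs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1,
      "seed must be a single integer")
  chk(is.character(cfg$out_dir) && length(cfg$out_dir) == 1,
      "out_dir must be a single path")
  pr <- cfg$protocol
  chk(is.list(pr) || is.numeric(pr), "protocol must be a mapping")
  if (is.list(pr)) {
    chk(!is.null(pr$G) && pr$G >= 2, "protocol.G must be >= 2")
    chk(!is.null(pr$n_chains) && pr$n_chains >= 1,
        "protocol.n_chains must be >= 1")
    chk(!is.null(pr$n_iter) && !is.null(pr$n_burnin) &&
          pr$n_iter > pr$n_burnin,
        "protocol.n_iter must exceed protocol.n_burnin")
    chk(is.null(pr$n_burnin) || pr$n_burnin >= 0,
        "protocol.n_burnin must be >= 0")
  }
  chk(length(cfg$categories) >= 1, "at least one category must be configured")
  chk(!is.null(cfg$block_map) &&
        all(unlist(cfg$block_map) %in% c("nominal", "ad hoc")),
      "block_map values must be 'nominal' or 'ad hoc'")
  for (cat in names(cfg$categories)) {
    spec <- cfg$categories[[cat]]
    chk(cat %in% names(cfg$block_map),
        paste0("category '", cat, "' missing from block_map"))
    if (is.null(spec$new_csv)) {
      sim_args <- spec[setdiff(names(spec), c("new_csv", "archival_csv"))]
      sim_args$category <- cat
      sim_args$seed <- if (!is.null(spec$seed)) spec$seed else cfg$seed
      test <- try(do.call(sim_config, sim_args), silent = TRUE)
      if (inherits(test, "try-error")) {
        errs <- c(errs, paste0("category '", cat, "': ",
                               trimws(attr(test, "condition")$message)))
      }
    } else {
      chk(file.exists(spec$new_csv),
          paste0("category '", cat, "': new_csv not found: ", spec$new_csv))
      if (!is.null(spec$archival_csv)) {
        chk(file.exists(spec$archival_csv),
            paste0("category '", cat, "': archival_csv not found: ",
                   spec$archival_csv))
      }
    }
  }
  if (length(errs)) {
    stop("invalid pipeline config:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  }
  cfg$drop_unknown_pairs <- isTRUE(cfg$drop_unknown_pairs)
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' For every configured category: obtain the two-session (and archival)
#' response tables — simulated with [generate_two_session_study()] or read
#' from CSV — then merge sessions, fit the mixture model, relabel, compute
#' convergence diagnostics, assign groups, and build the consistency and
#' criterion-change reports. All artifacts are written under
#' `cfg$out_dir/<category>/` as plain text (CSV/JSON), and a manifest
#' records every artifact together with the seed and a hash of the
#' configuration, so a re-run with the identical configuration reproduces
#' identical artifacts.
#'
#' @param cfg a `pipeline_config` from [validate_config()] (or a path to a
#'   config file).
#' @param verbose log stage progress.
#' @return the manifest, invisibly: a list with the config hash, seed, and
#'   per-category artifact paths. On a stage failure the error is
#'   re-thrown after writing a `FAILED` marker file, retaining partial
#'   artifacts.
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  if (is.character(cfg)) cfg <- validate_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  cfg_hash <- digest::digest(unclass(cfg))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  pr <- cfg$protocol
  manifest <- list(config_hash = cfg_hash, seed = cfg$seed,
                   categories = list())
  block_map <- unlist(cfg$block_map)

  for (cat in names(cfg$categories)) {
    cat_dir <- file.path(cfg$out_dir, cat)
    dir.create(cat_dir, recursive = TRUE, showWarnings = FALSE)
    marker <- file.path(cat_dir, "FAILED")
    if (file.exists(marker)) unlink(marker)
    arts <- list()
    result <- try({
      spec <- cfg$categories[[cat]]
      say("[%s] preparing data", cat)
      if (is.null(spec$new_csv)) {
        sim_args <- spec[setdiff(names(spec), c("new_csv", "archival_csv"))]
        sim_args$category <- cat
        sim_args$seed <- if (!is.null(spec$seed)) spec$seed else cfg$seed
        scfg <- do.call(sim_config, sim_args)
        truth <- generate_two_session_study(scfg)
        new_tab <- truth$table
        arch_tab <- truth$archival_table
        arts$responses <- file.path(cat_dir, "responses.csv")
        write_responses(new_tab, arts$responses)
        arts$truth <- file.path(cat_dir, "truth.json")
        jsonlite::write_json(
          list(switcher_ids = truth$switcher_ids,
               z_session1 = truth$params_session1$z,
               z_session2 = truth$params_session2$z,
               beta = truth$params_session1$beta,
               seed = scfg$seed),
          arts$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      } else {
        new_tab <- read_responses(spec$new_csv, provenance = "new")
        arch_tab <- if (!is.null(spec$archival_csv)) {
          read_responses(spec$archival_csv, provenance = "archival")
        } else NULL
      }

      say("[%s] merging sessions", cat)
      m <- merge_sessions(new_tab, arch_tab, cat)
      arts$matrix <- file.path(cat_dir, "merged_matrix.csv")
      write_matrix(m, arts$matrix)

      say("[%s] fitting: %d chains x %d iterations (burn-in %d)",
          cat, pr$n_chains, pr$n_iter, pr$n_burnin)
      fit <- fit_mcmc(m, G = pr$G, n_chains = pr$n_chains,
                      n_iter = pr$n_iter, n_burnin = pr$n_burnin,
                      seed = cfg$seed, verbose = verbose)
      fit <- relabel(fit)
      arts$samples <- file.path(cat_dir, "samples")
      write_samples(fit, arts$samples)

      diag <- convergence_diagnostics(fit)
      n_bad <- sum(diag$rhat > 1.1, na.rm = TRUE)
      if (n_bad > 0) {
        warning(sprintf("[%s] %d parameter(s) with split R-hat > 1.1",
                        cat, n_bad), call. = FALSE)
      }
      arts$diagnostics <- file.path(cat_dir, "diagnostics.csv")
      utils::write.csv(diag, arts$diagnostics, row.names = FALSE)

      say("[%s] assigning groups", cat)
      asg <- assign_groups(fit)
      if (any(asg$tie_flag)) {
        warning(sprintf("[%s] %d entry(ies) with tied assignment",
                        cat, sum(asg$tie_flag)), call. = FALSE)
      }
      arts$assignments <- file.path(cat_dir, "assignments.csv")
      utils::write.csv(as.data.frame(asg), arts$assignments, row.names = FALSE)

      pairs <- assign_sessions(asg, m)
      pairs$category <- cat
      cons <- build_consistency_report(new_tab, block_map[cat],
                                       drop_unknown_pairs = cfg$drop_unknown_pairs)
      changes <- build_group_change_report(pairs, cons)

      report <- list(
        category = cat,
        block = unname(block_map[cat]),
        config_hash = cfg_hash,
        seed = cfg$seed,
        overall_inconsistency = cons$overall,
        n_participants = nrow(pairs),
        n_changed = sum(pairs$changed),
        change_rate_among_inconsistent =
          changes$per_category$change_rate_among_inconsistent,
        rhat_max = suppressWarnings(max(diag$rhat, na.rm = TRUE)),
        n_ties = sum(asg$tie_flag)
      )
      arts$report <- file.path(cat_dir, "report.json")
      jsonlite::write_json(report, arts$report, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      arts$session_pairs <- file.path(cat_dir, "session_pairs.csv")
      utils::write.csv(pairs, arts$session_pairs, row.names = FALSE)
      "ok"
    }, silent = TRUE)
    if (inherits(result, "try-error")) {
      writeLines(as.character(result), marker)
      stop("pipeline failed for category '", cat, "': ",
           attr(result, "condition")$message, call. = FALSE)
    }
    manifest$categories[[cat]] <- arts
  }
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("pipeline complete: %s", manifest_path)
  invisible(manifest)
}
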