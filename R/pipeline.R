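#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run - generator sizes, judge panel,
#' level mapping, thresholds and form targets - into a validated list that
#' round-trips losslessly through JSON.  All thresholds are checked against
#' their documented ranges at construction.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param n_items,n_concepts synthetic bank size.
#' @param n_judges judge panel size (matching uses all of them).
#' @param n_children simulated cohort size for fitting and evaluation.
#' @param judge_error_rate adjacent-level flip probability, `[0, 0.5)`.
#' @param match_threshold edge threshold for equate groups, `(0, 1]`.
#' @param level_mapping named numeric over the four match levels.
#' @param form_kind `"short_form"` or `"long_form"`.
#' @param form_n_items target form length.
#' @param domain_targets named primary-domain weights.
#' @param start_pass_threshold start-rule pass threshold, `(0.5, 1]`.
#' @param stop_rule_k contiguous failures that stop administration (>= 1).
#' @param max_run longest tolerated same-domain run (>= 2).
#' @return object of class `PipelineConfig` (a validated list).
#' @export
pipelineConfig <- function(seed = 1L, n_items = 200L, n_concepts = 98L,
                           n_judges = 6L, n_children = 800L,
                           judge_error_rate = 0.1, match_threshold = 2 / 3,
                           level_mapping = defaultLevelMapping(),
                           form_kind = "short_form", form_n_items = 40L,
                           domain_targets = defaultDomainMix(),
                           start_pass_threshold = 0.9, stop_rule_k = 5L,
                           max_run = 3L) {
  level_mapping <- unlist(level_mapping)
  domain_targets <- unlist(domain_targets)
  cfg <- list(
    seed = as.integer(seed), n_items = as.integer(n_items),
    n_concepts = as.integer(n_concepts), n_judges = as.integer(n_judges),
    n_children = as.integer(n_children),
    judge_error_rate = judge_error_rate, match_threshold = match_threshold,
    level_mapping = level_mapping, form_kind = form_kind,
    form_n_items = as.integer(form_n_items), domain_targets = domain_targets,
    start_pass_threshold = start_pass_threshold,
    stop_rule_k = as.integer(stop_rule_k), max_run = as.integer(max_run)
  )
  stopIfNot(cfg$judge_error_rate >= 0 && cfg$judge_error_rate < 0.5,
            "judge_error_rate must be in [0, 0.5)")
  stopIfNot(cfg$match_threshold > 0 && cfg$match_threshold <= 1,
            "match_threshold must be in (0, 1]")
  stopIfNot(cfg$start_pass_threshold > 0.5 && cfg$start_pass_threshold <= 1,
            "start_pass_threshold must be in (0.5, 1]")
  stopIfNot(cfg$stop_rule_k >= 1L, "stop_rule_k must be >= 1")
  stopIfNot(cfg$max_run >= 2L, "max_run must be >= 2")
  stopIfNot(cfg$form_kind %in% c("short_form", "long_form"),
            "form_kind must be short_form or long_form")
  stopIfNot(setequal(names(cfg$level_mapping), MATCH_LEVELS),
            "level_mapping must cover the four match levels")
  class(cfg) <- "PipelineConfig"
  cfg
}

configToJSON <- function(cfg) {
  obj <- unclass(cfg)
  # named vectors must serialise as JSON objects, not bare arrays
  obj$level_mapping <- as.list(obj$level_mapping)
  obj$domain_targets <- as.list(obj$domain_targets)
  jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE, pretty = TRUE)
}

#' @rdname pipelineConfig
#' @param path file path for serialisation.
#' @export
writeConfig <- function(cfg, path) {
  writeLines(configToJSON(cfg), path)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readConfig <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    stopIfNot(requireNamespace("yaml", quietly = TRUE),
              "the yaml package is needed for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipelineConfig, obj)
}

#' @rdname pipelineConfig
#' @param cfg a `PipelineConfig`.
#' @export
configHash <- function(cfg) stableHash(as.character(configToJSON(cfg)))

# Structured audit logger: collects one record per decision, serialisable as
# JSON lines.  Byte-identical across runs with the same config.
newAudit <- function(cfg) {
  env <- new.env(parent = emptyenv())
  env$records <- list(list(
    stage = "init", event = "config",
    tool_version = as.character(packageVersion("raschform")),
    config_hash = configHash(cfg)
  ))
  env
}

auditLog <- function(audit, stage, event, ...) {
  audit$records[[length(audit$records) + 1L]] <-
    c(list(stage = stage, event = event), list(...))
  invisible(NULL)
}

writeAudit <- function(audit, path) {
  lines <- vapply(audit$records, function(r) {
    as.character(jsonlite::toJSON(r, digits = 15, auto_unbox = TRUE))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Run the full measure-creation pipeline
#'
#' Executes every stage on synthetic data: simulate an item bank, judge panel
#' outputs (matching, domain votes, feasibility flags); aggregate judgements
#' into matching coefficients, equate groups, domain profiles and feasibility
#' tables; simulate child responses and fit Rasch difficulties (anchored to the
#' generating scale through two anchor items); select representatives and
#' assemble, order and post-process a form (string-breaking for the short
#' form, three-group partition for the long form); derive start rules; and
#' evaluate the form.  Every artefact is written under `outDir` along with a
#' machine-readable audit log of each selection decision.  Fully deterministic
#' under the config seed; a stage failure halts with the stage name.
#'
#' @param cfg a [pipelineConfig()].
#' @param outDir output directory (created if absent).
#' @return invisibly, a list with the main in-memory artefacts (`bank`,
#'   `groups`, `params`, `form`, `report`, paths).
#' @export
runPipeline <- function(cfg, outDir) {
  stopIfNot(inherits(cfg, "PipelineConfig"), "cfg must be a PipelineConfig")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  audit <- newAudit(cfg)
  curve <- defaultReferenceCurve()
  stage <- "simulate"
  res <- tryCatch({
    ## --- simulate -----------------------------------------------------------
    bank <- simulateItemBank(cfg$n_items, cfg$n_concepts,
                             domainMix = cfg$domain_targets,
                             curve = curve, seed = subSeed(cfg$seed, 1L))
    ratings <- simulateJudgeMatchings(bank, cfg$n_judges, cfg$judge_error_rate,
                                      seed = subSeed(cfg$seed, 2L))
    votes <- simulateDomainVotes(bank, max(cfg$n_judges, 9L),
                                 seed = subSeed(cfg$seed, 3L))
    flags <- simulateFeasibilityFlags(bank, max(cfg$n_judges, 9L),
                                      seed = subSeed(cfg$seed, 4L))
    responses <- simulateResponses(bank, curve, cfg$n_children,
                                   seed = subSeed(cfg$seed, 5L))
    auditLog(audit, "simulate", "bank", n_items = nItems(bank),
             n_concepts = cfg$n_concepts)
    writeItemBank(bank, file.path(outDir, "bank.csv"))
    writeRatings(ratings, file.path(outDir, "ratings.csv"))
    writeRatings(votes, file.path(outDir, "votes.csv"))
    writeRatings(flags, file.path(outDir, "feasibility_flags.csv"))
    writeResponses(responses, file.path(outDir, "responses.csv"))
    writeGroundTruth(bank, curve, file.path(outDir, "ground_truth.json"))

    ## --- judgements ---------------------------------------------------------
    stage <- "judge"
    coef <- aggregateMatching(ratings, mapping = cfg$level_mapping)
    groups <- extractEquateGroups(coef, threshold = cfg$match_threshold)
    profiles <- buildDomainProfiles(votes, max(cfg$n_judges, 9L))
    modal <- modality(bank)
    feas <- list(
      direct_admin = tabulateFeasibility(
        flags[modal[flags$item_id] == "direct_admin", , drop = FALSE], "direct_admin"),
      caregiver_report = tabulateFeasibility(
        flags[modal[flags$item_id] == "caregiver_report", , drop = FALSE], "caregiver_report")
    )
    auditLog(audit, "judge", "aggregate", n_pairs = nrow(coef),
             n_groups = length(unique(groups$group_id)))
    writeRatings(coef, file.path(outDir, "matching_coefficients.csv"))
    jsonlite::write_json(split(groups$item_id, groups$group_id),
                         file.path(outDir, "equate_groups.json"), pretty = TRUE)
    writeRatings(profiles, file.path(outDir, "domain_profiles.csv"))
    writeRatings(feas$direct_admin$items, file.path(outDir, "feasibility_direct.csv"))
    writeRatings(feas$caregiver_report$items, file.path(outDir, "feasibility_caregiver.csv"))
    bank <- setEquateGroups(bank, groups)

    ## --- fit ----------------------------------------------------------------
    stage <- "fit"
    params <- fitDifficulties(responses, method = "mml", curve = curve)
    bank <- setDifficulties(bank, params)
    auditLog(audit, "fit", "difficulties",
             n_estimable = sum(params$estimable))
    writeRatings(params, file.path(outDir, "item_params.csv"))

    ## --- assemble -----------------------------------------------------------
    stage <- "assemble"
    want_modality <- if (cfg$form_kind == "short_form") "caregiver_report" else "direct_admin"
    feas_items <- feas[[want_modality]]$items
    reps <- selectRepresentatives(groups, bank, feasibility = feas_items,
                                  modality = want_modality)
    for (i in seq_len(nrow(reps))) {
      auditLog(audit, "assemble", "representative",
               group = reps$group_id[i], item = reps$item_id[i],
               reason = reps$reason[i])
    }
    form <- assembleForm(bank, cfg$form_kind, cfg$form_n_items, curve,
                         domainTargets = cfg$domain_targets,
                         representatives = reps)
    # facility precedence within latent concepts: lower rank precedes higher
    it <- itemData(bank)
    sel <- it[it$item_id %in% formItems(form), , drop = FALSE]
    pre <- do.call(rbind, lapply(split(sel, sel$latent_concept_id), function(s) {
      if (nrow(s) < 2L) return(NULL)
      s <- s[order(s$facility_rank), ]
      data.frame(earlier = head(s$item_id, -1), later = tail(s$item_id, -1))
    }))
    form <- orderItems(form, difficulties(bank),
                       precedence = pre)
    if (cfg$form_kind == "short_form") {
      doms <- setNames(primaryDomain(it$domain), it$item_id)
      form <- breakStrings(form, doms, maxRun = cfg$max_run)
      mv <- attr(form, "moves")
      for (i in seq_len(nrow(mv))) {
        auditLog(audit, "assemble", "string_break_move", item = mv$item_id[i],
                 from = mv$from[i], to = mv$to[i])
      }
    } else {
      form <- partitionLongForm(form, bank)
      auditLog(audit, "assemble", "partition",
               sizes = as.integer(table(formGroups(form))))
    }
    form@stop_rule_k <- cfg$stop_rule_k
    form <- deriveStartRules(form, responses,
                             passThreshold = cfg$start_pass_threshold)
    auditLog(audit, "assemble", "start_rule",
             brackets = startRule(form)$bracket_lower,
             start_index = startRule(form)$start_index)
    writeForm(form, file.path(outDir, "form.json"))
    writeAdminSheet(form, bank, file.path(outDir, "admin_sheet.txt"))

    ## --- evaluate -----------------------------------------------------------
    stage <- "evaluate"
    report <- evaluateForm(form, bank, curve, nChildren = cfg$n_children,
                           weights = profiles, seed = subSeed(cfg$seed, 6L))
    auditLog(audit, "evaluate", "report",
             daz_correlation = round(report@daz_correlation, 6),
             reliability = round(report@reliability, 6),
             mean_administered = round(report@admin_length$mean_administered, 3))
    jsonlite::write_json(
      list(
        form_id = report@form_id,
        config_hash = configHash(cfg),
        daz_correlation = report@daz_correlation,
        reliability = report@reliability,
        sem_by_age = report@sem_by_age,
        info_by_domain_age = report@info_by_domain_age,
        admin_length = report@admin_length
      ),
      file.path(outDir, "evaluation.json"),
      digits = 10, auto_unbox = TRUE, pretty = TRUE, na = "null"
    )

    list(bank = bank, coefficients = coef, groups = groups, params = params,
         form = form, report = report, out_dir = outDir)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  writeConfig(cfg, file.path(outDir, "config.json"))
  writeAudit(audit, file.path(outDir, "audit.jsonl"))
  invisible(res)
}
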