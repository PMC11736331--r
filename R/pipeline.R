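stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("[stage %s] %s", name, conditionMessage(e)),
                 class = "vetamc_stage_error", parent = e)
  })
}

#' Run the full national AMC surveillance pipeline
#'
#' Reads (or accepts in-memory) import records, the ingredient registry
#' and the livestock denominator inputs, then: screens records for
#' food-animal indication, quantifies them to grams of active
#' ingredient, aggregates to year-by-class totals, classifies totals by
#' WOAH/WHO importance, estimates the national biomass denominator,
#' standardises consumption as mg/kg, and tests the annual series for
#' monotonic trend. Writes the report bundle (class-by-year table,
#' importance table, mg/kg table, trend JSON, mg/kg bar chart, run log)
#' to `out_dir`.
#'
#' @param records `amc_records` or path to a records CSV.
#' @param registry `amc_registry` or path to a registry YAML; defaults
#'   to the bundled registry.
#' @param denominators `denominator_inputs` or path to a denominators
#'   CSV; `NULL` skips biomass adjustment.
#' @param out_dir output directory; `NULL` skips writing files.
#' @param years optional study window used to validate record years.
#' @param mk_method Mann-Kendall p-value method (see [mann_kendall()]).
#' @param biomass_mode small-ruminant biomass basis (see
#'   [species_biomass()]).
#' @param digits report-time rounding.
#' @param make_plot write the mg/kg bar chart (requires `out_dir`).
#' @return invisibly, a list with `totals`, `table1`, `importance`,
#'   `table2`, `biomass`, `adjusted`, `trend`, `excluded`.
#' @export
run_amc_pipeline <- function(records, registry = default_registry_path(),
                             denominators = NULL, out_dir = NULL,
                             years = NULL, mk_method = "auto",
                             biomass_mode = "population", digits = 2,
                             make_plot = TRUE) {
  registry <- stage("registry", {
    if (inherits(registry, "amc_registry")) registry
    else load_registry(registry)
  })
  records <- stage("records", {
    if (inherits(records, "amc_records")) records
    else read_import_records(records, years = years)
  })
  denominators <- stage("denominators", {
    if (is.null(denominators) || inherits(denominators, "denominator_inputs")) {
      denominators
    } else read_denominators(denominators)
  })

  screened <- stage("screening", screen_food_animal(records))
  quantified <- stage("quantification",
                      quantify_records(screened$kept, registry))
  totals <- stage("aggregation", aggregate_imports(quantified))
  table1 <- stage("aggregation", table1_report(totals, digits = digits))
  importance <- stage("classification",
                      who_flags(classify_importance(totals, registry)))
  table2 <- stage("classification", table2_report(importance, digits = digits))

  yrs <- sort(unique(totals$year))
  series <- annual_totals(totals)
  trend <- stage("trend", mann_kendall(series$total_kg, method = mk_method))

  biomass <- NULL
  adjusted <- NULL
  if (!is.null(denominators)) {
    biomass <- stage("biomass",
                     national_biomass(yrs, denominators, mode = biomass_mode))
    adjusted <- stage("adjustment", adjust_by_biomass(totals, biomass))
  }

  result <- list(totals = totals, table1 = table1, importance = importance,
                 table2 = table2, biomass = biomass, adjusted = adjusted,
                 trend = trend, excluded = screened$excluded)

  if (!is.null(out_dir)) {
    stage("reporting", write_report_bundle(result, out_dir,
                                           registry = registry,
                                           digits = digits,
                                           make_plot = make_plot))
  }
  invisible(result)
}

write_report_bundle <- function(result, out_dir, registry, digits = 2,
                                make_plot = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$table1, file.path(out_dir, "annual_class_totals.csv"),
                   progress = FALSE)
  readr::write_csv(result$table2, file.path(out_dir, "importance_summary.csv"),
                   progress = FALSE)

  trend <- result$trend
  jsonlite::write_json(
    list(n = trend$n, S = trend$S, tau = trend$tau, var_S = trend$var_S,
         p_value = trend$p_value, method = trend$method),
    file.path(out_dir, "trend.json"), auto_unbox = TRUE, digits = NA)

  if (!is.null(result$adjusted)) {
    adj <- result$adjusted
    out <- adj
    out$mg_per_kg <- round_half_up(out$mg_per_kg, digits)
    readr::write_csv(out, file.path(out_dir, "mg_per_kg.csv"),
                     progress = FALSE)
    if (make_plot) {
      p <- ggplot2::ggplot(adj, ggplot2::aes(x = factor(.data$year),
                                             y = .data$mg_per_kg)) +
        ggplot2::geom_col(fill = "steelblue") +
        ggplot2::labs(x = "Year",
                      y = "Antimicrobial imports (mg) per kg animal biomass",
                      title = "Biomass-adjusted antimicrobial consumption") +
        ggplot2::theme_minimal()
      ggplot2::ggsave(file.path(out_dir, "mg_per_kg.png"), p,
                      width = 6, height = 4, dpi = 150)
    }
  }

  log_lines <- c(
    sprintf("vetamc run %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("list editions: %s",
            paste(names(registry$list_edition),
                  unlist(registry$list_edition),
                  sep = " = ", collapse = "; ")),
    sprintf("trend method: %s", result$trend$method),
    sprintf("records excluded (no food-animal indication): %d",
            nrow(result$excluded))
  )
  if (nrow(result$excluded) > 0) {
    log_lines <- c(log_lines,
                   paste("  excluded record_id:",
                         paste(result$excluded$record_id, collapse = ", ")))
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
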