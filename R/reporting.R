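#' Export a weighted symptom graph
#'
#' Writes a DAG with arc strengths as Graphviz DOT, GraphML, or a TSV arc
#' table with columns `From`, `To`, `Strength` (the layout of the published
#' arc-strength tables). Edge weight is `|strength|`; the visual weight
#' (DOT `penwidth`, GraphML `visual_weight`) is `|strength|` rescaled
#' linearly onto `[0.5, 3]` within the graph — proportional emphasis, no
#' absolute scale. A graph with a single arc gets the maximal visual weight.
#'
#' @param g a [dag()].
#' @param strengths `data.frame` (`from`, `to`, `strength`) covering every
#'   arc of `g` (e.g. from [arc_strength()]); extra rows are ignored.
#' @param format `"dot"`, `"graphml"` or `"tsv"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_graph <- function(g, strengths, format = c("dot", "graphml", "tsv"),
                         path) {
  format <- match.arg(format)
  a <- arcs(g)
  key <- paste(a$from, a$to)
  skey <- paste(strengths$from, strengths$to)
  if (!all(key %in% skey))
    stop("strength missing for arcs: ", toString(setdiff(key, skey)))
  a$strength <- strengths$strength[match(key, skey)]
  w <- abs(a$strength)
  vis <- if (nrow(a) == 0) numeric(0)
         else if (diff(range(w)) < 1e-12) rep(3, nrow(a))
         else 0.5 + 2.5 * (w - min(w)) / (max(w) - min(w))
  if (format == "tsv") {
    utils::write.table(
      data.frame(From = a$from, To = a$to, Strength = a$strength),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "dot") {
    lines <- c("digraph symptom_network {",
               "  rankdir=LR;",
               sprintf("  \"%s\";", g$nodes),
               sprintf("  \"%s\" -> \"%s\" [weight=%.6g, penwidth=%.3f];",
                       a$from, a$to, w, vis),
               "}")
    writeLines(lines, path)
  } else {
    nodes_xml <- sprintf("    <node id=\"%s\"/>", g$nodes)
    edges_xml <- if (nrow(a)) {
      sprintf(paste0("    <edge source=\"%s\" target=\"%s\">",
                     "<data key=\"w\">%.10g</data>",
                     "<data key=\"vw\">%.4f</data></edge>"),
              a$from, a$to, w, vis)
    } else character(0)
    lines <- c(
      "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
      "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
      paste0("  <key id=\"w\" for=\"edge\" attr.name=\"weight\"",
             " attr.type=\"double\"/>"),
      paste0("  <key id=\"vw\" for=\"edge\" attr.name=\"visual_weight\"",
             " attr.type=\"double\"/>"),
      "  <graph id=\"G\" edgedefault=\"directed\">",
      nodes_xml, edges_xml,
      "  </graph>", "</graphml>")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Run the full analysis pipeline from a configuration file
#'
#' Executes cohort ingestion (or synthetic generation), inclusion filtering,
#' MetS classification and group split, the descriptive summary, and — per
#' group — hill-climbing structure learning, bootstrap stability, the
#' threshold-averaged network and full-data arc strengths; then writes all
#' publication-style outputs and a run manifest.
#'
#' Configuration (JSON or YAML) fields: `input` (path to a cohort CSV/TSV)
#' or `synthetic` (`n_total`, `prevalence`, or a `spec` file path); `seed`;
#' `score_kind` (`bic_gaussian` default); `boot_R` (default 200);
#' `strength_threshold` (0.85); `direction_threshold` (0.5); optional
#' `symptoms` (canonical symptom columns to analyse, default all ten);
#' `column_map` for non-canonical input headers. CLI flags of the bundled
#' wrapper map one-to-one onto these fields.
#'
#' Outputs in `out_dir`: `cohort.tsv` (with criterion flags), `table1.tsv` /
#' `table1.json`, and per group `arcs_<group>.tsv`, `stability_<group>.tsv`,
#' `network_<group>.dot` / `.graphml`, plus `manifest.json`. Any stage error
#' aborts the run with the stage name; `manifest.json` is then marked
#' incomplete.
#'
#' @param config_path path to the configuration file.
#' @param out_dir output directory (created if needed); defaults to the
#'   config's `out_dir`.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config_path, out_dir = NULL) {
  cfg <- if (grepl("\\.json$", config_path, ignore.case = TRUE)) {
    jsonlite::read_json(config_path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(config_path)
  }
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) stop("no output directory configured")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% 1)
  score_kind <- cfg$score_kind %||% "bic_gaussian"
  boot_R <- as.integer(cfg$boot_R %||% 200)
  st <- cfg$strength_threshold %||% 0.85
  dt <- cfg$direction_threshold %||% 0.5
  symptoms <- cfg$symptoms %||% phq_cols()
  manifest <- list(config = cfg, config_path = config_path, seed = seed,
                   boot_R = boot_R, strength_threshold = st,
                   direction_threshold = dt, score_kind = score_kind,
                   package_version = as.character(
                     utils::packageVersion("phqnet")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   complete = FALSE, stages = list())
  fail <- function(stage, e) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) fail(name, e))
    res
  }

  cohort <- stage("cohort", {
    if (!is.null(cfg$input)) {
      cmap <- unlist(cfg$column_map %||% list())
      rec <- load_cohort(cfg$input, cmap)
      apply_inclusion(rec, cfg$required_codes %||% c("F32.9", "F33.9"))
    } else {
      sp <- if (!is.null(cfg$synthetic$spec)) {
        read_synthetic_spec(cfg$synthetic$spec)
      } else {
        synthetic_spec(n_total = cfg$synthetic$n_total %||% 1779,
                       prevalence = cfg$synthetic$prevalence %||%
                         (315 / 1779),
                       seed = seed)
      }
      generate_cohort(sp)
    }
  })
  manifest$stages$cohort <- list(rows = nrow(cohort))
  stage("classify", write_cohort(cohort, file.path(out_dir, "cohort.tsv")))
  groups <- stage("split", split_groups(cohort))
  manifest$stages$split <- list(mets = nrow(groups$mets),
                                non_mets = nrow(groups$non_mets))
  stage("describe", {
    tbl <- summary_table(groups$mets, groups$non_mets)
    write_summary_table(tbl, file.path(out_dir, "table1.tsv"),
                        file.path(out_dir, "table1.json"))
  })

  for (grp in c("mets", "non_mets")) {
    dat <- groups[[grp]][, intersect(symptoms, names(cohort)), drop = FALSE]
    names(dat) <- toupper(names(dat))
    res <- stage(paste0("learn_", grp), {
      boots <- bootstrap_networks(dat, R = boot_R, seed = seed + 1,
                                  score_kind = score_kind)
      stab <- edge_stability(boots)
      avg <- averaged_network(stab, st, dt)
      strengths <- arc_strength(dat, avg$dag, score_kind)
      list(stab = stab, avg = avg, strengths = strengths)
    })
    stage(paste0("report_", grp), {
      utils::write.table(res$stab,
                         file.path(out_dir, paste0("stability_", grp, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      export_graph(res$avg$dag, res$strengths, "tsv",
                   file.path(out_dir, paste0("arcs_", grp, ".tsv")))
      export_graph(res$avg$dag, res$strengths, "dot",
                   file.path(out_dir, paste0("network_", grp, ".dot")))
      export_graph(res$avg$dag, res$strengths, "graphml",
                   file.path(out_dir, paste0("network_", grp, ".graphml")))
    })
    manifest$stages[[paste0("learn_", grp)]] <-
      list(replicates = boot_R, retained_arcs = narcs(res$avg$dag))
  }
  manifest$complete <- TRUE
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
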