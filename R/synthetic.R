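#' Ground-truth symptom networks for the two clinical groups
#'
#' Preset DAGs over the ten symptom nodes (`PHQ1`..`PHQ10`: the nine PHQ-9
#' items plus the functional-difficulty item) with the arc sets reported for
#' depressed adults with (11 arcs) and without (21 arcs) metabolic syndrome.
#' These serve as ground truth for the synthetic generator and for
#' structure-recovery tests; the numeric arc strengths of the source
#' analysis are data-dependent and are deliberately not part of the preset.
#'
#' @param group `"mets"` or `"non_mets"`.
#' @return a [dag()] on nodes `PHQ1`..`PHQ10`.
#' @export
make_preset_dag <- function(group = c("mets", "non_mets")) {
  group <- match.arg(group)
  nodes <- paste0("PHQ", 1:10)
  arcs_mets <- matrix(c(
    "PHQ1", "PHQ4",
    "PHQ2", "PHQ1",
    "PHQ2", "PHQ6",
    "PHQ2", "PHQ9",
    "PHQ3", "PHQ7",
    "PHQ4", "PHQ3",
    "PHQ4", "PHQ5",
    "PHQ4", "PHQ10",
    "PHQ5", "PHQ6",
    "PHQ5", "PHQ7",
    "PHQ10", "PHQ8"), ncol = 2, byrow = TRUE)
  arcs_non <- matrix(c(
    "PHQ1", "PHQ2",
    "PHQ1", "PHQ4",
    "PHQ1", "PHQ6",
    "PHQ1", "PHQ10",
    "PHQ2", "PHQ3",
    "PHQ2", "PHQ6",
    "PHQ2", "PHQ7",
    "PHQ2", "PHQ10",
    "PHQ3", "PHQ5",
    "PHQ4", "PHQ3",
    "PHQ4", "PHQ5",
    "PHQ6", "PHQ4",
    "PHQ6", "PHQ7",
    "PHQ6", "PHQ8",
    "PHQ6", "PHQ9",
    "PHQ6", "PHQ10",
    "PHQ7", "PHQ5",
    "PHQ7", "PHQ8",
    "PHQ8", "PHQ3",
    "PHQ10", "PHQ4",
    "PHQ10", "PHQ7"), ncol = 2, byrow = TRUE)
  a <- if (group == "mets") arcs_mets else arcs_non
  dag(nodes, data.frame(from = a[, 1], to = a[, 2], stringsAsFactors = FALSE))
}

#' Default arc coefficients for a ground-truth DAG
#'
#' Standardised linear effects assigned by the child's in-degree: 0.65 for a
#' single parent, 0.5 each for two, 0.33 each for three or more. The taper
#' keeps the implied linear predictor variance below 1 so every child can be
#' standardised to unit marginal variance (see [sample_symptoms()]); these
#' are arbitrary test magnitudes, not estimates from the source analysis.
#'
#' @param g a [dag()].
#' @return `data.frame` (`from`, `to`, `coef`).
#' @export
default_arc_coefficients <- function(g) {
  a <- arcs(g)
  if (!nrow(a)) return(cbind(a, coef = numeric(0)))
  indeg <- table(a$to)
  m <- as.integer(indeg[a$to])
  a$coef <- ifelse(m == 1, 0.65, ifelse(m == 2, 0.5, 0.33))
  a
}

#' Sample ordinal symptom data from a linear-Gaussian DAG
#'
#' Latent symptom scores are generated in topological order: each node is a
#' linear combination of its parents' latents plus Gaussian noise, with the
#' noise variance set to `1 - Var(linear predictor)` so every latent has
#' unit marginal variance (hence for a single arc the latent correlation
#' equals the coefficient). Latents are then discretised into the ordinal
#' 0-3 item scale by `cutpoints`. Errors if the coefficients imply a
#' predictor variance >= 1 for some node (no valid standardisation).
#'
#' @param g a [dag()] (the ground truth).
#' @param coefficients `data.frame` (`from`, `to`, `coef`) covering every
#'   arc of `g`; defaults to [default_arc_coefficients()].
#' @param cutpoints strictly increasing numeric vector of three latent
#'   thresholds mapping to scores 0..3. The default `c(-0.15, 0.75, 1.60)`
#'   gives item means near 0.85, inside the 0.2-1.7 range typical of PHQ
#'   items in depressed cohorts.
#' @param n rows to generate.
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @param keep_latent attach the latent matrix as attribute `"latent"`.
#' @return `data.frame` of integer items named as the DAG nodes.
#' @export
sample_symptoms <- function(g, coefficients = default_arc_coefficients(g),
                            cutpoints = c(-0.15, 0.75, 1.60), n = 1000,
                            seed = NULL, keep_latent = FALSE) {
  stopifnot(inherits(g, "dag"), n >= 1, !is.unsorted(cutpoints, strictly = TRUE))
  ord <- topo_sort(g)
  if (is.null(ord)) stop("input graph is cyclic")
  a <- arcs(g)
  ck <- paste(coefficients$from, coefficients$to)
  missing_arcs <- setdiff(paste(a$from, a$to), ck)
  if (length(missing_arcs))
    stop("coefficients missing for arcs: ", toString(missing_arcs))
  if (!is.null(seed)) set.seed(as.integer(seed))
  nodes <- g$nodes
  p <- length(nodes)
  lat <- matrix(0, n, p, dimnames = list(NULL, nodes))
  # population covariance of the latents, built in topological order, is used
  # to standardise each child to unit variance
  covm <- matrix(0, p, p, dimnames = list(nodes, nodes))
  for (nd in ord) {
    pa <- parents(g, nd)
    if (!length(pa)) {
      lat[, nd] <- stats::rnorm(n)
      covm[nd, nd] <- 1
      next
    }
    b <- coefficients$coef[match(paste(pa, nd), ck)]
    v_lin <- as.numeric(t(b) %*% covm[pa, pa, drop = FALSE] %*% b)
    if (v_lin >= 1 - 1e-6)
      stop("coefficients for node ", nd,
           " imply predictor variance >= 1; cannot standardise")
    lat[, nd] <- lat[, pa, drop = FALSE] %*% b +
      sqrt(1 - v_lin) * stats::rnorm(n)
    covm[, nd] <- covm[nd, ] <- as.numeric(covm[, pa, drop = FALSE] %*% b)
    covm[nd, nd] <- 1
  }
  items <- as.data.frame(lapply(nodes, function(nd)
    as.integer(findInterval(lat[, nd], cutpoints))))
  names(items) <- nodes
  if (keep_latent) attr(items, "latent") <- lat
  items
}

#' Specification of a synthetic cohort
#'
#' Bundles everything the generator needs: ground-truth symptom DAG and arc
#' coefficients per group, ordinal cutpoints, per-group metabolic
#' distributions (defaulting to the published group means/SDs of
#' [table1_presets()]), MetS prevalence, total size and seed.
#'
#' @param n_total cohort size; default 1779, the reference analysis size.
#' @param prevalence fraction of MetS participants, in (0, 1); default
#'   315/1779.
#' @param seed master RNG seed.
#' @param dag_mets,dag_non_mets ground-truth [dag()]s; default the presets.
#' @param coefficients_mets,coefficients_non_mets arc coefficient tables.
#' @param cutpoints ordinal discretisation thresholds.
#' @param metabolic per-group distribution table in the format of
#'   [table1_presets()].
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_total = 1779, prevalence = 315 / 1779, seed = 1,
                           dag_mets = make_preset_dag("mets"),
                           dag_non_mets = make_preset_dag("non_mets"),
                           coefficients_mets =
                             default_arc_coefficients(dag_mets),
                           coefficients_non_mets =
                             default_arc_coefficients(dag_non_mets),
                           cutpoints = c(-0.15, 0.75, 1.60),
                           metabolic = table1_presets()) {
  stopifnot(n_total >= 1, prevalence >= 0, prevalence < 1,
            is_acyclic(dag_mets), is_acyclic(dag_non_mets),
            !is.unsorted(cutpoints, strictly = TRUE))
  structure(list(n_total = n_total, prevalence = prevalence,
                 seed = as.integer(seed), dag_mets = dag_mets,
                 dag_non_mets = dag_non_mets,
                 coefficients_mets = coefficients_mets,
                 coefficients_non_mets = coefficients_non_mets,
                 cutpoints = cutpoints, metabolic = metabolic),
            class = "synthetic_spec")
}

#' Read a synthetic-cohort specification from JSON or YAML
#'
#' The file may override any of: `n_total`, `prevalence`, `seed`,
#' `cutpoints`, and per-group `arcs_mets` / `arcs_non_mets` (lists of
#' `from`/`to`/`coef`). A bundled paper-like spec is at
#' `system.file("extdata", "paper_like_spec.json", package = "phqnet")`.
#'
#' @param path JSON (`.json`) or YAML file.
#' @return a [synthetic_spec()].
#' @export
read_synthetic_spec <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list()
  for (f in c("n_total", "prevalence", "seed", "cutpoints"))
    if (!is.null(cfg[[f]])) args[[f]] <- cfg[[f]]
  for (grp in c("mets", "non_mets")) {
    af <- cfg[[paste0("arcs_", grp)]]
    if (!is.null(af)) {
      af <- as.data.frame(af, stringsAsFactors = FALSE)
      g <- dag(paste0("PHQ", 1:10), af[c("from", "to")])
      args[[paste0("dag_", grp)]] <- g
      args[[paste0("coefficients_", grp)]] <-
        if ("coef" %in% names(af)) af[c("from", "to", "coef")]
        else default_arc_coefficients(g)
    }
  }
  do.call(synthetic_spec, args)
}

#' Generate a synthetic participant cohort with known ground truth
#'
#' Emulates the shape of the NHANES MDD extract. Group sizes are fixed at
#' `round(prevalence * n_total)`. Metabolic panels are drawn from the
#' group's preset normal distributions (truncated at 0) and
#' rejection-sampled so that every MetS-group member meets >= 3 of the five
#' criteria and every non-MetS member <= 2 — the generator's labels are
#' therefore recovered exactly by [classify_mets()]. Symptoms are sampled
#' from the group's ground-truth DAG; all records carry an MDD ICD-10 code
#' (F32.9 or F33.9) and the psychotropic flag.
#'
#' @param spec a [synthetic_spec()].
#' @param thresholds classifier thresholds used to enforce the group labels.
#' @return cohort `data.frame` in the [cohort_fields()] schema plus a
#'   ground-truth `group` column; rows shuffled, ids `S00001`...
#' @export
generate_cohort <- function(spec = synthetic_spec(),
                            thresholds = mets_thresholds()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n_mets <- round(spec$prevalence * spec$n_total)
  n_non <- spec$n_total - n_mets
  met <- spec$metabolic
  grab <- function(col, grp, n) {
    mu <- met[[paste0(grp, "_mean")]][match(col, met$variable)]
    sd <- met[[paste0(grp, "_sd")]][match(col, met$variable)]
    v <- stats::rnorm(n, mu, sd)
    while (any(v <= 0)) v[v <= 0] <- stats::rnorm(sum(v <= 0), mu, sd)
    v
  }
  sex_p <- attr(met, "sex_counts")
  sample_group <- function(grp, n_target, want_mets) {
    if (n_target == 0) {
      out <- NULL
      return(out)
    }
    pref <- if (grp == "mets") "mets" else "non_mets"
    p_female <- sex_p[pref, "female"] / sum(sex_p[pref, ])
    got <- list()
    n_have <- 0
    vars <- c("age", "weight", "waist", "bmi", "sbp", "dbp", "glucose",
              "triglycerides", "hdl")
    for (batch in seq_len(200)) {
      m <- max(2 * (n_target - n_have), 50)
      cand <- data.frame(sex = ifelse(stats::runif(m) < p_female,
                                      "female", "male"),
                         stringsAsFactors = FALSE)
      for (v in vars) cand[[v]] <- grab(v, pref, m)
      cls <- classify_mets(cand, thresholds)
      ok <- if (want_mets) cls$mets_status else !cls$mets_status
      if (batch == 1 && mean(ok) < 0.01)
        stop("infeasible prevalence/distribution combination for group ",
             grp, " (rejection rate > 99%)")
      got[[batch]] <- cand[ok, , drop = FALSE]
      n_have <- n_have + sum(ok)
      if (n_have >= n_target) break
    }
    if (n_have < n_target)
      stop("could not generate enough ", grp, " records")
    out <- do.call(rbind, got)[seq_len(n_target), , drop = FALSE]
    dg <- spec[[paste0("dag_", pref)]]
    sym <- sample_symptoms(dg, spec[[paste0("coefficients_", pref)]],
                           spec$cutpoints, n = n_target, seed = NULL)
    names(sym) <- tolower(names(sym))
    out <- cbind(out, sym[phq_cols()])
    out$icd_codes <- sample(c("F32.9", "F33.9"), n_target, replace = TRUE)
    out$on_psychotropic <- TRUE
    out$group <- if (want_mets) "mets" else "non_mets"
    out
  }
  cohort <- rbind(sample_group("mets", n_mets, TRUE),
                  sample_group("non_mets", n_non, FALSE))
  cohort <- cohort[sample.int(nrow(cohort)), , drop = FALSE]
  cohort <- cbind(id = sprintf("S%05d", seq_len(nrow(cohort))), cohort,
                  stringsAsFactors = FALSE)
  rownames(cohort) <- NULL
  cohort[c(cohort_fields(), "group")]
}
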