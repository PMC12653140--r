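# fixtures are built in code; no data files

# one complete, inclusion-eligible participant row
base_record <- function(...) {
  rec <- data.frame(
    id = "P1", sex = "female", age = 50, weight = 80, waist = 95,
    bmi = 30, sbp = 120, dbp = 75, glucose = 95, triglycerides = 120,
    hdl = 55, phq1 = 1, phq2 = 1, phq3 = 2, phq4 = 2, phq5 = 1,
    phq6 = 0, phq7 = 1, phq8 = 0, phq9 = 0, phq10 = 1,
    icd_codes = "F33.9", on_psychotropic = TRUE,
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

# a record engineered to meet exactly `k` of the five criteria (female)
mets_k_record <- function(k, id = "M1") {
  vals <- list(waist = c(80, 100), triglycerides = c(100, 200),
               hdl = c(60, 30), sbp = c(110, 140), glucose = c(90, 120))
  rec <- base_record(id = id, sex = "female", dbp = 70)
  crit <- names(vals)
  for (i in seq_along(crit)) {
    rec[[crit[i]]] <- vals[[crit[i]]][if (i <= k) 2 else 1]
  }
  rec
}

write_cohort_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# random DAG over `nodes` with edge probability `prob` under a random order
random_dag <- function(nodes, prob = 0.4) {
  p <- length(nodes)
  ord <- sample(nodes)
  a <- data.frame(from = character(), to = character(),
                  stringsAsFactors = FALSE)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (runif(1) < prob) a <- rbind(a, data.frame(from = ord[i], to = ord[j]))
  }
  dag(nodes, a)
}

# continuous linear-Gaussian sample from a DAG; written independently of
# sample_symptoms (plain per-node loop, raw noise, no standardisation)
simulate_gaussian <- function(g, n, coef_range = c(0.4, 0.8), noise_sd = 1) {
  ord <- topo_sort(g)
  x <- matrix(0, n, length(g$nodes), dimnames = list(NULL, g$nodes))
  for (nd in ord) {
    pa <- parents(g, nd)
    mu <- 0
    for (q in pa) mu <- mu + runif(1, coef_range[1], coef_range[2]) * x[, q]
    x[, nd] <- mu + rnorm(n, sd = noise_sd)
  }
  as.data.frame(x)
}

# independent oracle: gaussian network BIC via lm() fits, per node
lm_network_score <- function(data, g) {
  n <- nrow(data)
  total <- 0
  for (nd in g$nodes) {
    pa <- parents(g, nd)
    fit <- if (length(pa)) {
      stats::lm(stats::reformulate(pa, response = nd), data = data)
    } else {
      stats::lm(stats::reformulate("1", response = nd), data = data)
    }
    s2 <- mean(stats::residuals(fit)^2)
    ll <- sum(stats::dnorm(stats::residuals(fit), 0, sqrt(s2), log = TRUE))
    total <- total + ll - ((length(pa) + 2) / 2) * log(n)
  }
  total
}

# independent oracle: edge presence/direction tallies by plain loops
count_stability <- function(dags) {
  nodes <- dags[[1]]$nodes
  pairs <- t(utils::combn(nodes, 2))
  out <- data.frame(from = pairs[, 1], to = pairs[, 2], strength = 0,
                    direction = NA_real_, stringsAsFactors = FALSE)
  for (r in seq_len(nrow(out))) {
    a <- out$from[r]; b <- out$to[r]
    pres <- 0; fwd <- 0
    for (g in dags) {
      ab <- g$amat[a, b]; ba <- g$amat[b, a]
      if (ab || ba) pres <- pres + 1
      if (ab) fwd <- fwd + 1
    }
    out$strength[r] <- pres / length(dags)
    out$direction[r] <- if (pres > 0) fwd / pres else NA_real_
  }
  out
}

# small hand-assembled dag collection
dag_from_arcs <- function(nodes, ...) {
  a <- matrix(c(...), ncol = 2, byrow = TRUE)
  dag(nodes, data.frame(from = a[, 1], to = a[, 2], stringsAsFactors = FALSE))
}
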