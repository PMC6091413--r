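#' Simulation configuration for synthetic CT data
#'
#' Defines a gene panel and an experimental design from which
#' [simulate_ct_dataset()] draws seeded CT tables with known ground truth.
#' The generative model on the CT scale is
#' `CT[i, (l, r, t)] = baseline_i + b_il + e_ilr + u_ilrt` with
#' per-level effects `b_il ~ N(0, tau_i^2)` (condition-correlated drift;
#' an unstable gene has large tau), biological noise
#' `e_ilr ~ N(0, sigma_bio_i^2)` and technical noise
#' `u_ilrt ~ N(0, sigma_tech^2)`. Additive Gaussian error on CT is the
#' standard assumption: CT is log-scale fluorescence.
#'
#' @param genes data frame with `symbol`, `baseline_ct`, `drift_sd`
#'   (tau, CT units), `noise_sd` (sigma_bio) and optionally
#'   `efficiency_percent`.
#' @param condition_set name of the condition set.
#' @param levels character vector of condition levels.
#' @param bio_reps biological replicates per level (>= 1).
#' @param tech_reps technical replicates per biological sample (>= 1).
#' @param tech_sd technical noise SD (CT units).
#' @param seed integer seed; (config, seed) fully determines the dataset.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genes, condition_set, levels, bio_reps = 3L,
                       tech_reps = 3L, tech_sd = 0.15, seed = 1L) {
  stopifnot(all(c("symbol", "baseline_ct", "drift_sd", "noise_sd")
                %in% names(genes)),
            all(genes$drift_sd >= 0), all(genes$noise_sd >= 0),
            tech_sd >= 0, bio_reps >= 1, tech_reps >= 1,
            length(levels) >= 1)
  structure(list(genes = genes, condition_set = condition_set,
                 levels = as.character(levels),
                 bio_reps = as.integer(bio_reps),
                 tech_reps = as.integer(tech_reps),
                 tech_sd = tech_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a CT dataset with ground truth
#'
#' Draws a CT table under the model described in [sim_config()]. The
#' returned ground truth stores the realized per-level effects and the
#' true stability order — genes ascending by `sqrt(tau^2 + sigma_bio^2)`,
#' the total per-sample CT dispersion that pairwise-SD stability methods
#' measure.
#'
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return List with `ct` (an uncollapsed [ct_table()], one column per
#'   technical replicate) and `truth` (`level_effects` gene x level,
#'   `true_order`, `true_sd`, the config).
#' @export
simulate_ct_dataset <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  g <- config$genes
  n_gene <- nrow(g)
  L <- length(config$levels)
  R <- config$bio_reps
  Tn <- config$tech_reps

  set.seed(seed)
  b <- matrix(stats::rnorm(n_gene * L, 0, rep(g$drift_sd, L)),
              n_gene, L, dimnames = list(g$symbol, config$levels))
  e <- array(stats::rnorm(n_gene * L * R, 0, rep(g$noise_sd, L * R)),
             dim = c(n_gene, L, R))
  u <- array(stats::rnorm(n_gene * L * R * Tn, 0, config$tech_sd),
             dim = c(n_gene, L, R, Tn))

  cols <- expand.grid(tech_rep = seq_len(Tn), bio_rep = seq_len(R),
                      level = config$levels, stringsAsFactors = FALSE)
  cols <- cols[, c("level", "bio_rep", "tech_rep")]
  ct <- matrix(NA_real_, n_gene, nrow(cols),
               dimnames = list(g$symbol, NULL))
  for (c_idx in seq_len(nrow(cols))) {
    l <- match(cols$level[c_idx], config$levels)
    r <- cols$bio_rep[c_idx]; tt <- cols$tech_rep[c_idx]
    ct[, c_idx] <- g$baseline_ct + b[, l] + e[, l, r] + u[, l, r, tt]
  }
  samples <- data.frame(
    sample_id = paste(config$condition_set, cols$level, cols$bio_rep,
                      sep = "_"),
    condition_set = config$condition_set,
    level = cols$level, bio_rep = cols$bio_rep, tech_rep = cols$tech_rep,
    stringsAsFactors = FALSE)
  colnames(ct) <- paste(samples$sample_id, samples$tech_rep, sep = ".")

  gene_meta <- data.frame(symbol = g$symbol, stringsAsFactors = FALSE)
  if (!is.null(g$efficiency_percent))
    gene_meta$efficiency_percent <- g$efficiency_percent

  true_sd <- sqrt(g$drift_sd^2 + g$noise_sd^2)
  names(true_sd) <- g$symbol
  truth <- list(level_effects = b, true_sd = true_sd,
                true_order = g$symbol[order(true_sd, g$symbol)],
                config = config, seed = seed)
  list(ct = ct_table(ct, samples, gene_meta, collapsed = FALSE),
       truth = truth)
}

#' Simulate a 10-fold dilution standard curve
#'
#' Points follow CT = intercept + slope * log10_dilution with
#' `slope = -1 / log10(1 + efficiency_percent/100)` plus Gaussian noise.
#'
#' @param true_efficiency_percent true amplification efficiency (%).
#' @param n_levels number of 10-fold dilution levels (>= 3), at
#'   log10 dilutions 0, -1, ..., -(n_levels - 1).
#' @param sd CT noise SD (0 = exact points).
#' @param seed integer seed.
#' @param intercept CT of the undiluted sample, default 30.
#' @return Data frame with `log10_dilution`, `ct`.
#' @export
simulate_standard_curve <- function(true_efficiency_percent, n_levels = 4L,
                                    sd = 0, seed = 1L, intercept = 30) {
  if (n_levels < 3) stop("need at least 3 dilution levels")
  slope <- -1 / log10(1 + true_efficiency_percent / 100)
  x <- -(seq_len(n_levels) - 1)
  set.seed(seed)
  data.frame(log10_dilution = x,
             ct = intercept + slope * x + stats::rnorm(n_levels, 0, sd))
}

# the ten-gene assay panel used across the design presets, with baseline
# mean CTs and amplification efficiencies typical of an insect
# reference-gene survey (two rRNAs at very high expression, EF/TBP at low
# expression, the rest moderate); 18S, 28S and beta-ACT are simulated as
# condition-sensitive (large drift), the remainder as stable.
preset_gene_panel <- function() {
  data.frame(
    symbol = c("GAPDH", "18S", "28S", "EF", "RPL12",
               "b-TUB", "ATPase", "TBP", "b-ACT", "CypA"),
    baseline_ct = c(18.87, 12.0, 10.71, 24.49, 19.84,
                    19.83, 21.57, 25.91, 15.82, 18.7),
    drift_sd = c(0.2, 1.0, 1.0, 0.2, 0.2, 0.2, 0.2, 0.2, 1.0, 0.2),
    noise_sd = rep(0.3, 10),
    efficiency_percent = c(105.8, 106.1, 98.8, 102.1, 100.9,
                           108.9, 102.5, 98.3, 96.8, 101.1),
    stringsAsFactors = FALSE)
}

#' Design presets emulating a multi-condition reference-gene survey
#'
#' Returns a ready [sim_config()] for one of six experimental designs:
#' 8 developmental stages, 4 larval tissues, 6 adult tissues, 4 rearing
#' densities, 2 photoperiods or 2 temperatures — each with the ten-gene
#' panel, 3 biological and 3 technical replicates per level.
#'
#' @param name one of `"developmental_stages"`, `"larval_tissues"`,
#'   `"adult_tissues"`, `"densities"`, `"photoperiod"`, `"temperature"`.
#' @param seed integer seed stored in the config.
#' @return A [sim_config()].
#' @export
paper_design_preset <- function(name, seed = 1L) {
  presets <- list(
    developmental_stages = c("L4", "L5", "L6", "PP", "P1", "P5", "P9", "A0"),
    larval_tissues = c("brain", "epidermis", "fat_body", "alimentary_canal"),
    adult_tissues = c("male_brain", "female_brain", "testis", "ovary",
                      "male_fat_body", "female_fat_body"),
    densities = c("d1", "d10", "d20", "d30"),
    photoperiod = c("8L16D", "16L8D"),
    temperature = c("18C", "25C"))
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; valid: ",
         paste(names(presets), collapse = ", "))
  sim_config(preset_gene_panel(), condition_set = name,
             levels = presets[[name]], bio_reps = 3L, tech_reps = 3L,
             tech_sd = 0.15, seed = seed)
}

#' All six design presets simulated and combined into one CT table
#'
#' Convenience for pooled analyses: simulates every preset (seeds derived
#' from `seed` by preset index) and column-binds the tables.
#'
#' @param seed base integer seed.
#' @return List with `ct` (uncollapsed combined [ct_table()]) and
#'   `truths` (per-preset ground truth).
#' @export
simulate_all_presets <- function(seed = 1L) {
  names <- c("developmental_stages", "larval_tissues", "adult_tissues",
             "densities", "photoperiod", "temperature")
  sims <- lapply(seq_along(names), function(i)
    simulate_ct_dataset(paper_design_preset(names[i], seed = seed + i)))
  ct <- do.call(cbind, lapply(sims, function(s) s$ct$ct))
  samples <- do.call(rbind, lapply(sims, function(s) s$ct$samples))
  rownames(samples) <- NULL
  genes <- sims[[1]]$ct$genes
  list(ct = ct_table(ct, samples, genes, collapsed = FALSE),
       truths = stats::setNames(lapply(sims, `[[`, "truth"), names))
}

#' Write ground truth as a structured text sidecar
#'
#' @param truth ground truth from [simulate_ct_dataset()].
#' @param path output TSV path.
#' @export
write_ground_truth <- function(truth, path) {
  df <- data.frame(gene = rownames(truth$level_effects),
                   true_sd = unname(truth$true_sd),
                   truth$level_effects, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
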