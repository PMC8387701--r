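## Seedable synthetic fixtures emulating the shape of the AUR-TPO modelling
## data: a class-conditional Gaussian descriptor table at the study's ~83%
## inactive imbalance, an assay table spanning all four selectivity
## categories, and a small SMILES list exercising every curation rule.
## The Gaussian model is chosen deliberately: it has a closed-form Bayes
## error, so recovery and accuracy expectations can be derived analytically.

#' Configuration for the synthetic descriptor generator
#'
#' Defaults mirror the most reliable study condition: 751 inactive and 153
#' active compounds (the HSE-versus-INA imbalance, 83% inactive), 50
#' descriptors of which 5 are informative, and a one-standard-deviation
#' class shift on the informative descriptors. With these defaults the
#' Bayes-optimal balanced accuracy is
#' `pnorm(sqrt(n_informative) * effect_size / 2)` (~0.87), which upper
#' bounds what any classifier can reach.
#'
#' @param n_inactive,n_active Class sizes.
#' @param n_features Total descriptors.
#' @param n_informative Descriptors whose mean differs between classes.
#' @param effect_size Mean shift of informative descriptors for actives, in
#'   SD units.
#' @param noise_sd Within-class standard deviation.
#' @param seed Integer seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_inactive = 751, n_active = 153, n_features = 50,
                         n_informative = 5, effect_size = 1.0,
                         noise_sd = 1.0, seed = 1) {
  stopifnot(n_inactive > 0, n_active > 0, n_informative <= n_features,
            noise_sd > 0)
  structure(list(n_inactive = n_inactive, n_active = n_active,
                 n_features = n_features, n_informative = n_informative,
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = seed),
            class = "synth_config")
}

#' Generate a synthetic descriptor table with known ground truth
#'
#' Class-conditional Gaussians: every descriptor is standard normal noise
#' (scaled by `noise_sd`) except the first `n_informative` columns, whose
#' mean is shifted by `effect_size` for active compounds. Reproducible per
#' seed.
#'
#' @param cfg A [synth_config()].
#' @return List with `x` (matrix, ids `Cxxxx` as row names, descriptors
#'   `D001`... as column names), `y` (factor inactive/active),
#'   `informative` (logical ground-truth mask over columns) and `cfg`.
#' @export
synth_feature_table <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_inactive + cfg$n_active
  y <- factor(rep(c("inactive", "active"), c(cfg$n_inactive, cfg$n_active)),
              levels = c("inactive", "active"))
  set.seed(substream_seed(cfg$seed, "features"))
  x <- matrix(stats::rnorm(n * cfg$n_features, sd = cfg$noise_sd), n,
              cfg$n_features)
  informative <- seq_len(cfg$n_features) <= cfg$n_informative
  if (cfg$n_informative > 0) {
    x[y == "active", informative] <- x[y == "active", informative] +
      cfg$effect_size
  }
  rownames(x) <- sprintf("C%04d", seq_len(n))
  colnames(x) <- sprintf("D%03d", seq_len(cfg$n_features))
  list(x = x, y = y, informative = informative, cfg = cfg)
}

#' Generate a synthetic assay table
#'
#' Log IC20 triples (AUR-TPO, luciferase, cytotoxicity) drawn so that the
#' resulting selectivity categories span INA, NSE, LSE and HSE; the emitted
#' `category` column is exactly [classify_selectivity()] applied to the
#' generated values, keeping the table internally consistent. About 70% of
#' compounds are inactive (missing TPO IC20); active compounds get a TPO
#' log IC20 in [-7, -4] and confounder offsets uniform in [-2, 2.5], which
#' covers all three selectivity strata.
#'
#' @param n Number of compounds (at least 8, so all categories appear with
#'   high probability).
#' @param seed Integer seed.
#' @return Data frame `id, logic20_tpo, logic20_luc, logic20_cyto, sel,
#'   category`.
#' @export
synth_assay_table <- function(n = 40, seed = 1) {
  stopifnot(n >= 8)
  set.seed(substream_seed(seed, "assay"))
  inactive <- stats::runif(n) < 0.7
  # guarantee representation of actives across strata for small n
  inactive[1:4] <- c(TRUE, FALSE, FALSE, FALSE)
  tpo <- ifelse(inactive, NA_real_, stats::runif(n, -7, -4))
  luc <- tpo + stats::runif(n, -2, 2.5)
  cyto <- tpo + stats::runif(n, -2, 2.5)
  # pin the first three actives to one stratum each
  luc[2] <- tpo[2] + 1.5; cyto[2] <- tpo[2] + 2.0    # HSE
  luc[3] <- tpo[3] + 0.5; cyto[3] <- tpo[3] + 0.8    # LSE
  luc[4] <- tpo[4] - 1.0; cyto[4] <- tpo[4] + 0.5    # NSE
  luc[inactive] <- NA_real_
  cyto[inactive] <- NA_real_
  sel <- rep(NA_real_, n)
  sel[!inactive] <- selectivity_score(tpo[!inactive], luc[!inactive],
                                      cyto[!inactive])
  data.frame(id = sprintf("A%04d", seq_len(n)),
             logic20_tpo = tpo, logic20_luc = luc, logic20_cyto = cyto,
             sel = sel,
             category = classify_selectivity(sel),
             stringsAsFactors = FALSE)
}

#' Fixture SMILES list exercising every curation rule
#'
#' A small fixed table of structures covering: plain organics, a sodium
#' salt (neutralizable), a carbon-free inorganic, an organometallic, a
#' selenium compound (element outside the whitelist), a two-organic-fragment
#' mixture, an unparseable SMILES, a concordant duplicate pair and a
#' contradictory duplicate pair.
#'
#' @return Data frame `id, smiles, category`.
#' @export
synth_smiles_table <- function() {
  data.frame(
    id = sprintf("S%02d", 1:12),
    smiles = c(
      "CCO",                          # plain organic, already canonical
      "[Na+].[O-]C(=O)c1ccccc1",      # salt: neutralize to benzoic acid
      "O=S(=O)(O)O",                  # inorganic (no carbon)
      "CC[Pb](CC)(CC)CC",             # organometallic (carbon + metal)
      "CC[Se]CC",                     # element outside whitelist
      "CCO.CCC",                      # mixture: two organic fragments
      "C1CC",                         # unparseable (unclosed ring)
      "Oc1ccccc1",                    # duplicate pair, concordant (HSE)
      "Oc1ccccc1",                    #   "
      "Nc1ccccc1",                    # duplicate pair, contradictory
      "Nc1ccccc1",                    #   (HSE vs INA)
      "CC(N)C(=O)O"),                 # plain organic (alanine)
    category = c("INA", "HSE", "INA", "INA", "NSE", "LSE", "INA",
                 "HSE", "HSE", "HSE", "INA", "LSE"),
    stringsAsFactors = FALSE)
}

#' Write the synthetic preset to a directory
#'
#' Emits `descriptors.csv`, `labels.csv`, `activity.csv` and `smiles.tsv`
#' for a given seed. Outputs are byte-identical across runs with the same
#' seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param cfg Descriptor-generator configuration.
#' @return The directory path, invisibly.
#' @export
write_synth_preset <- function(dir, seed = 1,
                               cfg = synth_config(seed = seed)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ft <- synth_feature_table(cfg)
  write_descriptors(round(ft$x, 10), file.path(dir, "descriptors.csv"))
  utils::write.csv(data.frame(id = rownames(ft$x), label = ft$y),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  at <- synth_assay_table(seed = seed)
  at[] <- lapply(at, function(col) if (is.numeric(col)) round(col, 10)
                 else col)
  utils::write.csv(at, file.path(dir, "activity.csv"), row.names = FALSE,
                   na = "")
  st <- synth_smiles_table()
  utils::write.table(st[, c("id", "smiles")], file.path(dir, "smiles.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(dir)
}
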