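#' Selectivity score of an AUR-TPO positive hit-call
#'
#' The selectivity (SEL) of a TPO-inhibition hit is the separation, on the
#' log10 IC20 scale, between the AUR-TPO assay and the most potent of two
#' confounding assays (luciferase inhibition and cytotoxicity):
#' `SEL = min(logIC20_luc, logIC20_cyto) - logIC20_tpo`. A large positive SEL
#' means the compound inhibits TPO at concentrations well below those causing
#' non-specific enzyme inhibition or cytotoxicity, i.e. the hit is
#' TPO-specific; negative SEL means a confounder is more potent than the TPO
#' signal.
#'
#' A missing confounder IC20 is replaced by `ceiling` (default `Inf`, meaning
#' "no confounding activity detected up to any tested concentration"); with
#' both confounders missing, SEL is `ceiling - logic20_tpo`.
#'
#' @param logic20_tpo log10 molar IC20 of the AUR-TPO assay. Must be present:
#'   SEL is defined only for positive hit-calls.
#' @param logic20_luc log10 IC20 of the luciferase (non-specific enzyme
#'   inhibition) assay, or `NA`.
#' @param logic20_cyto log10 IC20 of the cytotoxicity assay, or `NA`.
#' @param ceiling Value substituted for an absent confounder IC20.
#' @return Numeric vector of SEL values.
#' @export
selectivity_score <- function(logic20_tpo, logic20_luc = NA_real_,
                              logic20_cyto = NA_real_, ceiling = Inf) {
  n <- length(logic20_tpo)
  logic20_luc <- rep_len(logic20_luc, n)
  logic20_cyto <- rep_len(logic20_cyto, n)
  if (anyNA(logic20_tpo)) {
    stop("SEL undefined for inactives: logic20_tpo is missing")
  }
  luc <- ifelse(is.na(logic20_luc), ceiling, logic20_luc)
  cyto <- ifelse(is.na(logic20_cyto), ceiling, logic20_cyto)
  pmin(luc, cyto) - logic20_tpo
}

#' Classify a selectivity score into a hit-call category
#'
#' Active TPO hits are stratified by selectivity: non-selective
#' (NSE, SEL < 0), low selective (LSE, 0 <= SEL < 1) and high selective
#' (HSE, SEL >= 1). An absent SEL (no TPO hit-call) maps to INA (inactive).
#' The boundaries are closed on the right category: SEL = 0 is LSE and
#' SEL = 1 is HSE.
#'
#' @param sel Numeric vector of SEL values; `NA` for inactives.
#' @return Factor with levels `INA`, `NSE`, `LSE`, `HSE`.
#' @export
classify_selectivity <- function(sel) {
  out <- ifelse(is.na(sel), "INA",
         ifelse(sel < 0, "NSE",
         ifelse(sel < 1, "LSE", "HSE")))
  factor(out, levels = c("INA", "NSE", "LSE", "HSE"))
}

#' Binary partitioning schemes over hit-call categories
#'
#' Four schemes map the INA/NSE/LSE/HSE categories to a binary
#' active/inactive endpoint. INA is always inactive; the schemes differ in
#' how the three active-hit strata are assigned:
#'
#' * `"hse-only"`: active = HSE; inactive = LSE, NSE, INA.
#' * `"hse-lse"`: active = HSE, LSE; inactive = NSE, INA.
#' * `"all-active"`: active = HSE, LSE, NSE; inactive = INA.
#' * `"hse-vs-ina"`: active = HSE; inactive = INA; LSE and NSE are excluded
#'   from the dataset entirely (only the most reliable hit-calls retained).
#'
#' @param name Scheme name.
#' @return An object of class `partition_scheme` with elements `name`,
#'   `active`, `inactive` and `excluded` (character vectors of categories).
#' @export
partition_scheme <- function(name = c("hse-only", "hse-lse", "all-active",
                                      "hse-vs-ina")) {
  name <- match.arg(name)
  sets <- switch(name,
    "hse-only"   = list(active = "HSE", inactive = c("LSE", "NSE", "INA"),
                        excluded = character()),
    "hse-lse"    = list(active = c("HSE", "LSE"), inactive = c("NSE", "INA"),
                        excluded = character()),
    "all-active" = list(active = c("HSE", "LSE", "NSE"), inactive = "INA",
                        excluded = character()),
    "hse-vs-ina" = list(active = "HSE", inactive = "INA",
                        excluded = c("LSE", "NSE")))
  structure(c(list(name = name), sets), class = "partition_scheme")
}

#' @export
print.partition_scheme <- function(x, ...) {
  cat("Partitioning scheme:", x$name, "\n")
  cat("  active:  ", paste(x$active, collapse = " + "), "\n")
  cat("  inactive:", paste(x$inactive, collapse = " + "), "\n")
  if (length(x$excluded)) {
    cat("  excluded:", paste(x$excluded, collapse = " + "), "\n")
  }
  invisible(x)
}

#' Apply a partitioning scheme to hit-call categories
#'
#' @param categories Factor or character vector of `INA`/`NSE`/`LSE`/`HSE`.
#' @param scheme A [partition_scheme()] object or scheme name.
#' @return A list with `label` (factor `inactive`/`active`, `NA` for
#'   excluded compounds) and `counts` (named vector: `active`, `inactive`,
#'   `excluded`, `total` = usable compounds).
#' @export
apply_partition_scheme <- function(categories, scheme) {
  if (is.character(scheme)) scheme <- partition_scheme(scheme)
  categories <- as.character(categories)
  known <- c("INA", "NSE", "LSE", "HSE")
  if (!all(categories %in% known)) {
    stop("unknown category: ",
         paste(setdiff(unique(categories), known), collapse = ", "))
  }
  label <- rep(NA_character_, length(categories))
  label[categories %in% scheme$active] <- "active"
  label[categories %in% scheme$inactive] <- "inactive"
  label <- factor(label, levels = c("inactive", "active"))
  counts <- c(active = sum(label == "active", na.rm = TRUE),
              inactive = sum(label == "inactive", na.rm = TRUE),
              excluded = sum(is.na(label)),
              total = sum(!is.na(label)))
  list(label = label, counts = counts)
}

#' Stratified train/test split with largest-remainder allocation
#'
#' Splits a binary-labelled dataset into a training set (TrS) and a test set
#' (TeS) preserving the class ratio. The total test size is
#' `ceiling(test_fraction * N)`; per-class test sizes follow the
#' largest-remainder rule on the exact class quotas, so the realized class
#' ratio is as close to the global one as integer counts permit. With 751
#' inactives and 153 actives at `test_fraction = 0.2` this yields a test set
#' of 181 (150 inactive + 31 active) and a training set of 723.
#'
#' @param labels Binary class vector (see [as_activity()]). `NA` entries
#'   (excluded compounds) are not allowed.
#' @param test_fraction Fraction of compounds assigned to the test set.
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @return A list with `split` (factor `TrS`/`TeS` per compound),
#'   `test_fraction` and `seed`.
#' @export
stratified_split <- function(labels, test_fraction = 0.2, seed = 1) {
  y <- as_activity(labels)
  stopifnot(test_fraction > 0, test_fraction < 1)
  if (nlevels(droplevels(y)) < 2L) {
    stop("both classes must be present to stratify the split")
  }
  n <- length(y)
  n_test <- ceiling(test_fraction * n)
  quota <- n_test * table(y) / n
  base <- floor(quota)
  rem <- n_test - sum(base)
  if (rem > 0) {
    # largest fractional remainder first; ties broken by class level order
    ord <- order(-(quota - base), seq_along(quota))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  split <- rep("TrS", n)
  set.seed(substream_seed(seed, "split"))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    take <- sample(idx, base[[cl]])
    split[take] <- "TeS"
  }
  list(split = factor(split, levels = c("TrS", "TeS")),
       test_fraction = test_fraction, seed = seed)
}
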