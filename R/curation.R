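## SMILES curation: structure standardization, element filtering,
## salt handling and tautomer-aware deduplication. Chemistry is delegated to
## OpenBabel through the ChemmineOB package; everything above the toolkit
## (fragment logic, element rules, conflict resolution) is defined here.

# elements allowed in the modelled chemical space
ELEMENT_WHITELIST <- c("H", "C", "N", "O", "F", "Br", "I", "Cl", "P", "S")

# metals and metalloids whose presence marks a structure inorganic /
# organometallic rather than merely carrying an unusual element
METALS <- c(
  "Li", "Be", "Na", "Mg", "Al", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn",
  "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Rb", "Sr", "Y", "Zr", "Nb", "Mo",
  "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn", "Sb", "Cs", "Ba", "La",
  "Ce", "Pr", "Nd", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb",
  "Bi", "Th", "U")

.require_chem_backend <- function() {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("the ChemmineOB package is required for SMILES curation")
  }
}

# internal: OpenBabel properties of one SMILES, or NULL when unparseable
ob_props <- function(smiles) {
  .require_chem_backend()
  res <- tryCatch(
    suppressWarnings(
      ChemmineOB::forEachMol("SMILES", smiles, ChemmineOB::prop_OB)),
    error = function(e) NULL)
  if (is.null(res) || length(res) == 0L) return(NULL)
  p <- res[[1L]]
  if (is.null(p$cansmi) || !nzchar(trimws(p$cansmi))) return(NULL)
  p$cansmi <- trimws(p$cansmi)
  p$InChI <- trimws(p$InChI)
  p
}

# internal: canonical SMILES after OpenBabel charge neutralization
ob_neutralize <- function(smiles) {
  .require_chem_backend()
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "CAN", smiles,
      options = data.frame(names = "neutralize", args = ""))),
    error = function(e) "")
  trimws(out)
}

# internal: element symbols occurring in a Hill-notation molecular formula
formula_elements <- function(formula) {
  m <- gregexpr("[A-Z][a-z]?", formula)[[1L]]
  if (m[1L] == -1L) return(character())
  unique(substring(formula, m, m + attr(m, "match.length") - 1L))
}

#' Element whitelist filter
#'
#' Accepts a structure only when every atom is one of the elements the
#' models are trained on: H, C, N, O, F, Br, I, Cl, P, S. Compounds with any
#' other element (selenium, silicon, metals, ...) fall outside the modelled
#' chemical space and are rejected.
#'
#' @param smiles Character vector of SMILES.
#' @return Logical vector: `TRUE` = all atoms whitelisted, `FALSE` =
#'   rejected, `NA` = unparseable.
#' @export
filter_elements <- function(smiles) {
  vapply(smiles, function(s) {
    p <- ob_props(s)
    if (is.null(p)) return(NA)
    all(formula_elements(p$formula) %in% ELEMENT_WHITELIST)
  }, logical(1), USE.NAMES = FALSE)
}

#' Standardize a chemical structure
#'
#' One structure at a time, applies the curation rules used to prepare the
#' modelling dataset:
#'
#' 1. unparseable SMILES are rejected (`rejected_no_unique_structure`);
#' 2. carbon-free structures are inorganic (`rejected_inorganic`);
#' 3. multi-fragment structures are salts only when exactly one fragment
#'    contains carbon — the counter-ions are stripped; two or more organic
#'    fragments are a mixture (`rejected_mixture`);
#' 4. a metal element in the remaining organic fragment marks an
#'    organometallic (`rejected_inorganic`); any other element outside
#'    H, C, N, O, F, Br, I, Cl, P, S is rejected (`rejected_element`);
#' 5. charges with a neutral form are neutralized and the structure is
#'    emitted as canonical SMILES, together with its standard InChI (used as
#'    a tautomer-aware duplicate hash: the InChI mobile-hydrogen layer maps
#'    heteroatom tautomers to one identifier).
#'
#' The operation is idempotent: re-standardizing an accepted canonical
#' SMILES returns the same canonical SMILES.
#'
#' @param smiles A single SMILES string.
#' @return A list with `status` (one of `accepted`, `rejected_inorganic`,
#'   `rejected_mixture`, `rejected_element`, `rejected_no_unique_structure`),
#'   `curated_smiles` (canonical SMILES or `NA`), `inchi` (duplicate hash or
#'   `NA`) and `notes`.
#' @export
standardize_structure <- function(smiles) {
  out <- function(status, curated = NA_character_, inchi = NA_character_,
                  notes = "") {
    list(status = status, curated_smiles = curated, inchi = inchi,
         notes = notes)
  }
  if (length(smiles) != 1L || is.na(smiles) || !nzchar(trimws(smiles))) {
    return(out("rejected_no_unique_structure", notes = "empty SMILES"))
  }
  smiles <- trimws(smiles)
  if (is.null(ob_props(smiles))) {
    return(out("rejected_no_unique_structure", notes = "unparseable SMILES"))
  }
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1L]]
  frags <- frags[nzchar(frags)]
  fprops <- lapply(frags, ob_props)
  if (any(vapply(fprops, is.null, logical(1)))) {
    return(out("rejected_no_unique_structure",
               notes = "unparseable fragment"))
  }
  has_c <- vapply(fprops, function(p) "C" %in% formula_elements(p$formula),
                  logical(1))
  if (!any(has_c)) {
    return(out("rejected_inorganic", notes = "no carbon atom"))
  }
  if (sum(has_c) > 1L) {
    return(out("rejected_mixture",
               notes = sprintf("%d organic fragments", sum(has_c))))
  }
  keep <- frags[which(has_c)]
  notes <- if (length(frags) > 1L) "counter-ion(s) stripped" else ""
  elems <- formula_elements(fprops[[which(has_c)]]$formula)
  if (any(elems %in% METALS)) {
    return(out("rejected_inorganic",
               notes = paste0("organometallic: contains ",
                              paste(intersect(elems, METALS),
                                    collapse = ", "))))
  }
  bad <- setdiff(elems, ELEMENT_WHITELIST)
  if (length(bad)) {
    return(out("rejected_element",
               notes = paste0("element(s) outside whitelist: ",
                              paste(bad, collapse = ", "))))
  }
  can <- ob_neutralize(keep)
  if (!nzchar(can)) {
    return(out("rejected_no_unique_structure",
               notes = "standardization failed"))
  }
  p <- ob_props(can)
  if (is.null(p)) {
    return(out("rejected_no_unique_structure",
               notes = "canonical form unparseable"))
  }
  out("accepted", curated = p$cansmi, inchi = p$InChI, notes = notes)
}

#' Resolve duplicate structures
#'
#' Records sharing one standardized structure (identical InChI hash, which
#' merges heteroatom tautomers) are collapsed: when their hit-call
#' categories agree the first record is kept (`merged_duplicate`, the others
#' point to it), and when the categories are contradictory the whole group
#' is removed (`removed_contradictory_duplicate`). By default contradiction
#' is judged on the binary hit-call (INA versus any active stratum);
#' `conflict_on = "category"` treats any disagreement among
#' INA/NSE/LSE/HSE as contradictory.
#'
#' @param report Data frame with columns `id`, `status`, `curated_smiles`,
#'   `inchi`, `notes` (from [standardize_structure()]) and `category`.
#' @param conflict_on `"binary"` or `"category"`.
#' @return The report with updated `status`/`notes` and a logical `kept`
#'   column marking the records that enter the modelling dataset. Every
#'   input id appears exactly once; no two kept records share a structure.
#' @export
deduplicate_structures <- function(report, conflict_on = c("binary",
                                                           "category")) {
  conflict_on <- match.arg(conflict_on)
  stopifnot(all(c("id", "status", "curated_smiles", "inchi", "category")
                %in% names(report)))
  if (anyDuplicated(report$id)) stop("duplicate ids in curation input")
  report$kept <- report$status == "accepted"
  acc <- which(report$kept)
  key <- report$inchi[acc]
  for (grp in split(acc, key)) {
    if (length(grp) < 2L) next
    cats <- as.character(report$category[grp])
    eff <- if (conflict_on == "binary") {
      ifelse(cats == "INA", "inactive", "active")
    } else cats
    if (length(unique(eff)) > 1L) {
      report$status[grp] <- "removed_contradictory_duplicate"
      report$curated_smiles[grp] <- NA_character_
      report$kept[grp] <- FALSE
      report$notes[grp] <- paste0("contradictory categories: ",
                                  paste(cats, collapse = "/"))
    } else {
      report$status[grp] <- "merged_duplicate"
      report$kept[grp] <- FALSE
      report$kept[grp[1L]] <- TRUE
      report$notes[grp[1L]] <- sprintf("%d duplicate record(s) merged",
                                       length(grp) - 1L)
      report$notes[grp[-1L]] <- paste0("merged into ", report$id[grp[1L]])
    }
  }
  report
}

#' Curate a table of chemical structures
#'
#' Runs [standardize_structure()] on every record and resolves duplicates
#' with [deduplicate_structures()]. The result is a per-record curation
#' report; rows with `kept = TRUE` form the curated dataset.
#'
#' @param records Data frame with columns `id`, `smiles` and optionally
#'   `category` (INA/NSE/LSE/HSE; defaults to `INA` when absent).
#' @param conflict_on Passed to [deduplicate_structures()].
#' @return Data frame `id, smiles, category, status, curated_smiles, inchi,
#'   notes, kept`.
#' @export
curate_structures <- function(records, conflict_on = "binary") {
  stopifnot(all(c("id", "smiles") %in% names(records)))
  if (anyDuplicated(records$id)) stop("compound ids must be unique")
  if (is.null(records$category)) records$category <- "INA"
  std <- lapply(records$smiles, standardize_structure)
  report <- data.frame(
    id = records$id,
    smiles = records$smiles,
    category = as.character(records$category),
    status = vapply(std, `[[`, "", "status"),
    curated_smiles = vapply(std, `[[`, "", "curated_smiles"),
    inchi = vapply(std, `[[`, "", "inchi"),
    notes = vapply(std, `[[`, "", "notes"),
    stringsAsFactors = FALSE)
  deduplicate_structures(report, conflict_on = conflict_on)
}

#' Read a structure table
#'
#' Accepts either a CSV with columns `id,smiles[,category|ic20_tpo,
#' ic20_luc,ic20_cyto]` or a two-column tab-separated SMILES file
#' (`id<TAB>smiles`, no header).
#'
#' @param path File path.
#' @return Data frame with at least `id` and `smiles`.
#' @export
read_structures <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(df)[1:2] <- c("id", "smiles")
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "smiles") %in% names(df)))
  df$id <- as.character(df$id)
  df
}

#' Write a curation report CSV
#'
#' @param report Output of [curate_structures()].
#' @param path Destination CSV (`id,status,curated_smiles,notes`).
#' @export
write_curation_report <- function(report, path) {
  utils::write.csv(report[, c("id", "status", "curated_smiles", "notes")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}
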